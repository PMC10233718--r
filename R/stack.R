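#' Multi-channel 3D image stack with physical calibration
#'
#' Container for a multi-channel fluorescence z-stack. Voxel data are stored
#' as a 4D array indexed `(channel, z, y, x)`; the physical calibration
#' (nm per pixel in xy, nm per slice in z) travels with the data so that no
#' downstream operation ever works in bare pixel units.
#'
#' Coordinate conventions used throughout the package: voxel coordinates are
#' 0-based continuous values in axis order `(z, y, x)`, with the origin at the
#' center of the first voxel; physical coordinates are in nanometres,
#' obtained with [px_to_nm()]. R's 1-based array subscripting is an internal
#' detail only.
#'
#' @param data numeric 4D array, dim `(n_channels, nz, ny, nx)`, non-negative.
#' @param voxel_size_xy in-plane pixel size in nm (default 110, a typical
#'   60x sCMOS configuration; always configurable).
#' @param voxel_size_z z-step in nm (default 1000).
#' @param channels character vector of channel labels, length `dim(data)[1]`.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, voxel_size_xy = 110, voxel_size_z = 1000,
                        channels = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (channel, z, y, x)")
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[1]))
  if (length(channels) != dim(data)[1])
    stop("length(channels) must equal the number of channels")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!(voxel_size_xy > 0 && voxel_size_z > 0))
    stop("voxel sizes must be strictly positive")
  if (anyNA(data) || min(data) < 0)
    stop("intensities must be finite and non-negative")
  structure(list(data = data,
                 voxel_size_xy = as.numeric(voxel_size_xy),
                 voxel_size_z = as.numeric(voxel_size_z),
                 channels = as.character(channels)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s) [%s], %d z x %d y x %d x voxels\n",
              d[1], paste(x$channels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  calibration: %.1f nm/px (xy), %.1f nm/slice (z)\n",
              x$voxel_size_xy, x$voxel_size_z))
  invisible(x)
}

#' Extract one channel volume
#'
#' @param stack an `ImageStack`.
#' @param channel channel label or index.
#' @return 3D array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channels)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else i <- channel
  v <- stack$data[i, , , , drop = FALSE]
  array(v, dim = dim(stack$data)[2:4])
}

#' Convert voxel coordinates to physical nanometres (and back)
#'
#' `px_to_nm` scales 0-based voxel coordinates `(z, y, x)` by the stack
#' calibration; `nm_to_px` is its exact inverse. The origin sits at the
#' center of voxel `(0, 0, 0)`.
#'
#' @param coord numeric vector `(z, y, x)` or matrix with 3 columns.
#' @param stack an `ImageStack`, or a list with `voxel_size_xy`/`voxel_size_z`.
#' @return coordinates in nm (or voxels) with the same shape as the input.
#' @export
px_to_nm <- function(coord, stack) {
  s <- c(stack$voxel_size_z, stack$voxel_size_xy, stack$voxel_size_xy)
  if (is.matrix(coord)) sweep(coord, 2, s, "*") else coord * s
}

#' @rdname px_to_nm
#' @export
nm_to_px <- function(coord, stack) {
  s <- c(stack$voxel_size_z, stack$voxel_size_xy, stack$voxel_size_xy)
  if (is.matrix(coord)) sweep(coord, 2, s, "/") else coord / s
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z slices of channel 1, then channel
#' 2, ...) as 32-bit float TIFF. Because the TIFF writer stores float data in
#' `[0, 1]`, intensities are scaled by the stack maximum and the scale factor
#' is recorded in the sidecar `<path>.json`, together with the voxel
#' calibration, channel labels and page layout. The sidecar is mandatory on
#' read: a stack without calibration is refused rather than silently treated
#' as pixel units.
#'
#' @param stack an `ImageStack`.
#' @param path TIFF file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_stack` returns `path` invisibly; `read_stack` an `ImageStack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- matrix(stack$data[ch, z, , ] / scale, d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(format_version = 1L,
               layout = "channel-major",
               channels = stack$channels,
               n_z = d[2],
               voxel_size_xy = stack$voxel_size_xy,
               voxel_size_z = stack$voxel_size_z,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("calibration sidecar missing (", sidecar, "): refusing to guess ",
         "pixel units")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("channels", "n_z", "voxel_size_xy", "voxel_size_z",
              "intensity_scale"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent TIFF page shapes: ", paste(unique(shapes),
                                                  collapse = ", "))
  nc <- length(meta$channels)
  nz <- as.integer(meta$n_z)
  if (length(pages) != nc * nz)
    stop("page count ", length(pages), " does not match layout ",
         nc, " channels x ", nz, " slices")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nc, nz, ny, nx))
  k <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      data[ch, z, , ] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  image_stack(data, meta$voxel_size_xy, meta$voxel_size_z, meta$channels)
}
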