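#' Chromatic channel transform
#'
#' In-plane similarity transform (translation, rotation, isotropic scale)
#' mapping one channel's pixel coordinates onto the reference channel. Only
#' xy is corrected: at a 1000 nm z-step, axial chromatic registration is
#' ill-posed, and z is left aligned. Applying a transform and then its
#' inverse recovers the input to machine precision.
#'
#' The mapping is `p' = s * R(theta) * (p - c) + c + t` for in-plane points
#' `p = (x, y)`, with `c` the rotation center (by convention the image
#' center; the parameterization is center-invariant because the translation
#' is co-estimated).
#'
#' @param channel source channel label.
#' @param dx,dy translation in px.
#' @param rotation rotation in radians.
#' @param scale unitless magnification factor; sanity bounds (0.9, 1.1).
#' @param center rotation center `(x, y)` in px.
#' @param residual_px,residual_nm rms residual over the beads used to fit.
#' @param degenerate TRUE when a collinear bead layout forced a
#'   translation-only fallback.
#' @return object of class `ChannelTransform`.
#' @export
channel_transform <- function(channel = NA_character_, dx = 0, dy = 0,
                              rotation = 0, scale = 1, center = c(0, 0),
                              residual_px = NA_real_, residual_nm = NA_real_,
                              degenerate = FALSE) {
  if (scale <= 0.9 || scale >= 1.1)
    stop("scale ", scale, " outside the plausible chromatic range (0.9, 1.1)")
  if (abs(rotation) > 5 * pi / 180)
    stop("rotation ", rotation, " rad exceeds the plausible +/-5 degrees")
  structure(list(channel = channel, dx = dx, dy = dy, rotation = rotation,
                 scale = scale, center = as.numeric(center),
                 residual_px = residual_px, residual_nm = residual_nm,
                 degenerate = isTRUE(degenerate)),
            class = "ChannelTransform")
}

#' @export
print.ChannelTransform <- function(x, ...) {
  cat(sprintf(paste0("ChannelTransform [%s]: shift (%.4f, %.4f) px, ",
                     "rotation %.5f deg, scale %.6f\n"),
              x$channel, x$dx, x$dy, x$rotation * 180 / pi, x$scale))
  if (!is.na(x$residual_px))
    cat(sprintf("  rms residual %.4f px%s\n", x$residual_px,
                if (x$degenerate) " (translation-only fallback)" else ""))
  invisible(x)
}

#' Apply (or invert) a channel transform
#'
#' Transforms in-plane coordinates from the source channel frame into the
#' reference frame. Accepts an n x 2 matrix of `(x, y)` pixel coordinates or
#' a spot table with `x`, `y` columns (coordinates are corrected in place).
#' Correction is applied to fitted coordinates, never by resampling voxel
#' data, so no interpolation artifacts enter the distance analysis.
#'
#' @param coords matrix with columns x, y (px), or a spot-table data.frame.
#' @param transform a `ChannelTransform`.
#' @return corrected coordinates of the same type as the input.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "ChannelTransform"))
  if (is.data.frame(coords)) {
    m <- apply_transform(cbind(coords$x, coords$y), transform)
    coords$x <- m[, 1]; coords$y <- m[, 2]
    return(coords)
  }
  coords <- rbind(coords)  # promote a bare length-2 vector
  th <- transform$rotation; s <- transform$scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(transform$center, nrow(coords), 2, byrow = TRUE)
  out <- s * (coords - ctr) %*% t(R) + ctr
  out[, 1] <- out[, 1] + transform$dx
  out[, 2] <- out[, 2] + transform$dy
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "ChannelTransform"))
  th <- transform$rotation; s <- transform$scale
  # inverse of p' = sR(p - c) + c + t
  # p = (1/s) R^-1 (p' - c - t) + c = (1/s)R^-1 (p - c) + c + t'
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tvec <- -solve(s * R, c(transform$dx, transform$dy))
  channel_transform(transform$channel, dx = tvec[1], dy = tvec[2],
                    rotation = -th, scale = 1 / s, center = transform$center,
                    residual_px = transform$residual_px,
                    residual_nm = transform$residual_nm,
                    degenerate = transform$degenerate)
}

#' Estimate a similarity transform from matched bead centers
#'
#' Closed-form least-squares (Procrustes/Umeyama) fit of translation,
#' rotation and isotropic scale mapping `moving` onto `reference`,
#' minimizing the summed squared distances between matched peaks. With
#' collinear bead layouts the rotation/scale part is unidentifiable; a
#' translation-only fallback is returned with `degenerate = TRUE` and a
#' warning.
#'
#' @param reference,moving n x 2 matrices of matched `(x, y)` centers (px),
#'   n >= 3.
#' @param center rotation center used to parameterize the result
#'   (default the centroid of the reference set; pass the image center when
#'   known).
#' @param channel label stored in the result.
#' @param voxel_size_xy nm/px used to report the residual in nm.
#' @return a `ChannelTransform` with rms residual over the fitted beads.
#' @export
estimate_transform <- function(reference, moving, center = NULL,
                               channel = NA_character_, voxel_size_xy = 110) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (nrow(reference) != nrow(moving))
    stop("matched sets differ in length")
  if (nrow(reference) < 3)
    stop("similarity transform unidentifiable with fewer than 3 matched beads")
  mr <- colMeans(reference); mm <- colMeans(moving)
  X <- sweep(moving, 2, mm); Y <- sweep(reference, 2, mr)
  if (is.null(center)) center <- mr
  S <- crossprod(X, Y) / nrow(X)          # 2x2 cross-covariance
  sv <- svd(S)
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)
  if (degenerate) {
    warning("collinear bead configuration: translation-only fallback")
    th <- 0; s <- 1
  } else {
    D <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    th <- atan2(R[2, 1], R[1, 1])
    s <- sum(diag(D) * sv$d) / mean(rowSums(X^2))
  }
  # translation such that s R (mm - c) + c + t = mr
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tvec <- mr - (s * Rm %*% (mm - center) + center)
  tr <- channel_transform(channel, dx = tvec[1], dy = tvec[2], rotation = th,
                          scale = s, center = center, degenerate = degenerate)
  corrected <- apply_transform(moving, tr)
  rms <- sqrt(mean(rowSums((corrected - reference)^2)))
  tr$residual_px <- rms
  tr$residual_nm <- rms * voxel_size_xy
  tr
}

#' Localize beads and match them across channels
#'
#' Fits every fiducial bead in each channel of a calibration stack to a 3D
#' Gaussian (same constrained fit as for smFISH spots) and matches beads
#' across channels to the reference channel by nearest neighbour within a
#' maximum pairing radius. Beads closer together than the fit window, or
#' visible in the reference channel only, are dropped.
#'
#' @param bead_stack `ImageStack` of the bead field.
#' @param reference_channel label of the reference channel (typically the
#'   far-red channel, which has the lowest background).
#' @param params detection parameter list (see [default_config()]
#'   `$detection`).
#' @param pairing_radius maximum center distance for cross-channel matching
#'   (px, default 5).
#' @return list with `centers` (per-channel list of n x 2 matrices of matched
#'   `(x, y)` centers, row-aligned to the reference) and `n_rejected`.
#' @export
localize_beads <- function(bead_stack, reference_channel,
                           params = default_config()$detection,
                           pairing_radius = 5) {
  stopifnot(inherits(bead_stack, "ImageStack"))
  if (!reference_channel %in% bead_stack$channels)
    stop("unknown reference channel: ", reference_channel)
  fit1 <- function(ch) {
    spots <- detect_spots(bead_stack, ch, params, preprocess = TRUE)
    spots <- spots[spots$accepted, , drop = FALSE]
    if (nrow(spots) >= 2) {      # reject beads closer than the fit window
      d <- as.matrix(stats::dist(cbind(spots$x, spots$y)))
      diag(d) <- Inf
      keep <- apply(d, 1, min) > params$fit_window_xy
      spots <- spots[keep, , drop = FALSE]
    }
    spots
  }
  ref <- fit1(reference_channel)
  others <- setdiff(bead_stack$channels, reference_channel)
  centers <- list()
  keep_ref <- rep(TRUE, nrow(ref))
  matched <- list()
  for (ch in others) {
    sp <- fit1(ch)
    idx <- rep(NA_integer_, nrow(ref))
    for (i in seq_len(nrow(ref))) {
      if (!nrow(sp)) break
      d <- sqrt((sp$x - ref$x[i])^2 + (sp$y - ref$y[i])^2)
      j <- which.min(d)
      if (d[j] <= pairing_radius) idx[i] <- j
    }
    matched[[ch]] <- idx
    keep_ref <- keep_ref & !is.na(idx)
    centers[[ch]] <- sp
  }
  if (sum(keep_ref) < 3)
    stop("fewer than 3 beads matched across all channels: ",
         "transform unidentifiable")
  out <- list()
  out[[reference_channel]] <- cbind(ref$x, ref$y)[keep_ref, , drop = FALSE]
  for (ch in others) {
    sp <- centers[[ch]]
    out[[ch]] <- cbind(sp$x, sp$y)[matched[[ch]][keep_ref], , drop = FALSE]
  }
  list(centers = out, n_rejected = nrow(ref) - sum(keep_ref),
       reference_channel = reference_channel)
}

#' Estimate chromatic transforms for every channel of a bead field
#'
#' Convenience wrapper: localize and match beads, then fit one similarity
#' transform per non-reference channel, parameterized about the image
#' center.
#'
#' @inheritParams localize_beads
#' @return named list of `ChannelTransform` (reference channel maps to the
#'   identity).
#' @export
register_channels <- function(bead_stack, reference_channel,
                              params = default_config()$detection,
                              pairing_radius = 5) {
  m <- localize_beads(bead_stack, reference_channel, params, pairing_radius)
  d <- dim(bead_stack$data)
  ctr <- c((d[4] - 1) / 2, (d[3] - 1) / 2)   # (x, y) image center, 0-based
  out <- list()
  for (ch in bead_stack$channels) {
    if (ch == reference_channel) {
      out[[ch]] <- channel_transform(ch, center = ctr, residual_px = 0,
                                     residual_nm = 0)
    } else {
      out[[ch]] <- estimate_transform(m$centers[[reference_channel]],
                                      m$centers[[ch]], center = ctr,
                                      channel = ch,
                                      voxel_size_xy = bead_stack$voxel_size_xy)
    }
  }
  out
}

#' Persist channel transforms as JSON
#'
#' @param transforms named list of `ChannelTransform`.
#' @param path JSON path.
#' @export
write_transforms <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(r)
    channel_transform(r$channel, r$dx, r$dy, r$rotation, r$scale,
                      unlist(r$center), r$residual_px, r$residual_nm,
                      r$degenerate))
}

#' Register a spot table into the physical reference frame
#'
#' Applies the channel's chromatic transform to the fitted pixel coordinates
#' and converts to nanometres, populating `x_nm`, `y_nm`, `z_nm`. For the
#' reference channel pass `transform = NULL` (identity).
#'
#' @param spots spot table with `x`, `y`, `z` (0-based px).
#' @param stack the `ImageStack` the spots were fitted on (for calibration).
#' @param transform a `ChannelTransform` or NULL.
#' @return the spot table with physical reference-frame coordinates.
#' @export
register_spots <- function(spots, stack, transform = NULL) {
  xy <- cbind(spots$x, spots$y)
  if (!is.null(transform)) xy <- apply_transform(xy, transform)
  spots$x_nm <- xy[, 1] * stack$voxel_size_xy
  spots$y_nm <- xy[, 2] * stack$voxel_size_xy
  spots$z_nm <- spots$z * stack$voxel_size_z
  spots
}
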