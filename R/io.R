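#' Region-of-interest polygons
#'
#' ROIs are simple polygons drawn on the 2D projection of a section (for
#' example around the neural tube or a somite), in 0-based pixel coordinates
#' `(x, y)`. They are stored as JSON: a list of objects with `label`,
#' `section_id` and a `vertices` array of `[x, y]` pairs. ImageJ's binary
#' `.roi` dialect is not read; convert upstream.
#'
#' @param label region name, e.g. `"neural_tube"`.
#' @param vertices numeric matrix with columns x, y; at least 3 rows.
#' @param section_id identifier of the section the ROI belongs to.
#' @return an object of class `RoiPolygon`.
#' @export
roi_polygon <- function(label, vertices, section_id = NA_character_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("an ROI needs >= 3 (x, y) vertices")
  if (anyNA(vertices)) stop("ROI vertices must be finite")
  structure(list(label = as.character(label),
                 vertices = unname(vertices),
                 section_id = as.character(section_id)),
            class = "RoiPolygon")
}

#' @rdname roi_polygon
#' @param rois list of `RoiPolygon` objects (a single one is accepted).
#' @param path JSON file path.
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "RoiPolygon")) rois <- list(rois)
  out <- lapply(rois, function(r)
    list(label = r$label, section_id = r$section_id,
         vertices = apply(r$vertices, 1, function(v) c(v[1], v[2]),
                          simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname roi_polygon
#' @export
read_roi <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, function(p) c(p[[1]], p[[2]])))
    roi_polygon(r$label, v, r$section_id %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spot_columns <- c("channel", "z", "y", "x", "amplitude", "sigma_xy",
                   "sigma_z", "background", "residual", "accepted", "reason",
                   "z_nm", "y_nm", "x_nm", "section_id", "in_roi")

#' Read and write spot tables
#'
#' Spot tables are plain CSV files with a fixed, versioned column schema
#' (one row per fitted spot). Coordinates `z, y, x` are 0-based sub-voxel
#' positions; `z_nm, y_nm, x_nm` are physical reference-frame coordinates
#' present only after registration.
#'
#' @param spots data.frame of fitted spots.
#' @param path CSV path.
#' @return `read_spots` returns the data.frame; round-trips are lossless at
#'   the declared precision (15 significant digits).
#' @export
write_spots <- function(spots, path) {
  missing <- setdiff(.spot_columns, names(spots))
  for (m in missing) spots[[m]] <- NA
  utils::write.csv(format(spots[.spot_columns], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.spot_columns, names(df))
  if (length(missing))
    stop("spot table missing columns: ", paste(missing, collapse = ", "))
  num <- setdiff(.spot_columns, c("channel", "reason", "section_id",
                                  "accepted", "in_roi"))
  for (n in num) df[[n]] <- as.numeric(df[[n]])
  df$accepted <- as.logical(df$accepted)
  df$in_roi <- as.logical(df$in_roi)
  df
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Ray-casting test with an explicit on-edge check; points lying exactly on
#' a polygon edge or vertex count as inside, the convention used when
#' assigning spots to hand-drawn ROIs.
#'
#' @param px,py point coordinates (vectors).
#' @param vertices polygon vertex matrix, columns x, y.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  jx <- vx[c(n, seq_len(n - 1))]; jy <- vy[c(n, seq_len(n - 1))]
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    # boundary check: point on segment?
    for (i in seq_len(n)) {
      ax <- vx[i]; ay <- vy[i]; bx <- jx[i]; by <- jy[i]
      cross <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
      if (abs(cross) < 1e-9 &&
          x >= min(ax, bx) - 1e-9 && x <= max(ax, bx) + 1e-9 &&
          y >= min(ay, by) - 1e-9 && y <= max(ay, by) + 1e-9)
        return(TRUE)
    }
    inside <- FALSE
    for (i in seq_len(n)) {
      ax <- vx[i]; ay <- vy[i]; bx <- jx[i]; by <- jy[i]
      if ((ay > y) != (by > y)) {
        xint <- ax + (y - ay) / (by - ay) * (bx - ax)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Restrict a spot table to an ROI
#'
#' Keeps the spots whose 2D projected center `(x, y)` falls inside the ROI
#' polygon (boundary counts as inside) and sets their `in_roi` flag.
#'
#' @param spots spot table with `x`, `y` columns (pixel frame of the ROI).
#' @param roi an `RoiPolygon`.
#' @return the retained rows, with `in_roi = TRUE`.
#' @export
filter_spots_by_roi <- function(spots, roi) {
  stopifnot(inherits(roi, "RoiPolygon"))
  if (!is.na(roi$section_id) && "section_id" %in% names(spots)) {
    sid <- unique(stats::na.omit(spots$section_id))
    if (length(sid) && !all(sid == roi$section_id))
      stop("section frame mismatch: spots from '", paste(sid, collapse = ","),
           "', ROI for '", roi$section_id, "'")
  }
  keep <- point_in_polygon(spots$x, spots$y, roi$vertices)
  out <- spots[keep, , drop = FALSE]
  if (nrow(out)) out$in_roi <- TRUE
  out
}

#' Pipeline configuration
#'
#' A single YAML file carries every numeric parameter of the pipeline, with
#' the published processing chain's values as defaults: 1 px blur sigma,
#' 15 px rolling-ball radius, 20 px / 6 slice mask spheroid, 5% stop rule,
#' 20x20x6 fit window with a 2 px / 2 slice center constraint, 3.9 um
#' search square, 500 nm co-localization radius, 3 um nuclear radius,
#' 0-1 um distance gate. The in-plane pixel size is an instrument property
#' and must be reviewed per dataset (default 110 nm/px).
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    voxel_size_xy = 110, voxel_size_z = 1000,
    detection = list(blur_sigma = 1, rolling_ball_radius = 15,
                     mask_diameter_xy = 20, mask_depth_z = 6,
                     stop_fraction = 0.05, fit_window_xy = 20,
                     fit_window_z = 6, center_constraint_xy = 2,
                     center_constraint_z = 2, seg_threshold = 0.2,
                     size_min = 2, size_max = 1000,
                     sigma_xy_bounds = c(0.5, 5), sigma_z_bounds = c(0.5, 3)),
    registration = list(reference_channel = "far_red", pairing_radius = 5),
    colocalization = list(search_halfwidth = 1950, coloc_radius = 500,
                          nuclear_radius = 3000, distance_frame = "2d",
                          triple_rule = "clique"),
    distance = list(gate = c(0, 1000), bin_width = 25, n_boot = 1000)
  )
}

#' @rdname default_config
#' @param config named list (as from `default_config`).
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
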