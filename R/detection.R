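#' Preprocess a channel volume for peak finding
#'
#' Per-slice Gaussian blur (sigma = `blur_sigma`, default 1 px) followed by
#' per-slice rolling-ball background subtraction (ball radius
#' `rolling_ball_radius`, default 15 px). The rolling ball is a grayscale
#' opening with a non-flat ball structuring element; because the opening is
#' a lower envelope, subtracting it removes any additive constant offset
#' exactly and the output is non-negative.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param params detection parameter list (see [default_config()]
#'   `$detection`).
#' @return filtered volume, same shape.
#' @export
preprocess_channel <- function(volume, params = default_config()$detection) {
  d <- dim(volume)
  if (length(d) != 3) stop("expected a 3D (z, y, x) volume")
  if (min(d[2], d[3]) < 2 * params$rolling_ball_radius + 1)
    stop("volume smaller in xy than the rolling-ball diameter (",
         2 * params$rolling_ball_radius + 1, " px)")
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    sl <- cpp_gauss_blur(matrix(volume[z, , ], d[2], d[3]), params$blur_sigma)
    bg <- cpp_ball_background(sl, params$rolling_ball_radius)
    out[z, , ] <- pmax(sl - bg, 0)
  }
  out
}

.ellipsoid_offsets <- function(diameter_xy, depth_z) {
  rx <- diameter_xy / 2; rz <- depth_z / 2
  ix <- -floor(rx):floor(rx); iz <- -floor(rz):floor(rz)
  g <- expand.grid(dz = iz, dy = ix, dx = ix)
  keep <- (g$dx^2 + g$dy^2) / rx^2 + g$dz^2 / rz^2 <= 1
  as.matrix(g[keep, c("dz", "dy", "dx")])
}

#' Greedy "max not mask" peak finding
#'
#' Repeatedly takes the brightest remaining voxel as a candidate and masks a
#' surrounding spheroid (diameter `mask_diameter_xy` px in xy,
#' `mask_depth_z` slices in z) with zeros, until no voxel remains above
#' `stop_fraction` (default 5%) of the original volume maximum. Candidates
#' come back in strictly decreasing seed-intensity order. Exact intensity
#' ties are broken toward the lowest `(z, y, x)` index for determinism.
#'
#' @param volume preprocessed 3D volume `(z, y, x)`.
#' @param params detection parameter list.
#' @return data.frame with 0-based integer seed coordinates `z, y, x` and
#'   `intensity`; zero rows for an all-zero volume.
#' @export
find_peaks_max_not_mask <- function(volume,
                                    params = default_config()$detection) {
  d <- dim(volume)
  v <- volume
  thr <- params$stop_fraction * max(v)
  off <- .ellipsoid_offsets(params$mask_diameter_xy, params$mask_depth_z)
  res <- list()
  repeat {
    mx <- max(v)
    if (mx <= 0 || mx < thr) break
    idx <- which(v == mx)
    co <- arrayInd(idx, d)               # (z, y, x), 1-based
    o <- order(co[, 1], co[, 2], co[, 3])[1]
    z <- co[o, 1]; y <- co[o, 2]; x <- co[o, 3]
    res[[length(res) + 1L]] <- c(z - 1L, y - 1L, x - 1L, mx)
    mz <- z + off[, 1]; my <- y + off[, 2]; mx2 <- x + off[, 3]
    ok <- mz >= 1 & mz <= d[1] & my >= 1 & my <= d[2] & mx2 >= 1 & mx2 <= d[3]
    v[cbind(mz[ok], my[ok], mx2[ok])] <- 0
  }
  if (!length(res))
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric()))
  m <- do.call(rbind, res)
  data.frame(z = as.integer(m[, 1]), y = as.integer(m[, 2]),
             x = as.integer(m[, 3]), intensity = m[, 4])
}

.window_offsets <- function(n) {
  h <- (n - 1L) %/% 2L
  (-h):(n - 1L - h)
}

#' Constrained 3D Gaussian refinement of a candidate peak
#'
#' Nonlinear least-squares fit of
#' `background + amplitude * G(center; sigma_xy, sigma_xy, sigma_z)` to a
#' `fit_window_xy` x `fit_window_xy` x `fit_window_z` voxel window around
#' the candidate (defaults 20 x 20 px, 6 slices), on the *raw* channel data.
#' The fitted center is constrained to `center_constraint_xy` px in xy and
#' `center_constraint_z` slices in z of the seed; a fit pinned at that
#' boundary, a non-converging fit, or a window extending outside the volume
#' marks the spot rejected with a reason (`"constraint"`, `"fit"`,
#' `"edge"`). Sigma bounds (defaults 0.5-5 px in xy, 0.5-3 slices in z)
#' exclude pure-noise fits.
#'
#' @param volume raw 3D channel volume `(z, y, x)`.
#' @param candidate list/row with 0-based integer `z, y, x` seed.
#' @param params detection parameter list.
#' @return one-row data.frame (spot-table schema, pixel coordinates).
#' @export
refine_gaussian3d <- function(volume, candidate,
                              params = default_config()$detection) {
  d <- dim(volume)
  z0 <- candidate$z; y0 <- candidate$y; x0 <- candidate$x   # 0-based ints
  ox <- .window_offsets(params$fit_window_xy)
  oz <- .window_offsets(params$fit_window_z)
  zi <- z0 + oz + 1L; yi <- y0 + ox + 1L; xi <- x0 + ox + 1L  # 1-based
  row <- data.frame(channel = NA_character_, z = NA_real_, y = NA_real_,
                    x = NA_real_, amplitude = NA_real_, sigma_xy = NA_real_,
                    sigma_z = NA_real_, background = NA_real_,
                    residual = NA_real_, accepted = FALSE,
                    reason = NA_character_, z_nm = NA_real_, y_nm = NA_real_,
                    x_nm = NA_real_, section_id = NA_character_,
                    in_roi = NA)
  if (min(zi, yi, xi) < 1 || max(zi) > d[1] || max(yi) > d[2] ||
      max(xi) > d[3]) {
    row$reason <- "edge"
    row$z <- z0; row$y <- y0; row$x <- x0
    return(row)
  }
  win <- volume[zi, yi, xi]
  if (anyNA(win) || any(!is.finite(win)))
    stop("non-finite voxels in fit window")
  grid <- expand.grid(z = z0 + oz, y = y0 + ox, x = x0 + ox)
  vals <- as.vector(win)
  bg0 <- min(vals)
  a0 <- max(vals) - bg0
  df <- data.frame(v = vals, z = grid$z, y = grid$y, x = grid$x)
  cxy <- params$center_constraint_xy; cz <- params$center_constraint_z
  sxyb <- params$sigma_xy_bounds %||% c(0.5, 5)
  szb <- params$sigma_z_bounds %||% c(0.5, 3)
  lower <- c(A = 0, x0 = x0 - cxy, y0 = y0 - cxy, z0 = z0 - cz,
             sxy = sxyb[1], sz = szb[1], bg = -Inf)
  upper <- c(A = Inf, x0 = x0 + cxy, y0 = y0 + cxy, z0 = z0 + cz,
             sxy = sxyb[2], sz = szb[2], bg = Inf)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ bg + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sxy^2) -
                         (z - z0)^2 / (2 * sz^2)),
      data = df,
      start = list(A = max(a0, 1e-6), x0 = x0, y0 = y0, z0 = z0,
                   sxy = 1.5, sz = 1.0, bg = bg0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    row$reason <- "fit"
    row$z <- z0; row$y <- y0; row$x <- x0
    return(row)
  }
  p <- stats::coef(fit)
  row$z <- p[["z0"]]; row$y <- p[["y0"]]; row$x <- p[["x0"]]
  row$amplitude <- p[["A"]]; row$sigma_xy <- p[["sxy"]]
  row$sigma_z <- p[["sz"]]; row$background <- p[["bg"]]
  row$residual <- sqrt(mean(stats::resid(fit)^2))
  eps <- 1e-6
  pinned <- abs(p[["x0"]] - x0) > cxy - eps ||
    abs(p[["y0"]] - y0) > cxy - eps || abs(p[["z0"]] - z0) > cz - eps
  if (pinned) {
    row$reason <- "constraint"
  } else if (p[["A"]] <= 0) {
    row$reason <- "fit"
  } else {
    row$accepted <- TRUE
  }
  row
}

#' Detect and refine spots in one channel
#'
#' The full peak pipeline for one probe channel: preprocess (blur +
#' rolling ball), greedy max-not-mask candidate search, then constrained 3D
#' Gaussian refinement of every candidate on the raw volume. The 5% stop
#' rule is applied on the preprocessed volume (the object being searched).
#'
#' @param stack an `ImageStack`.
#' @param channel channel label.
#' @param params detection parameter list.
#' @param preprocess set FALSE if `stack` already holds filtered data.
#' @return spot table (one row per candidate, `accepted` flag set).
#' @export
detect_spots <- function(stack, channel,
                         params = default_config()$detection,
                         preprocess = TRUE) {
  vol <- get_channel(stack, channel)
  filt <- if (preprocess) preprocess_channel(vol, params) else vol
  cands <- find_peaks_max_not_mask(filt, params)
  if (!nrow(cands)) {
    out <- refine_gaussian3d(vol, list(z = 0L, y = 0L, x = 0L), params)[0, ]
    return(out)
  }
  rows <- lapply(seq_len(nrow(cands)), function(i)
    refine_gaussian3d(vol, cands[i, ], params))
  out <- do.call(rbind, rows)
  out$channel <- channel
  out
}

#' Threshold-and-segment spot detection (projected 2D centroids)
#'
#' Classical stand-in for a learned per-voxel classifier, with the same
#' downstream contract: the volume is thresholded at `seg_threshold` x its
#' maximum, 3D 6-connected components are extracted, components outside
#' `[size_min, size_max]` voxels are removed (two spots merging into one
#' oversized component are dropped — a documented failure mode, not an
#' error), and survivors are projected to 2D and refined to sub-pixel
#' centers by a 2D Gaussian fit on the local sum projection.
#'
#' @param volume preprocessed 3D volume `(z, y, x)`.
#' @param params detection parameter list.
#' @return data.frame with 0-based `x`, `y` centers, `size` (voxels),
#'   `amplitude`, `score` (component peak intensity over volume maximum).
#' @export
segment_spots <- function(volume, params = default_config()$detection) {
  d <- dim(volume)
  vmax <- max(volume)
  mask <- volume >= params$seg_threshold * vmax & volume > 0
  lab <- cpp_label_components(as.logical(mask), as.integer(d))
  if (!any(lab > 0))
    return(data.frame(x = numeric(), y = numeric(), size = integer(),
                      amplitude = numeric(), score = numeric()))
  tab <- tabulate(lab)
  keep <- which(tab >= params$size_min & tab <= params$size_max)
  if (!length(keep))
    return(data.frame(x = numeric(), y = numeric(), size = integer(),
                      amplitude = numeric(), score = numeric()))
  rows <- lapply(keep, function(k) {
    idx <- which(lab == k)
    co <- arrayInd(idx, d)
    w <- volume[idx]
    cy <- sum((co[, 2] - 1) * w) / sum(w)
    cx <- sum((co[, 3] - 1) * w) / sum(w)
    fit <- .refine_gaussian2d(volume, cx, cy, params)
    data.frame(x = fit$x, y = fit$y, size = length(idx),
               amplitude = fit$amplitude, score = max(w) / vmax)
  })
  do.call(rbind, rows)
}

# 2D Gaussian refinement of a projected centroid on the sum projection.
.refine_gaussian2d <- function(volume, cx, cy, params) {
  d <- dim(volume)
  proj <- apply(volume, c(2, 3), sum)
  ox <- .window_offsets(min(params$fit_window_xy, 11L))
  xi <- round(cx) + ox + 1L; yi <- round(cy) + ox + 1L
  xi <- xi[xi >= 1 & xi <= d[3]]; yi <- yi[yi >= 1 & yi <= d[2]]
  win <- proj[yi, xi, drop = FALSE]
  g <- expand.grid(y = yi - 1, x = xi - 1)
  df <- data.frame(v = as.vector(win), x = g$x, y = g$y)
  bg0 <- min(df$v); a0 <- max(df$v) - bg0
  cxy <- params$center_constraint_xy
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ bg + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = df,
      start = list(A = max(a0, 1e-6), x0 = cx, y0 = cy, s = 1.5, bg = bg0),
      lower = c(A = 0, x0 = cx - cxy, y0 = cy - cxy, s = 0.5, bg = -Inf),
      upper = c(A = Inf, x0 = cx + cxy, y0 = cy + cxy, s = 10, bg = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(x = cx, y = cy, amplitude = NA_real_))
  p <- stats::coef(fit)
  list(x = p[["x0"]], y = p[["y0"]], amplitude = p[["A"]])
}
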