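#' 2D amplitude-distance histogram for cross-channel spot pairs
#'
#' Bins pair distances against a relative spot amplitude (the geometric
#' mean of the two members' fitted amplitudes, normalized by its median
#' over pairs — the "peak reference" axis). Counts are conserved: the
#' histogram total equals the number of pairs.
#'
#' @param distances_nm pair center distances (nm).
#' @param amplitudes pair amplitude values (same length); NULL for a
#'   distance-only histogram.
#' @param dist_breaks,amp_breaks bin edges (defaults: 25 nm bins over the
#'   observed range; 20 amplitude bins).
#' @return list of class `DistHist2D` with `counts`, `dist_breaks`,
#'   `amp_breaks`, `n`.
#' @export
build_histogram <- function(distances_nm, amplitudes = NULL,
                            dist_breaks = NULL, amp_breaks = NULL) {
  n <- length(distances_nm)
  if (n && is.null(dist_breaks))
    dist_breaks <- seq(0, max(distances_nm) + 25, by = 25)
  if (is.null(dist_breaks)) dist_breaks <- c(0, 25)
  if (is.null(amplitudes)) amplitudes <- rep(1, n)
  if (n && is.null(amp_breaks)) {
    rng <- range(amplitudes)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    amp_breaks <- seq(rng[1], rng[2], length.out = 21)
  }
  if (is.null(amp_breaks)) amp_breaks <- 0:1
  di <- cut(distances_nm, dist_breaks, include.lowest = TRUE)
  ai <- cut(amplitudes, amp_breaks, include.lowest = TRUE)
  counts <- table(ai, di)
  structure(list(counts = unclass(counts), dist_breaks = dist_breaks,
                 amp_breaks = amp_breaks, n = n),
            class = "DistHist2D")
}

#' Fit a 1D Gaussian to the gated distance histogram
#'
#' Distances are gated to `gate` (0-1 um by default), binned (25 nm bins by
#' default), and the binned counts are fit to a one-dimensional Gaussian by
#' nonlinear least squares; the fitted mean is the peak separation. The
#' standard error is obtained by bootstrap over pairs (default 1000
#' resamples, seeded, refitting each resample). With fewer than 10 gated
#' distances the median is reported with a warning instead of a fit; if the
#' fit fails to converge the histogram mode is returned and flagged.
#'
#' @param distances_nm pair distances in nm.
#' @param gate `c(lo, hi)` nm; values outside are discarded (re-gating
#'   already gated data is a no-op).
#' @param bin_width histogram bin width, nm.
#' @param n_boot bootstrap resamples for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `DistancePeakFit`: `peak`, `width` (fitted sigma),
#'   `se`, `n`, `method` (`"gaussian"`, `"mode"` or `"median"`), `gate`,
#'   `hist` (gated 1D counts and mids).
#' @export
fit_distance_peak <- function(distances_nm, gate = c(0, 1000),
                              bin_width = 25, n_boot = 1000, seed = 1L) {
  d <- distances_nm[distances_nm >= gate[1] & distances_nm <= gate[2]]
  n <- length(d)
  breaks <- seq(gate[1], gate[2] + bin_width, by = bin_width)
  mk_hist <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(mids = h$mids, counts = h$counts)
  }
  fit1 <- function(x) {
    if (length(unique(x)) == 1) return(list(peak = x[1], width = 0,
                                            method = "gaussian"))
    h <- mk_hist(x)
    df <- data.frame(v = h$counts, m = h$mids)
    mu0 <- h$mids[which.max(h$counts)]
    s0 <- max(stats::sd(x), bin_width / 2)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(v ~ A * exp(-(m - mu)^2 / (2 * s^2)), data = df,
                          start = list(A = max(h$counts), mu = mu0, s = s0),
                          lower = c(A = 0, mu = gate[1], s = bin_width / 10),
                          upper = c(A = Inf, mu = gate[2], s = diff(gate)),
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(peak = mu0, width = NA_real_, method = "mode"))
    p <- stats::coef(fit)
    list(peak = p[["mu"]], width = p[["s"]], method = "gaussian")
  }
  if (n == 0) stop("no distances inside the gate")
  if (n < 10) {
    warning("fewer than 10 gated distances: reporting the median")
    return(structure(list(peak = stats::median(d), width = NA_real_,
                          se = NA_real_, n = n, method = "median",
                          gate = gate, hist = mk_hist(d)),
                     class = "DistancePeakFit"))
  }
  main <- fit1(d)
  set.seed(seed)
  if (length(unique(d)) == 1) {
    se <- 0
  } else {
    boots <- vapply(seq_len(n_boot), function(b) {
      fit1(d[sample.int(n, n, replace = TRUE)])$peak
    }, numeric(1))
    se <- stats::sd(boots)
  }
  structure(list(peak = main$peak, width = main$width, se = se, n = n,
                 method = main$method, gate = gate, hist = mk_hist(d)),
            class = "DistancePeakFit")
}

#' @export
print.DistancePeakFit <- function(x, ...) {
  cat(sprintf("Distance peak: %.1f nm (width %.1f nm, bootstrap SE %.2f nm, n = %d, %s fit)\n",
              x$peak, x$width, x$se, x$n, x$method))
  invisible(x)
}

#' Plot a gated distance histogram with its Gaussian fit
#'
#' @param x a `DistancePeakFit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.DistancePeakFit <- function(x, ...) {
  graphics::plot(x$hist$mids, x$hist$counts, type = "h", lwd = 3,
                 col = "grey60", xlab = "distance (nm)",
                 ylab = "pairs", ...)
  if (x$method == "gaussian" && !is.na(x$width) && x$width > 0) {
    xs <- seq(x$gate[1], x$gate[2], length.out = 200)
    A <- max(x$hist$counts)
    graphics::lines(xs, A * exp(-(xs - x$peak)^2 / (2 * x$width^2)),
                    col = "firebrick", lwd = 2)
  }
  graphics::abline(v = x$peak, lty = 2)
  invisible(x)
}

#' Pairwise inter-locus distance report (with triangle summary)
#'
#' For every channel pair, collects the center distances of co-localized
#' spots (3D physical frame from the constrained 3D fits by default),
#' builds the amplitude-distance histogram, gates 0-1 um and fits the 1D
#' Gaussian peak with bootstrap SE. In triangle mode (3 channels) only
#' records where all three loci are active (triples) contribute, and the
#' three peaks are arranged as a triangle with the first channel anchored
#' at 0.
#'
#' @param coloc a `ColocResult` built from 3D-registered spot tables.
#' @param params a `ColocParams` (frame used for the reported distances).
#' @param gate,bin_width,n_boot,seed passed to [fit_distance_peak()].
#' @param triangle if TRUE restrict to triples and add triangle vertex
#'   coordinates (requires 3 channels).
#' @return list of class `DistanceReport`: per-pair list with `distances`,
#'   `hist2d` (`DistHist2D`), `fit` (`DistancePeakFit`); plus `triangle`
#'   (vertex coordinates, nm) when requested.
#' @export
pairwise_peak_report <- function(coloc, params = coloc_params(distance_frame = "3d"),
                                 gate = c(0, 1000), bin_width = 25,
                                 n_boot = 1000, seed = 1L, triangle = FALSE) {
  stopifnot(inherits(coloc, "ColocResult"))
  chs <- coloc$summary$channel
  if (triangle && length(chs) < 3)
    stop("triangle mode needs 3 channels")
  mem <- coloc$members
  recs <- coloc$records
  use <- if (triangle) recs$record_id[recs$n_members == 3] else
    recs$record_id[recs$n_members > 1]
  mem <- mem[mem$record_id %in% use, , drop = FALSE]
  pairs <- utils::combn(chs, 2, simplify = FALSE)
  out <- list()
  for (cc in pairs) {
    da <- mem[mem$channel == cc[1], ]; db <- mem[mem$channel == cc[2], ]
    common <- intersect(da$record_id, db$record_id)
    ia <- match(common, da$record_id); ib <- match(common, db$record_id)
    dx <- da$x_nm[ia] - db$x_nm[ib]; dy <- da$y_nm[ia] - db$y_nm[ib]
    dz <- da$z_nm[ia] - db$z_nm[ib]
    dist <- if (params$distance_frame == "3d")
      sqrt(dx^2 + dy^2 + dz^2) else sqrt(dx^2 + dy^2)
    amp <- sqrt(pmax(da$amplitude[ia], 0) * pmax(db$amplitude[ib], 0))
    amp <- if (length(amp) && any(amp > 0)) amp / stats::median(amp[amp > 0])
      else amp
    nm <- paste(cc, collapse = "+")
    out[[nm]] <- list(
      channels = cc, distances = dist, n = length(dist),
      hist2d = build_histogram(dist, amp),
      fit = if (length(dist)) fit_distance_peak(dist, gate, bin_width,
                                                n_boot, seed) else NULL)
  }
  res <- list(pairs = out, channels = chs, triangle = NULL)
  if (triangle) {
    p12 <- out[[paste(chs[1:2], collapse = "+")]]$fit$peak
    p13 <- out[[paste(chs[c(1, 3)], collapse = "+")]]$fit$peak
    p23 <- out[[paste(chs[2:3], collapse = "+")]]$fit$peak
    # anchor channel 1 at the origin, channel 2 on the x axis
    cosg <- (p12^2 + p13^2 - p23^2) / (2 * p12 * p13)
    cosg <- min(1, max(-1, cosg))
    res$triangle <- data.frame(
      channel = chs,
      x = c(0, p12, p13 * cosg),
      y = c(0, 0, p13 * sqrt(max(0, 1 - cosg^2))))
  }
  structure(res, class = "DistanceReport")
}

#' @export
print.DistanceReport <- function(x, ...) {
  cat("Inter-locus distance report\n")
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    if (is.null(p$fit)) {
      cat(sprintf("  %-22s no pairs\n", nm))
    } else {
      cat(sprintf("  %-22s peak %.1f nm +/- %.2f (n = %d)\n", nm,
                  p$fit$peak, p$fit$se, p$n))
    }
  }
  if (!is.null(x$triangle)) {
    cat("  triangle vertices (nm):\n")
    print(x$triangle, row.names = FALSE)
  }
  invisible(x)
}

#' Triangle plot of pairwise peak distances
#'
#' @param report a `DistanceReport` produced with `triangle = TRUE`.
#' @export
plot_triangle <- function(report) {
  stopifnot(inherits(report, "DistanceReport"), !is.null(report$triangle))
  t <- report$triangle
  graphics::plot(t$x, t$y, asp = 1, pch = 19, xlab = "nm", ylab = "nm",
                 xlim = range(t$x) + c(-50, 50),
                 ylim = range(t$y) + c(-50, 50))
  graphics::polygon(t$x, t$y, border = "grey40")
  graphics::text(t$x, t$y, t$channel, pos = 3)
  invisible(report)
}
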