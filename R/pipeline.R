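#' Analyze one section stack end to end
#'
#' Wires the stages for a single multi-channel section: detect and refine
#' spots in every probe channel, register them into the physical reference
#' frame (applying per-channel chromatic transforms when supplied),
#' classify cross-channel co-occurrence, estimate the cell count from the
#' DAPI sum projection, and summarize per-cell rates.
#'
#' @param stack `ImageStack` containing the probe channels and a DAPI
#'   channel.
#' @param probe_channels labels of the probe channels to quantify.
#' @param dapi_channel DAPI channel label.
#' @param transforms named list of `ChannelTransform` (missing channel =
#'   identity).
#' @param detection detection parameter list.
#' @param coloc a `ColocParams`.
#' @param reference_intensity,n_reference DAPI cell-count reference (see
#'   [estimate_cell_count()]).
#' @param dapi_background per-pixel background of the DAPI sum projection
#'   (median of a declared nucleus-free region).
#' @param roi optional `RoiPolygon` restricting spots and DAPI integration.
#' @param section_id,genotype metadata labels.
#' @return list with `spots` (per-channel registered accepted spot tables),
#'   `coloc` (`ColocResult`), `cells` (`CellCountEstimate`), `summary`
#'   (`SectionSummary`).
#' @export
analyze_section <- function(stack, probe_channels, dapi_channel = "dapi",
                            transforms = list(),
                            detection = default_config()$detection,
                            coloc = coloc_params(),
                            reference_intensity, n_reference,
                            dapi_background = 0,
                            roi = NULL, section_id = NA_character_,
                            genotype = NA_character_) {
  stopifnot(inherits(stack, "ImageStack"))
  spots <- list()
  for (ch in probe_channels) {
    s <- detect_spots(stack, ch, detection)
    s <- s[s$accepted, , drop = FALSE]
    s$section_id <- section_id
    if (!is.null(roi) && nrow(s)) s <- filter_spots_by_roi(s, roi)
    spots[[ch]] <- register_spots(s, stack, transforms[[ch]])
  }
  cres <- classify_cooccurrence(spots, coloc)
  dapi_sum <- apply(get_channel(stack, dapi_channel), c(2, 3), sum)
  cells <- estimate_cell_count(dapi_sum, roi, reference_intensity,
                               n_reference, background = dapi_background)
  summ <- summarize_section(spots, cres, cells, section_id = section_id,
                            genotype = genotype)
  list(spots = spots, coloc = cres, cells = cells, summary = summ)
}

#' Match detected spots to ground truth and score detection quality
#'
#' Greedy nearest-first matching of accepted detections to true spot
#' positions within `match_radius_px` (in-plane), then recall, precision,
#' F1 and the localization RMSE over matched spots.
#'
#' @param detected spot table with 0-based `x, y, z` pixel coordinates.
#' @param truth_px matrix/data.frame of true 0-based `z, y, x` pixel
#'   positions.
#' @param match_radius_px maximum in-plane match distance (default 2).
#' @return list `recall`, `precision`, `f1`, `rmse_xy_px`, `rmse_z_px`,
#'   `n_matched`, `matches` (index pairs).
#' @export
evaluate_detection <- function(detected, truth_px, match_radius_px = 2) {
  truth_px <- as.data.frame(truth_px)
  nd <- nrow(detected); nt <- nrow(truth_px)
  if (nd == 0 || nt == 0)
    return(list(recall = 0, precision = if (nd == 0) NA_real_ else 0,
                f1 = 0, rmse_xy_px = NA_real_, rmse_z_px = NA_real_,
                n_matched = 0, matches = NULL))
  dxy <- sqrt(outer(detected$x, truth_px$x, "-")^2 +
                outer(detected$y, truth_px$y, "-")^2)
  pairs <- which(dxy <= match_radius_px, arr.ind = TRUE)
  ord <- order(dxy[pairs])
  used_d <- logical(nd); used_t <- logical(nt)
  matches <- list()
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    matches[[length(matches) + 1L]] <- c(i, j)
  }
  m <- if (length(matches)) do.call(rbind, matches) else
    matrix(integer(), 0, 2)
  nm <- nrow(m)
  recall <- nm / nt; precision <- nm / nd
  f1 <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  rmse_xy <- if (nm) sqrt(mean((detected$x[m[, 1]] - truth_px$x[m[, 2]])^2 +
                                 (detected$y[m[, 1]] - truth_px$y[m[, 2]])^2))
    else NA_real_
  rmse_z <- if (nm) sqrt(mean((detected$z[m[, 1]] - truth_px$z[m[, 2]])^2))
    else NA_real_
  list(recall = recall, precision = precision, f1 = f1,
       rmse_xy_px = rmse_xy, rmse_z_px = rmse_z, n_matched = nm,
       matches = m)
}
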