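#' Estimate the number of cells in an ROI from integrated DAPI intensity
#'
#' In dense neural-tube tissue individual nuclei cannot be segmented
#' reliably, so cell numbers are estimated by intensity ratio: the
#' background-subtracted integrated DAPI intensity of the ROI (on the sum
#' projection) divided by a per-nucleus reference intensity measured in a
#' sparse region where nuclei can be counted by eye. The estimate is kept
#' real-valued — it divides spot counts, and rounding would bias the rates.
#'
#' @param dapi_sum 2D matrix, the z-sum projection of the DAPI channel
#'   (`(y, x)` pixel order).
#' @param roi `RoiPolygon`, or NULL for the whole field.
#' @param reference_intensity integrated DAPI intensity of the reference
#'   region (same projection, background subtracted).
#' @param n_reference number of nuclei counted in the reference region
#'   (> 0).
#' @param background per-pixel background level, subtracted before
#'   integration (e.g. the median of a declared nucleus-free region;
#'   default 0).
#' @return list of class `CellCountEstimate` with `count`,
#'   `integrated_intensity`, `reference_per_nucleus`.
#' @export
estimate_cell_count <- function(dapi_sum, roi = NULL, reference_intensity,
                                n_reference, background = 0) {
  if (n_reference <= 0) stop("reference nucleus count must be positive")
  if (reference_intensity <= 0) stop("reference intensity must be positive")
  d <- dim(dapi_sum)
  if (is.null(roi)) {
    inside <- matrix(TRUE, d[1], d[2])
  } else {
    stopifnot(inherits(roi, "RoiPolygon"))
    v <- roi$vertices
    if (min(v[, 1]) > d[2] - 1 || max(v[, 1]) < 0 ||
        min(v[, 2]) > d[1] - 1 || max(v[, 2]) < 0)
      stop("ROI lies outside the image")
    g <- expand.grid(y = 0:(d[1] - 1), x = 0:(d[2] - 1))
    inside <- matrix(point_in_polygon(g$x, g$y, v), d[1], d[2])
  }
  integ <- sum(dapi_sum[inside]) - background * sum(inside)
  integ <- max(integ, 0)
  ref <- reference_intensity / n_reference
  structure(list(count = integ / ref, integrated_intensity = integ,
                 reference_per_nucleus = ref, n_reference = n_reference,
                 roi_label = if (is.null(roi)) "full_field" else roi$label),
            class = "CellCountEstimate")
}

#' @export
print.CellCountEstimate <- function(x, ...) {
  cat(sprintf("CellCountEstimate [%s]: %.2f cells (%.4g counts / %.4g per ",
              x$roi_label, x$count, x$integrated_intensity,
              x$reference_per_nucleus), "nucleus)\n", sep = "")
  invisible(x)
}

#' Per-section summary: spots per cell and co-occurrence classes
#'
#' Collapses one section's detections into per-cell rates: accepted spot
#' count per transcript divided by the DAPI-based cell count, plus
#' per-class co-occurrence counts (per cell). A channel absent from
#' `spot_tables` is reported as not measured (`NA`), never as zero;
#' zero detected spots is a valid measurement distinct from not-measured.
#'
#' @param spot_tables named list of accepted spot tables (one per
#'   transcript).
#' @param coloc a `ColocResult` for the same section (or NULL).
#' @param cell_count a `CellCountEstimate` or a positive number.
#' @param section_id,genotype,region metadata labels.
#' @param channels optional full transcript panel; panel members missing
#'   from `spot_tables` are marked not-measured.
#' @return one-row-per-transcript data.frame of class `SectionSummary`
#'   with attributes `coloc_per_cell` (per-combination rates) and
#'   `cell_count`.
#' @export
summarize_section <- function(spot_tables, coloc = NULL, cell_count,
                              section_id = NA_character_,
                              genotype = NA_character_,
                              region = NA_character_, channels = NULL) {
  cc <- if (inherits(cell_count, "CellCountEstimate")) cell_count$count else
    as.numeric(cell_count)
  if (is.na(cc) || cc <= 0) stop("cell count must be positive")
  if (is.null(channels)) channels <- names(spot_tables)
  rows <- lapply(channels, function(ch) {
    s <- spot_tables[[ch]]
    n <- if (is.null(s)) NA_integer_ else
      sum(if ("accepted" %in% names(s)) s$accepted else rep(TRUE, nrow(s)))
    data.frame(section_id = section_id, genotype = genotype, region = region,
               transcript = ch, n_spots = n, cell_count = cc,
               spots_per_cell = n / cc, measured = !is.null(s))
  })
  out <- do.call(rbind, rows)
  if (!is.null(coloc)) {
    stopifnot(inherits(coloc, "ColocResult"))
    combos <- coloc$records$combo[coloc$records$n_members > 1]
    cpc <- if (length(combos)) table(combos) / cc else table(character())
    attr(out, "coloc_per_cell") <- cpc
    # conservation: per-channel class memberships sum to totals
    stopifnot(all(coloc$summary$singles + coloc$summary$doubles +
                    coloc$summary$triples == coloc$summary$total))
  }
  attr(out, "cell_count") <- cc
  class(out) <- c("SectionSummary", "data.frame")
  out
}

#' Between-gene abundance ratios per section
#'
#' For each section where both transcripts were measured, the ratio of
#' per-cell rates (equivalently of counts, the cell count cancels) of gene
#' A over gene B. Sections with a zero denominator yield a missing value
#' and are flagged, not silently dropped.
#'
#' @param summaries data.frame of stacked `SectionSummary` rows.
#' @param gene_a,gene_b transcript labels.
#' @return data.frame `section_id, rate_a, rate_b, ratio, excluded`.
#' @export
abundance_ratio <- function(summaries, gene_a, gene_b) {
  a <- summaries[summaries$transcript == gene_a & summaries$measured, ]
  b <- summaries[summaries$transcript == gene_b & summaries$measured, ]
  common <- intersect(a$section_id, b$section_id)
  if (!length(common)) stop("no common sections for ", gene_a, " and ",
                            gene_b)
  ra <- a$spots_per_cell[match(common, a$section_id)]
  rb <- b$spots_per_cell[match(common, b$section_id)]
  ratio <- ifelse(rb > 0, ra / rb, NA_real_)
  excl <- is.na(ratio)
  if (any(excl))
    message(sum(excl), " section(s) excluded from ", gene_a, "/", gene_b,
            " ratio (zero denominator)")
  data.frame(section_id = common, rate_a = ra, rate_b = rb, ratio = ratio,
             excluded = excl)
}
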