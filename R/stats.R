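#' Mann-Whitney rank-sum test between two per-section samples
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test: the exact distribution
#' is enumerated for small tie-free samples (combined n <= 20), otherwise
#' the normal approximation with tie correction is used. A thin, contract-
#' checked wrapper over [stats::wilcox.test()].
#'
#' @param sample_a,sample_b numeric vectors (each n >= 2).
#' @return list with `statistic` (U for sample_a) and `p`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs n >= 2")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && (length(sample_a) + length(sample_b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = !exact,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1),
       exact = exact)
}

#' Variance-ratio F test between two samples
#'
#' Two-sided parametric F test on the sample variances, reported with the
#' larger variance in the numerator so `F >= 1`; the p-value comes from the
#' F distribution with the matching degrees of freedom.
#'
#' @param sample_a,sample_b numeric vectors (each n >= 2, finite variance).
#' @return list with `F`, `df` and `p`.
#' @export
variance_ratio_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs n >= 2")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  if (va >= vb) {
    num <- sample_a; den <- sample_b
  } else {
    num <- sample_b; den <- sample_a
  }
  ft <- stats::var.test(num, den)
  list(F = unname(ft$statistic),
       df = unname(ft$parameter),
       p = min(ft$p.value, 1))
}

#' Significance annotation
#'
#' Maps p-values to the conventional star codes: `ns` for p > 0.05, then
#' `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001).
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[p <= 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Compare per-section measurements between genotypes
#'
#' For every measured transcript, tests each non-reference genotype against
#' the reference with the rank-sum test (location) and the variance-ratio F
#' test (spread), annotating stars at the 0.05 / 0.01 / 0.001 / 0.0001
#' thresholds and a variance star at F-test p < 0.05. Raw p-values are
#' always retained alongside the annotations. No multiple-testing
#' correction is applied by default (per-gene reporting); set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted location p-values in an
#' extra column.
#'
#' @param summaries stacked `SectionSummary` rows (one row per section x
#'   transcript) with `genotype`, `transcript`, and the measurement in
#'   `value_col`.
#' @param reference reference genotype label (e.g. `"wt"`).
#' @param value_col measurement column (default `"spots_per_cell"`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `GroupComparison` with one row per
#'   transcript x genotype.
#' @export
compare_groups <- function(summaries, reference,
                           value_col = "spots_per_cell", adjust = "none") {
  stopifnot(reference %in% summaries$genotype)
  transcripts <- unique(summaries$transcript)
  genos <- setdiff(unique(summaries$genotype), reference)
  rows <- list()
  for (tr in transcripts) {
    ref <- summaries[summaries$transcript == tr &
                       summaries$genotype == reference, value_col]
    ref <- ref[is.finite(ref)]
    for (g in genos) {
      alt <- summaries[summaries$transcript == tr &
                         summaries$genotype == g, value_col]
      alt <- alt[is.finite(alt)]
      if (length(ref) < 2 || length(alt) < 2) next
      rs <- rank_sum_test(alt, ref)
      vt <- variance_ratio_test(alt, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tr, genotype = g, n_ref = length(ref),
        n_alt = length(alt),
        median_ref = stats::median(ref), median_alt = stats::median(alt),
        p_location = rs$p, F_variance = vt$F, p_variance = vt$p)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_location)
  out$variance_star <- out$p_variance < 0.05
  if (identical(adjust, "BH"))
    out$p_location_bh <- stats::p.adjust(out$p_location, "BH")
  class(out) <- c("GroupComparison", "data.frame")
  out
}

#' @export
print.GroupComparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_location <- signif(df$p_location, 3)
  df$p_variance <- signif(df$p_variance, 3)
  df$F_variance <- signif(df$F_variance, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
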