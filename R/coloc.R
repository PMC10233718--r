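#' Co-localization parameters
#'
#' @param search_halfwidth half-side of the square search window around each
#'   spot, nm (default 1950, i.e. a 3.9 x 3.9 um square).
#' @param coloc_radius center-to-center distance below which two spots of
#'   different probes are called co-localized (nm, default 500).
#' @param nuclear_radius nm, used by the random-chance model (default 3000).
#' @param distance_frame `"2d"` (projected centers, the frame used for
#'   co-localization calls) or `"3d"` (used by the distance analysis).
#' @param triple_rule `"clique"` (all three pairwise distances within the
#'   radius; default) or `"chain"` (joining spot need only be within the
#'   radius of one member).
#' @return validated list of class `ColocParams`.
#' @export
coloc_params <- function(search_halfwidth = 1950, coloc_radius = 500,
                         nuclear_radius = 3000,
                         distance_frame = c("2d", "3d"),
                         triple_rule = c("clique", "chain")) {
  distance_frame <- match.arg(distance_frame)
  triple_rule <- match.arg(triple_rule)
  stopifnot(search_halfwidth > 0, coloc_radius > 0, nuclear_radius > 0)
  if (coloc_radius >= 2 * search_halfwidth)
    stop("coloc_radius must be smaller than the search-square side")
  structure(list(search_halfwidth = search_halfwidth,
                 coloc_radius = coloc_radius,
                 nuclear_radius = nuclear_radius,
                 distance_frame = distance_frame,
                 triple_rule = triple_rule),
            class = "ColocParams")
}

.pair_dist <- function(a, i, b, j, frame) {
  dx <- a$x_nm[i] - b$x_nm[j]; dy <- a$y_nm[i] - b$y_nm[j]
  if (frame == "3d") sqrt(dx^2 + dy^2 + (a$z_nm[i] - b$z_nm[j])^2)
  else sqrt(dx^2 + dy^2)
}

.check_registered <- function(spots, who) {
  if (!all(c("x_nm", "y_nm") %in% names(spots)) ||
      (nrow(spots) && anyNA(spots$x_nm)))
    stop(who, " not registered to the reference frame (missing nm ",
         "coordinates); run register_spots() first")
}

#' Cross-channel candidate pairs within the search window
#'
#' All pairs of spots from two channels whose in-plane offsets fit inside a
#' square window of side `2 * search_halfwidth` (3.9 um by default) centred
#' on either spot, with their center distance in nm. The relation is
#' symmetric.
#'
#' @param spots_a,spots_b registered spot tables (columns `x_nm`, `y_nm`,
#'   and `z_nm` for the 3D frame).
#' @param params a `ColocParams`.
#' @return data.frame `i, j, distance_nm` (row indices into the two
#'   tables).
#' @export
pair_candidates <- function(spots_a, spots_b, params = coloc_params()) {
  .check_registered(spots_a, "spots_a"); .check_registered(spots_b, "spots_b")
  if (!nrow(spots_a) || !nrow(spots_b))
    return(data.frame(i = integer(), j = integer(), distance_nm = numeric()))
  w <- params$search_halfwidth
  # sorted sliding window on x keeps the candidate search near-linear
  ord <- order(spots_b$x_nm)
  bx <- spots_b$x_nm[ord]; by <- spots_b$y_nm[ord]
  lo <- findInterval(spots_a$x_nm - w, bx) + 1L
  hi <- findInterval(spots_a$x_nm + w, bx)
  res_i <- vector("list", nrow(spots_a))
  res_j <- vector("list", nrow(spots_a))
  for (i in seq_len(nrow(spots_a))) {
    if (lo[i] > hi[i]) next
    js <- lo[i]:hi[i]
    js <- js[abs(by[js] - spots_a$y_nm[i]) <= w]
    if (length(js)) {
      res_i[[i]] <- rep.int(i, length(js))
      res_j[[i]] <- ord[js]
    }
  }
  i <- unlist(res_i); j <- unlist(res_j)
  if (!length(i))
    return(data.frame(i = integer(), j = integer(), distance_nm = numeric()))
  d <- sqrt((spots_a$x_nm[i] - spots_b$x_nm[j])^2 +
              (spots_a$y_nm[i] - spots_b$y_nm[j])^2)
  if (params$distance_frame == "3d")
    d <- sqrt(d^2 + (spots_a$z_nm[i] - spots_b$z_nm[j])^2)
  out <- data.frame(i = i, j = j, distance_nm = d)
  out[order(out$distance_nm, out$i, out$j), , drop = FALSE]
}

#' Classify per-locus co-occurrence into singles, doubles and triples
#'
#' Greedy globally-closest-first grouping of registered spots from 2-3
#' probe channels: the closest unassigned cross-channel pair within
#' `coloc_radius` is merged into a record; a spot from a third channel
#' joins an existing record only if it is within the radius of *all*
#' current members (clique rule; configurable). Every spot ends up in
#' exactly one record; ungrouped spots are singles. Ties in distance are
#' broken lexicographically by channel and row index for determinism.
#'
#' Per-channel conservation (singles + double-memberships +
#' triple-memberships = total spots) is asserted on every run.
#'
#' @param spot_tables named list (2-3 channels) of registered spot tables.
#' @param params a `ColocParams`.
#' @return list of class `ColocResult`: `records` (one row per record:
#'   `record_id`, `class`, `combo` of sorted channel labels, `max_pair_nm`),
#'   `members` (record_id, channel, row index, spot nm coordinates),
#'   `summary` (per channel: total and per-class counts), `params`.
#' @export
classify_cooccurrence <- function(spot_tables, params = coloc_params()) {
  chs <- names(spot_tables)
  if (length(chs) < 2 || length(chs) > 3)
    stop("2 or 3 channels required")
  for (ch in chs) .check_registered(spot_tables[[ch]], ch)
  # candidate pairs within the coloc radius across all channel pairs
  pairs <- list()
  combos <- utils::combn(chs, 2, simplify = FALSE)
  for (cc in combos) {
    pc <- pair_candidates(spot_tables[[cc[1]]], spot_tables[[cc[2]]], params)
    pc <- pc[pc$distance_nm <= params$coloc_radius, , drop = FALSE]
    if (nrow(pc))
      pairs[[length(pairs) + 1L]] <-
        data.frame(cha = cc[1], ia = pc$i, chb = cc[2], ib = pc$j,
                   d = pc$distance_nm)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(cha = character(), ia = integer(), chb = character(),
               ib = integer(), d = numeric())
  pairs <- pairs[order(pairs$d, pairs$cha, pairs$chb, pairs$ia, pairs$ib), ,
                 drop = FALSE]
  assign <- lapply(spot_tables, function(s) rep(NA_integer_, nrow(s)))
  rec_members <- list()   # record id -> data.frame(channel, idx)
  getd <- function(ch1, i1, ch2, i2)
    .pair_dist(spot_tables[[ch1]], i1, spot_tables[[ch2]], i2,
               params$distance_frame)
  for (r in seq_len(nrow(pairs))) {
    cha <- pairs$cha[r]; ia <- pairs$ia[r]
    chb <- pairs$chb[r]; ib <- pairs$ib[r]
    aa <- assign[[cha]][ia]; ab <- assign[[chb]][ib]
    if (is.na(aa) && is.na(ab)) {
      id <- length(rec_members) + 1L
      rec_members[[id]] <- data.frame(channel = c(cha, chb), idx = c(ia, ib))
      assign[[cha]][ia] <- id; assign[[chb]][ib] <- id
    } else if (xor(is.na(aa), is.na(ab))) {
      id <- if (is.na(aa)) ab else aa
      joiner <- if (is.na(aa)) list(ch = cha, i = ia) else
        list(ch = chb, i = ib)
      mem <- rec_members[[id]]
      if (nrow(mem) >= 3 || joiner$ch %in% mem$channel) next
      ok <- if (params$triple_rule == "clique") {
        all(vapply(seq_len(nrow(mem)), function(k)
          getd(joiner$ch, joiner$i, mem$channel[k], mem$idx[k]) <=
            params$coloc_radius, logical(1)))
      } else TRUE
      if (!ok) next
      rec_members[[id]] <- rbind(mem, data.frame(channel = joiner$ch,
                                                 idx = joiner$i))
      assign[[joiner$ch]][joiner$i] <- id
    }
    # both already assigned: skip (a spot belongs to exactly one record)
  }
  # singles: every still-unassigned spot becomes its own record
  n_multi <- length(rec_members)
  single_ch <- character(0); single_idx <- integer(0)
  for (ch in chs) {
    un <- which(is.na(assign[[ch]]))
    if (length(un)) {
      assign[[ch]][un] <- n_multi + length(single_idx) + seq_along(un)
      single_ch <- c(single_ch, rep(ch, length(un)))
      single_idx <- c(single_idx, un)
    }
  }
  classes <- c("single", "double", "triple")
  multi <- lapply(seq_len(n_multi), function(id) {
    mem <- rec_members[[id]]
    n <- nrow(mem)
    maxd <- max(apply(utils::combn(n, 2), 2, function(p)
      getd(mem$channel[p[1]], mem$idx[p[1]],
           mem$channel[p[2]], mem$idx[p[2]])))
    list(n = n, combo = paste(sort(mem$channel), collapse = "+"),
         maxd = maxd)
  })
  n_mem <- c(vapply(multi, function(m) m$n, 0L + 0L),
             rep(1L, length(single_idx)))
  records <- data.frame(
    record_id = seq_len(n_multi + length(single_idx)),
    class = classes[n_mem],
    combo = c(vapply(multi, function(m) m$combo, ""), single_ch),
    n_members = n_mem,
    max_pair_nm = c(vapply(multi, function(m) m$maxd, 0),
                    rep(0, length(single_idx))))
  mem_id <- c(rep(seq_len(n_multi),
                  times = vapply(rec_members, nrow, 0L)),
              n_multi + seq_along(single_idx))
  mem_ch <- c(unlist(lapply(rec_members, `[[`, "channel")), single_ch)
  mem_idx <- c(unlist(lapply(rec_members, `[[`, "idx")), single_idx)
  pull <- function(col, default = NA_real_) {
    vapply(seq_along(mem_ch), function(k) {
      s <- spot_tables[[mem_ch[k]]]
      if (col %in% names(s)) s[[col]][mem_idx[k]] else default
    }, numeric(1))
  }
  members <- data.frame(record_id = mem_id, channel = mem_ch, idx = mem_idx,
                        x_nm = pull("x_nm"), y_nm = pull("y_nm"),
                        z_nm = pull("z_nm"), amplitude = pull("amplitude"))
  summary <- do.call(rbind, lapply(chs, function(ch) {
    ids <- assign[[ch]]
    sizes <- records$n_members[ids]
    data.frame(channel = ch, total = length(ids),
               singles = sum(sizes == 1), doubles = sum(sizes == 2),
               triples = sum(sizes == 3))
  }))
  # conservation, asserted on every run
  stopifnot(all(summary$singles + summary$doubles + summary$triples ==
                  summary$total))
  structure(list(records = records, members = members, summary = summary,
                 assignments = assign, params = params),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat("Co-localization result:", nrow(x$records), "records\n")
  print(x$summary, row.names = FALSE)
  combos <- table(x$records$combo[x$records$n_members > 1])
  if (length(combos)) {
    cat("  co-localized combinations:\n")
    for (n in names(combos)) cat(sprintf("    %-28s %d\n", n, combos[[n]]))
  }
  invisible(x)
}

#' Fraction of a channel's spots in a given co-occurrence class
#'
#' Computes, e.g., the fraction of gene-A spots that co-localize with gene B
#' (records whose channel set is exactly \{A, B\}), the fraction occurring
#' as isolated singles (`partners = "none"`), in a triple
#' (`partners = "all"`), or in any multi-spot record (`partners = "any"`).
#'
#' @param coloc a `ColocResult`.
#' @param channel channel label.
#' @param partners `"none"`, `"any"`, `"all"`, or a character vector of
#'   partner channels for an exact-combination match.
#' @return fraction in `[0, 1]`; `NA` when the channel has no spots (an
#'   undefined fraction is reported as missing, never as 0).
#' @export
coloc_fraction <- function(coloc, channel, partners = "any") {
  stopifnot(inherits(coloc, "ColocResult"))
  ids <- coloc$assignments[[channel]]
  if (is.null(ids)) stop("unknown channel: ", channel)
  if (!length(ids)) return(NA_real_)
  rec <- coloc$records
  sizes <- rec$n_members[ids]
  hit <- if (identical(partners, "none")) {
    sizes == 1
  } else if (identical(partners, "any")) {
    sizes > 1
  } else if (identical(partners, "all")) {
    sizes == 3
  } else {
    want <- paste(sort(c(channel, partners)), collapse = "+")
    rec$combo[ids] == want
  }
  mean(hit)
}

#' Expected co-localization under random chance
#'
#' Two null models for the number of co-localized doubles (and triples)
#' expected if bursting were independent across genes, given the observed
#' per-channel spot counts and an estimated cell count `C`:
#'
#' * model (a), cell-level: spots land in cells independently, any
#'   co-occupancy counts — `E[doubles AB] = n_A n_B / C`,
#'   `E[triple] = n_A n_B n_C / C^2`;
#' * model (b), spatial: model (a) thinned by the probability `p_s`
#'   (`p_t` for triples) that spots placed uniformly and independently in
#'   one nucleus sphere fall within the co-localization radius, estimated
#'   by Monte Carlo with a reported standard error.
#'
#' Alongside the expectations, a Monte-Carlo 95% *predictive* interval for
#' the observed count under model (b) is returned (hypergeometric
#' cell-overlap draw thinned binomially by `p_s`), which is the interval an
#' observed count should fall in when bursting really is independent.
#'
#' @param counts named per-channel spot counts (2 or 3 channels).
#' @param n_cells estimated number of cells in the region.
#' @param params a `ColocParams` (for `coloc_radius`, `nuclear_radius`,
#'   `distance_frame`).
#' @param n_mc Monte-Carlo replicates for the predictive interval.
#' @param n_ps point pairs used to estimate `p_s`.
#' @param seed RNG seed.
#' @return list of class `RandomColocExpectation`.
#' @export
expected_random_coloc <- function(counts, n_cells, params = coloc_params(),
                                  n_mc = 5000, n_ps = 200000, seed = 1L) {
  stopifnot(all(counts >= 0), n_cells > 0)
  chs <- names(counts)
  if (length(chs) < 2) stop("at least two channels required")
  if (any(counts > 2 * n_cells))
    warning("spot counts exceed 2 alleles x n_cells; check inputs")
  set.seed(seed)
  R <- params$nuclear_radius; r <- params$coloc_radius
  # p_s: two uniform points in one nucleus within r (2D-projected or 3D
  # frame, matching the classification frame)
  one <- .runif_sphere(n_ps, c(0, 0, 0), R)
  two <- .runif_sphere(n_ps, c(0, 0, 0), R)
  dd <- if (params$distance_frame == "3d") sqrt(rowSums((one - two)^2)) else
    sqrt((one[, 2] - two[, 2])^2 + (one[, 3] - two[, 3])^2)
  p_s <- mean(dd <= r)
  p_s_se <- sqrt(p_s * (1 - p_s) / n_ps)
  three <- .runif_sphere(n_ps, c(0, 0, 0), R)
  d13 <- if (params$distance_frame == "3d") sqrt(rowSums((one - three)^2)) else
    sqrt((one[, 2] - three[, 2])^2 + (one[, 3] - three[, 3])^2)
  d23 <- if (params$distance_frame == "3d") sqrt(rowSums((two - three)^2)) else
    sqrt((two[, 2] - three[, 2])^2 + (two[, 3] - three[, 3])^2)
  p_t <- mean(dd <= r & d13 <= r & d23 <= r)
  C <- n_cells
  pair_names <- utils::combn(chs, 2, FUN = paste, collapse = "+")
  pair_idx <- utils::combn(seq_along(chs), 2)
  model_a <- stats::setNames(counts[pair_idx[1, ]] * counts[pair_idx[2, ]] / C,
                             pair_names)
  model_b <- model_a * p_s
  triple_a <- if (length(chs) == 3) prod(counts) / C^2 else NA_real_
  triple_b <- if (length(chs) == 3) triple_a * p_t else NA_real_
  # predictive interval under model (b): occupied-cell overlap is
  # hypergeometric (active cells are a random subset), then binomial
  # thinning by p_s. Valid for single-allele counts; with 2 alleles the
  # count-based expectation above is the reference.
  ci <- matrix(NA_real_, ncol(pair_idx), 2)
  sims <- vector("list", ncol(pair_idx))
  for (k in seq_len(ncol(pair_idx))) {
    na <- min(counts[pair_idx[1, k]], C); nb <- min(counts[pair_idx[2, k]], C)
    ov <- stats::rhyper(n_mc, na, C - na, nb)
    sim <- stats::rbinom(n_mc, ov, p_s)
    ci[k, ] <- stats::quantile(sim, c(0.025, 0.975))
    sims[[k]] <- sim
  }
  rownames(ci) <- pair_names
  structure(list(counts = counts, n_cells = n_cells,
                 p_s = p_s, p_s_se = p_s_se, p_t = p_t,
                 doubles_model_a = model_a, doubles_model_b = model_b,
                 triples_model_a = triple_a, triples_model_b = triple_b,
                 doubles_predictive_ci = ci, mc_draws = sims,
                 params = params),
            class = "RandomColocExpectation")
}

#' @export
print.RandomColocExpectation <- function(x, ...) {
  cat("Random-chance co-localization expectation\n")
  cat(sprintf("  p_s (same-nucleus proximity) = %.5f +/- %.5f\n",
              x$p_s, x$p_s_se))
  for (nm in names(x$doubles_model_a))
    cat(sprintf("  %s: E(a) = %.3f, E(b) = %.3f, 95%% predictive [%g, %g]\n",
                nm, x$doubles_model_a[[nm]], x$doubles_model_b[[nm]],
                x$doubles_predictive_ci[nm, 1], x$doubles_predictive_ci[nm, 2]))
  invisible(x)
}
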