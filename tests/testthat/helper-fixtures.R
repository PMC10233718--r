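# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# a small empty volume with a few Gaussian spots at known sub-voxel centers
make_spot_volume <- function(dim = c(12, 48, 48), centers, amplitude = 100,
                             sxy = 1.3, sz = 0.8, background = 0) {
  vol <- array(background, dim)
  amplitude <- rep_len(amplitude, nrow(centers))
  for (i in seq_len(nrow(centers)))
    vol <- nascentfish:::.render_spot(vol, centers[i, ], amplitude[i],
                                      sxy, sz)
  vol
}

# registered spot table directly from nm coordinates
spots_from_nm <- function(x_nm, y_nm, z_nm = 0, channel = "ch",
                          amplitude = 100) {
  n <- length(x_nm)
  z_nm <- rep_len(z_nm, n)
  data.frame(channel = rep_len(channel, n), z = z_nm / 1000, y = y_nm / 110,
             x = x_nm / 110, amplitude = rep_len(amplitude, n),
             sigma_xy = rep_len(1.3, n), sigma_z = rep_len(0.8, n),
             background = rep_len(0, n), residual = rep_len(0, n),
             accepted = rep_len(TRUE, n), reason = rep_len(NA_character_, n),
             z_nm = z_nm, y_nm = y_nm, x_nm = x_nm,
             section_id = rep_len(NA_character_, n), in_roi = rep_len(NA, n))
}

# brute-force greedy max-not-mask oracle: works on the flattened vector and
# recomputes the masked set by explicit distance evaluation each iteration
# (independent of the package's offset-patch implementation)
oracle_max_not_mask <- function(vol, diameter_xy = 20, depth_z = 6,
                                stop_fraction = 0.05) {
  d <- dim(vol)
  co <- arrayInd(seq_along(vol), d)
  v <- as.vector(vol)
  thr <- stop_fraction * max(v)
  rx <- diameter_xy / 2; rz <- depth_z / 2
  out <- list()
  repeat {
    mx <- max(v)
    if (mx <= 0 || mx < thr) break
    cand <- which(v == mx)
    cc <- co[cand, , drop = FALSE]
    o <- order(cc[, 1], cc[, 2], cc[, 3])[1]
    seed <- cc[o, ]
    out[[length(out) + 1L]] <- c(seed - 1L, mx)
    inside <- ((co[, 2] - seed[2])^2 + (co[, 3] - seed[3])^2) / rx^2 +
      (co[, 1] - seed[1])^2 / rz^2 <= 1
    v[inside] <- 0
  }
  if (!length(out))
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric()))
  m <- do.call(rbind, out)
  data.frame(z = as.integer(m[, 1]), y = as.integer(m[, 2]),
             x = as.integer(m[, 3]), intensity = m[, 4])
}

# exhaustive optimal co-localization grouping for small instances:
# enumerate all ways to partition spots into cross-channel groups whose
# pairwise distances are all within `radius`, maximizing the number of
# grouped (non-single) spots first, then minimizing the summed pairwise
# distance. Returns the optimal per-channel class counts.
oracle_grouping <- function(spot_tables, radius, frame = "2d") {
  chs <- names(spot_tables)
  spots <- do.call(rbind, lapply(chs, function(ch) {
    s <- spot_tables[[ch]]
    if (!nrow(s)) return(NULL)
    data.frame(channel = ch, x = s$x_nm, y = s$y_nm,
               z = if (frame == "3d") s$z_nm else 0)
  }))
  n <- if (is.null(spots)) 0 else nrow(spots)
  if (n == 0) return(list(score = c(0, 0), sizes = integer()))
  dmat <- as.matrix(stats::dist(spots[, c("x", "y", "z")]))
  ok_group <- function(idx) {
    if (anyDuplicated(spots$channel[idx])) return(FALSE)
    if (length(idx) > 1 && max(dmat[idx, idx]) > radius) return(FALSE)
    TRUE
  }
  group_cost <- function(idx)
    if (length(idx) < 2) 0 else sum(dmat[idx, idx][upper.tri(dmat[idx, idx])])
  best <- NULL
  recurse <- function(remaining, groups) {
    if (!length(remaining)) {
      sizes <- lengths(groups)
      score <- c(sum(sizes[sizes > 1]), -sum(vapply(groups, group_cost, 0)))
      if (is.null(best) ||
          score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]))
        best <<- list(score = score, groups = groups)
      return(invisible())
    }
    i <- remaining[1]
    rest <- remaining[-1]
    # i alone
    recurse(rest, c(groups, list(i)))
    # i with one or two partners from the rest
    for (j in rest) {
      if (!ok_group(c(i, j))) next
      recurse(setdiff(rest, j), c(groups, list(c(i, j))))
      for (k in setdiff(rest, j)) {
        if (k < j) next
        if (!ok_group(c(i, j, k))) next
        recurse(setdiff(rest, c(j, k)), c(groups, list(c(i, j, k))))
      }
    }
  }
  recurse(seq_len(n), list())
  sizes <- lengths(best$groups)
  counts <- lapply(chs, function(ch) {
    idx <- which(spots$channel == ch)
    memb <- vapply(idx, function(i)
      sizes[which(vapply(best$groups, function(g) i %in% g, logical(1)))],
      numeric(1))
    c(total = length(idx), singles = sum(memb == 1),
      doubles = sum(memb == 2), triples = sum(memb == 3))
  })
  names(counts) <- chs
  list(score = best$score, counts = counts)
}

# closed-form CDF of the distance between two independent uniform points in
# a sphere of radius R (used as the analytic oracle for p_s)
sphere_dist_cdf <- function(d, R) {
  u <- d / R
  u^3 - (9 / 16) * u^4 + (1 / 32) * u^6
}
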