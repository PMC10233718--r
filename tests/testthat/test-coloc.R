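cp2d <- nascentfish::coloc_params()

test_that("candidate pairing respects the search square and reports distances", {
  a <- spots_from_nm(0, 0)
  b <- spots_from_nm(300, 400)
  pc <- pair_candidates(a, b, cp2d)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$distance_nm, 500)   # 3-4-5 triangle

  # inside the window but beyond the coloc radius: still a candidate
  b2 <- spots_from_nm(1500, 0)
  pc <- pair_candidates(a, b2, cp2d)
  expect_equal(pc$distance_nm, 1500)

  # outside the 3.9 um square: no candidate
  b3 <- spots_from_nm(2000, 0)
  expect_equal(nrow(pair_candidates(a, b3, cp2d)), 0)

  # symmetry and equality with the quadratic all-pairs oracle
  set.seed(20)
  a <- spots_from_nm(runif(200, 0, 20000), runif(200, 0, 20000))
  b <- spots_from_nm(runif(200, 0, 20000), runif(200, 0, 20000))
  pc <- pair_candidates(a, b, cp2d)
  brute <- do.call(rbind, lapply(1:200, function(i) {
    js <- which(abs(b$x_nm - a$x_nm[i]) <= cp2d$search_halfwidth &
                  abs(b$y_nm - a$y_nm[i]) <= cp2d$search_halfwidth)
    if (!length(js)) return(NULL)
    data.frame(i = i, j = js,
               d = sqrt((a$x_nm[i] - b$x_nm[js])^2 +
                          (a$y_nm[i] - b$y_nm[js])^2))
  }))
  expect_equal(nrow(pc), nrow(brute))
  key <- function(i, j) paste(i, j)
  expect_setequal(key(pc$i, pc$j), key(brute$i, brute$j))
  ba <- pair_candidates(b, a, cp2d)
  expect_setequal(key(pc$i, pc$j), key(ba$j, ba$i))

  # unregistered tables are refused
  raw <- a; raw$x_nm <- NULL; raw$y_nm <- NULL
  expect_error(pair_candidates(raw, b, cp2d), "register")
})

test_that("greedy grouping classifies singles, doubles and triples", {
  # three spots, one per channel, pairwise <= 500 nm: one triple
  tabs <- list(A = spots_from_nm(0, 0, channel = "A"),
               B = spots_from_nm(300, 0, channel = "B"),
               C = spots_from_nm(150, 260, channel = "C"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_equal(res$records$class, "triple")
  expect_equal(res$summary$triples, c(1, 1, 1))

  # clique rule: A-B 300, B-C 300, A-C 600 -> double(AB) + single(C)
  tabs <- list(A = spots_from_nm(0, 0, channel = "A"),
               B = spots_from_nm(300, 0, channel = "B"),
               C = spots_from_nm(600, 0, channel = "C"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_setequal(res$records$combo, c("A+B", "C"))
  # chain rule admits the triple instead
  resc <- classify_cooccurrence(tabs, coloc_params(triple_rule = "chain"))
  expect_equal(resc$records$combo, "A+B+C")

  # disjoint channels: all singles, per-channel totals conserved
  tabs <- list(A = spots_from_nm(c(0, 1000), c(0, 0), channel = "A"),
               B = spots_from_nm(c(50000, 51000), c(0, 0), channel = "B"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_equal(res$summary$singles, c(2, 2))
  expect_equal(res$summary$total, c(2, 2))
})

test_that("every spot lands in exactly one record on crowded random fields", {
  set.seed(21)
  for (rep in 1:5) {
    tabs <- list(
      A = spots_from_nm(runif(30, 0, 5000), runif(30, 0, 5000), channel = "A"),
      B = spots_from_nm(runif(25, 0, 5000), runif(25, 0, 5000), channel = "B"),
      C = spots_from_nm(runif(20, 0, 5000), runif(20, 0, 5000), channel = "C"))
    res <- classify_cooccurrence(tabs, cp2d)
    # conservation per channel
    expect_equal(res$summary$singles + res$summary$doubles +
                   res$summary$triples, res$summary$total)
    # assignment is a partition
    for (ch in names(tabs))
      expect_true(all(!is.na(res$assignments[[ch]])))
    expect_equal(sum(res$records$n_members), 30 + 25 + 20)
    # all grouped distances obey the radius (clique rule)
    expect_true(all(res$records$max_pair_nm <= cp2d$coloc_radius))
  }
})

test_that("greedy grouping is optimal when groups are spatially isolated", {
  # generative geometry: each nucleus contributes at most one spot per
  # channel and nuclei are separated by more than the coloc radius
  set.seed(22)
  for (rep in 1:20) {
    centers <- cbind(runif(4, 0, 40000), runif(4, 0, 40000))
    keep <- rep(TRUE, 4)
    for (i in 2:4) if (min(sqrt(rowSums(sweep(centers[seq_len(i - 1), ,
      drop = FALSE], 2, centers[i, ])^2))) < 8000) keep[i] <- FALSE
    centers <- centers[keep, , drop = FALSE]
    mk <- function(ch) {
      present <- runif(nrow(centers)) < 0.7
      if (!any(present)) present[1] <- TRUE
      x <- centers[present, 1] + runif(sum(present), -200, 200)
      y <- centers[present, 2] + runif(sum(present), -200, 200)
      spots_from_nm(x, y, channel = ch)
    }
    tabs <- list(A = mk("A"), B = mk("B"), C = mk("C"))
    res <- classify_cooccurrence(tabs, cp2d)
    want <- oracle_grouping(tabs, cp2d$coloc_radius)
    for (ch in names(tabs)) {
      got <- res$summary[res$summary$channel == ch, ]
      expect_equal(got$singles, unname(want$counts[[ch]]["singles"]))
      expect_equal(got$doubles, unname(want$counts[[ch]]["doubles"]))
      expect_equal(got$triples, unname(want$counts[[ch]]["triples"]))
    }
  }
})

test_that("coloc_radius monotonicity: wider radius never ungroups spots", {
  set.seed(23)
  tabs <- list(
    A = spots_from_nm(runif(40, 0, 8000), runif(40, 0, 8000), channel = "A"),
    B = spots_from_nm(runif(40, 0, 8000), runif(40, 0, 8000), channel = "B"))
  grouped <- sapply(c(100, 250, 500, 1000, 1950), function(r) {
    res <- classify_cooccurrence(tabs, coloc_params(coloc_radius = r))
    sum(res$summary$doubles + res$summary$triples)
  })
  expect_true(all(diff(grouped) >= 0))
})

test_that("co-localization fractions follow the stated accounting", {
  # 10 A spots, 4 of them in doubles with B -> 0.4
  ax <- c(seq(0, 9000, by = 1000))
  tabs <- list(A = spots_from_nm(ax, rep(0, 10), channel = "A"),
               B = spots_from_nm(ax[1:4] + 300, rep(0, 4), channel = "B"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_equal(coloc_fraction(res, "A", partners = "B"), 0.4)
  expect_equal(coloc_fraction(res, "A", partners = "any"), 0.4)
  expect_equal(coloc_fraction(res, "A", partners = "none"), 0.6)
  expect_equal(coloc_fraction(res, "B", partners = "A"), 1.0)

  # all spots single -> 0
  tabs <- list(A = spots_from_nm(0, 0, channel = "A"),
               B = spots_from_nm(9000, 9000, channel = "B"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_equal(coloc_fraction(res, "A", partners = "any"), 0)

  # empty channel: missing, not zero
  tabs <- list(A = spots_from_nm(numeric(0), numeric(0), channel = "A"),
               B = spots_from_nm(0, 0, channel = "B"))
  res <- classify_cooccurrence(tabs, cp2d)
  expect_true(is.na(coloc_fraction(res, "A", partners = "any")))
})

test_that("random-chance expectation matches analytic and Monte-Carlo oracles", {
  # model (a): n_A = n_B = 10 in 100 cells -> 1.0 expected co-occupied pair
  ex <- expected_random_coloc(c(A = 10, B = 10), n_cells = 100, cp2d,
                              n_mc = 2000, n_ps = 50000, seed = 5)
  expect_equal(unname(ex$doubles_model_a), 1.0)
  # Monte-Carlo assignment oracle for the cell-level expectation
  set.seed(6)
  overlap <- replicate(20000, {
    a <- sample.int(100, 10); b <- sample.int(100, 10)
    length(intersect(a, b))
  })
  expect_equal(mean(overlap), 1.0, tolerance = 0.03)

  # p_s agrees with the closed-form sphere-distance CDF (3D frame)
  cp3 <- coloc_params(distance_frame = "3d")
  ex3 <- expected_random_coloc(c(A = 50, B = 60), n_cells = 400, cp3,
                               n_mc = 500, n_ps = 200000, seed = 7)
  want <- sphere_dist_cdf(cp3$coloc_radius, cp3$nuclear_radius)
  expect_lt(abs(ex3$p_s - want), 4 * ex3$p_s_se)

  # zero counts give zero expectations
  ex0 <- expected_random_coloc(c(A = 0, B = 10), 100, cp2d, n_mc = 200,
                               n_ps = 1000, seed = 1)
  expect_equal(unname(ex0$doubles_model_a), 0)
  expect_equal(unname(ex0$doubles_model_b), 0)

  # limiting case: radius -> sphere diameter makes p_s -> 1 and model (b)
  # collapse onto model (a)
  cpl <- coloc_params(coloc_radius = 6000, nuclear_radius = 3000,
                      distance_frame = "3d", search_halfwidth = 4000)
  exl <- expected_random_coloc(c(A = 10, B = 10), 100, cpl, n_mc = 200,
                               n_ps = 20000, seed = 2)
  expect_equal(exl$p_s, 1)
  expect_equal(exl$doubles_model_b, exl$doubles_model_a)

  expect_warning(expected_random_coloc(c(A = 500, B = 2), 100, cp2d,
                                       n_mc = 100, n_ps = 1000, seed = 1),
                 "alleles")
})
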