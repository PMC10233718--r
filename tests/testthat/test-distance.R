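test_that("2D histograms conserve counts and bin structure", {
  h <- build_histogram(c(100, 350, 600), c(1, 1.2, 0.8))
  expect_equal(sum(h$counts), 3)
  expect_equal(h$n, 3)

  # all distances equal: a single occupied distance column
  h <- build_histogram(rep(400, 25), runif(25, 0.5, 2))
  occupied <- colSums(h$counts) > 0
  expect_equal(sum(occupied), 1)
  expect_equal(sum(h$counts), 25)

  # empty input is a valid empty histogram
  h0 <- build_histogram(numeric(0))
  expect_equal(sum(h0$counts), 0)

  # uniform random distances: chi-square uniformity not rejected
  set.seed(40)
  d <- runif(10000, 0, 1000)
  h <- build_histogram(d, dist_breaks = seq(0, 1000, by = 50))
  cs <- colSums(h$counts)
  p <- stats::chisq.test(cs)$p.value
  expect_gt(p, 0.01)
})

test_that("the gated 1D Gaussian fit recovers a generative peak", {
  set.seed(41)
  d <- rnorm(500, 350, 50)
  f <- fit_distance_peak(d, gate = c(0, 1000), n_boot = 300, seed = 2)
  expect_equal(f$method, "gaussian")
  expect_lt(abs(f$peak - 350), 3 * f$se)
  expect_equal(f$width, 50, tolerance = 0.15)
  # bootstrap SE close to the analytic sd/sqrt(n)
  expect_equal(f$se, 50 / sqrt(500), tolerance = 0.5)

  # determinism given the seed
  f2 <- fit_distance_peak(d, gate = c(0, 1000), n_boot = 300, seed = 2)
  expect_identical(f$se, f2$se)

  # degenerate sample: exact peak, zero SE
  f <- fit_distance_peak(rep(400, 50), n_boot = 50, seed = 1)
  expect_equal(f$peak, 400)
  expect_equal(f$se, 0)

  # small sample falls back to the median with a warning
  expect_warning(f <- fit_distance_peak(c(200, 300, 400), n_boot = 10),
                 "median")
  expect_equal(f$method, "median")
  expect_equal(f$peak, 300)

  expect_error(fit_distance_peak(c(2000, 3000)), "gate")
})

test_that("the 0-1 um gate excludes a far mode and re-gating is idempotent", {
  set.seed(42)
  near <- rnorm(400, 350, 40)
  far <- rnorm(400, 1400, 60)
  f <- fit_distance_peak(c(near, far), gate = c(0, 1000), n_boot = 200,
                         seed = 3)
  expect_lt(abs(f$peak - 350), 3 * f$se)
  expect_equal(f$n, sum(c(near, far) <= 1000))

  # compare with the single-mode fit: same peak within the joint error
  f1 <- fit_distance_peak(near, gate = c(0, 1000), n_boot = 200, seed = 3)
  expect_lt(abs(f$peak - f1$peak), 3 * sqrt(f$se^2 + f1$se^2) + 1)

  gated <- near[near >= 0 & near <= 1000]
  fa <- fit_distance_peak(gated, gate = c(0, 1000), n_boot = 100, seed = 4)
  fb <- fit_distance_peak(gated[gated >= 0 & gated <= 1000],
                          gate = c(0, 1000), n_boot = 100, seed = 4)
  expect_identical(fa$peak, fb$peak)
})

test_that("peak sensitivity to bin width stays within one bin", {
  set.seed(43)
  d <- rnorm(600, 420, 60)
  peaks <- sapply(c(15, 25, 40), function(bw)
    fit_distance_peak(d, bin_width = bw, n_boot = 0 + 50, seed = 5)$peak)
  expect_lt(max(peaks) - min(peaks), 40)
})

test_that("bootstrap SE shrinks like 1/sqrt(n)", {
  set.seed(44)
  d <- rnorm(1600, 350, 50)
  f_half <- fit_distance_peak(d[1:400], n_boot = 400, seed = 6)
  f_full <- fit_distance_peak(d, n_boot = 400, seed = 6)
  ratio <- f_half$se / f_full$se
  expect_lt(abs(ratio - 2), 0.55)
})

# build a ColocResult whose triples have controlled pairwise separations
make_triple_field <- function(n, seps, jitter_sd = 5, seed = 1) {
  # seps = c(AB, AC, BC) nm; place A at nucleus anchors on a sparse grid
  set.seed(seed)
  g <- expand.grid(x = seq(0, by = 8000, length.out = ceiling(sqrt(n))),
                   y = seq(0, by = 8000, length.out = ceiling(sqrt(n))))
  g <- g[seq_len(n), ]
  cosg <- (seps[1]^2 + seps[2]^2 - seps[3]^2) / (2 * seps[1] * seps[2])
  bx <- seps[1]; cx <- seps[2] * cosg; cy <- seps[2] * sqrt(1 - cosg^2)
  th <- runif(n, 0, 2 * pi)
  rot <- function(px, py) cbind(px * cos(th) - py * sin(th),
                                px * sin(th) + py * cos(th))
  a <- cbind(g$x, g$y) + matrix(rnorm(2 * n, 0, jitter_sd), n, 2)
  b <- cbind(g$x, g$y) + rot(bx, 0) + matrix(rnorm(2 * n, 0, jitter_sd), n, 2)
  cc <- cbind(g$x, g$y) + rot(cx, cy) + matrix(rnorm(2 * n, 0, jitter_sd), n, 2)
  list(A = spots_from_nm(a[, 1], a[, 2], channel = "A"),
       B = spots_from_nm(b[, 1], b[, 2], channel = "B"),
       C = spots_from_nm(cc[, 1], cc[, 2], channel = "C"))
}

test_that("pairwise peak report recovers known separations and the triangle", {
  tabs <- make_triple_field(144, c(300, 350, 400), seed = 7)
  res <- classify_cooccurrence(tabs, coloc_params())
  rep3 <- pairwise_peak_report(res, coloc_params(distance_frame = "2d"),
                               n_boot = 200, seed = 8, triangle = TRUE)
  got <- c(rep3$pairs[["A+B"]]$fit$peak, rep3$pairs[["A+C"]]$fit$peak,
           rep3$pairs[["B+C"]]$fit$peak)
  se <- c(rep3$pairs[["A+B"]]$fit$se, rep3$pairs[["A+C"]]$fit$se,
          rep3$pairs[["B+C"]]$fit$se)
  want <- c(300, 350, 400)
  expect_true(all(abs(got - want) <= 3 * se + 5))
  # triangle: vertex distances reproduce the three peaks
  tri <- rep3$triangle
  expect_equal(tri$x[1], 0)
  d12 <- sqrt(sum((tri[2, 2:3] - tri[1, 2:3])^2))
  d13 <- sqrt(sum((tri[3, 2:3] - tri[1, 2:3])^2))
  d23 <- sqrt(sum((tri[3, 2:3] - tri[2, 2:3])^2))
  expect_equal(c(d12, d13, d23), got, tolerance = 1e-6)
  # geometric consistency: peaks satisfy the triangle inequality
  expect_lt(max(got), sum(got) - max(got) + 3 * sqrt(sum(se^2)))

  expect_error(pairwise_peak_report(
    classify_cooccurrence(tabs[1:2], coloc_params()), triangle = TRUE),
    "3 channels")
})

test_that("a channel against a jittered copy peaks at the noise floor", {
  # mirrors the intron/exon self-comparison control: same loci seen twice
  set.seed(9)
  n <- 150
  x <- runif(n, 0, 6e4); y <- runif(n, 0, 6e4)
  sdloc <- 30
  tabs <- list(E = spots_from_nm(x, y, channel = "E"),
               I = spots_from_nm(x + rnorm(n, 0, sdloc),
                                 y + rnorm(n, 0, sdloc), channel = "I"))
  res <- classify_cooccurrence(tabs, coloc_params())
  rep2 <- pairwise_peak_report(res, coloc_params(distance_frame = "2d"),
                               bin_width = 10, n_boot = 200, seed = 10)
  peak <- rep2$pairs[["E+I"]]$fit$peak
  # 2D displacement with per-axis sd*sqrt(2) noise peaks near sd*sqrt(2)
  expect_lt(peak, 4 * sdloc)
  expect_gt(peak, 10)
})

test_that("chromatic correction is required to recover nanoscale separations", {
  # true separation 350 nm; the second channel carries a ~3 px shift
  set.seed(11)
  n <- 400
  gx <- runif(n, 2000, 26000); gy <- runif(n, 2000, 26000)
  th <- runif(n, 0, 2 * pi)
  ax <- gx; ay <- gy
  bx_true <- gx + 350 * cos(th); by_true <- gy + 350 * sin(th)
  # a misalignment of a few pixels: the uncorrected pair distance can never
  # drop below |shift| - 350 nm, pushing the whole gated mode upward
  tr <- channel_transform("B", dx = 6, dy = -4, rotation = 0.002,
                          scale = 1.001, center = c(127.5, 127.5))
  # observed B coordinates live in the miscalibrated channel frame
  obs <- apply_transform(cbind(bx_true / 110, by_true / 110),
                         invert_transform(tr))
  jit <- function(v) v + rnorm(n, 0, 15)
  tabs_uncorr <- list(
    A = spots_from_nm(jit(ax), jit(ay), channel = "A"),
    B = spots_from_nm(jit(obs[, 1] * 110), jit(obs[, 2] * 110),
                      channel = "B"))
  corr <- apply_transform(obs, tr)
  tabs_corr <- list(
    A = tabs_uncorr$A,
    B = spots_from_nm(jit(corr[, 1] * 110), jit(corr[, 2] * 110),
                      channel = "B"))
  peak_of <- function(tabs) {
    res <- classify_cooccurrence(tabs, coloc_params(coloc_radius = 1000,
                                                    distance_frame = "2d"))
    pairwise_peak_report(res, coloc_params(distance_frame = "2d"),
                         n_boot = 150, seed = 12)$pairs[["A+B"]]$fit
  }
  f_corr <- peak_of(tabs_corr)
  f_unc <- peak_of(tabs_uncorr)
  expect_lt(abs(f_corr$peak - 350), 3 * f_corr$se + 5)
  expect_gt(abs(f_unc$peak - 350), 3 * f_unc$se + 5)
  expect_gt(f_unc$peak, f_corr$peak)
})
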