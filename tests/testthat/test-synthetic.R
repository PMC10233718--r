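test_that("burst-state sampling honours marginals, coupling and seeds", {
  # probability-1 marginals: every cell active for both genes
  m <- sample_burst_states(200, c(1, 1), coupling = 1, seed = 3)
  expect_true(all(m == 1))

  # forced exclusion: coupling 0 means no doubly active cell
  m <- sample_burst_states(5000, c(0.5, 0.5), coupling = 0, seed = 3)
  expect_equal(sum(m[, 1] & m[, 2]), 0)
  expect_equal(mean(m[, 1]), 0.5, tolerance = 3 * sqrt(0.25 / 5000) / 0.5)

  # independence: co-activation converges to the product of marginals
  n <- 1e5
  m <- sample_burst_states(n, c(0.5, 0.5), coupling = 1, seed = 11)
  co <- mean(m[, 1] & m[, 2])
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(co - 0.25), 3 * se)

  # pairwise lift: P(both) = c * p1 * p2
  m <- sample_burst_states(n, c(0.4, 0.3), coupling = 1.5, seed = 12)
  expect_lt(abs(mean(m[, 1] & m[, 2]) - 1.5 * 0.4 * 0.3), 3 * sqrt(0.18 * 0.82 / n))
  expect_lt(abs(mean(m[, 1]) - 0.4), 3 * sqrt(0.4 * 0.6 / n))

  # three genes, marginals preserved under coupling
  m <- sample_burst_states(n, c(0.3, 0.4, 0.5), coupling = 1.2, seed = 13)
  for (j in 1:3) {
    p <- c(0.3, 0.4, 0.5)[j]
    expect_lt(abs(mean(m[, j]) - p), 3 * sqrt(p * (1 - p) / n))
  }

  # determinism
  expect_identical(sample_burst_states(100, c(0.3, 0.6), 1.1, seed = 9),
                   sample_burst_states(100, c(0.3, 0.6), 1.1, seed = 9))

  # invalid parameter sets are rejected with a parameter-validity error
  expect_error(sample_burst_states(10, c(0.9, 0.9), coupling = 1.3, seed = 1),
               "joint probabilities")
  expect_error(sample_burst_states(10, c(0.5, 1.2), coupling = 1, seed = 1))
})

test_that("rendered sections carry a faithful ground truth", {
  p <- simulation_params(n_cells = 6, seed = 21,
                         channels = c("geneA", "geneB"),
                         image_shape = c(14, 200, 200))
  r <- render_section(p)

  # determinism: identical params and seed give bit-identical output
  r2 <- render_section(p)
  expect_identical(r$stack$data, r2$stack$data)
  expect_identical(r$truth$spots, r2$truth$spots)

  # every true spot lies inside its nucleus sphere
  tr <- r$truth
  d <- sqrt((tr$spots$z_nm - tr$cells$z_nm[tr$spots$cell])^2 +
              (tr$spots$y_nm - tr$cells$y_nm[tr$spots$cell])^2 +
              (tr$spots$x_nm - tr$cells$x_nm[tr$spots$cell])^2)
  expect_true(all(d <= p$nuclear_radius + 1e-9))

  # burst-state marginals equal realized per-gene active-cell counts
  for (j in seq_along(p$channels)) {
    active <- unique(tr$spots$cell[tr$spots$channel == p$channels[j]])
    expect_setequal(active, which(tr$burst_states[, j] == 1))
  }

  # conservation: rendered spot count equals ground-truth table rows
  expect_equal(nrow(tr$spots),
               sum(tr$burst_states) * p$spots_per_active_cell)

  # nuclei do not overlap
  cd <- as.matrix(dist(tr$cells[, c("z_nm", "y_nm", "x_nm")]))
  diag(cd) <- Inf
  expect_gte(min(cd), 2 * p$nuclear_radius)
})

test_that("zero-amplitude spots leave the mean background unchanged", {
  base <- simulation_params(n_cells = 3, seed = 4, spot_amplitude = 0,
                            autofluorescence_density = 0,
                            image_shape = c(12, 160, 160),
                            camera_noise_sd = 0, shot_noise = FALSE)
  r <- render_section(base)
  vol <- get_channel(r$stack, "geneA")
  expect_equal(mean(vol), base$background_level, tolerance = 1e-12)
})

test_that("a single noiseless spot produces one maximum at the true center", {
  p <- simulation_params(n_cells = 1, seed = 5, channels = "geneA",
                         burst_prob = 1, spots_per_active_cell = 1,
                         autofluorescence_density = 0, background_level = 0,
                         camera_noise_sd = 0, shot_noise = FALSE,
                         image_shape = c(12, 96, 96))
  r <- render_section(p)
  vol <- get_channel(r$stack, "geneA")
  idx <- arrayInd(which.max(vol), dim(vol)) - 1   # 0-based
  sp <- r$truth$spots
  true_px <- c(sp$z_nm / p$voxel_size_z, sp$y_nm / p$voxel_size_xy,
               sp$x_nm / p$voxel_size_xy)
  expect_true(all(abs(idx - true_px) <= 0.5 + 1e-9))
})

test_that("integrated DAPI intensity is linear in the cell count", {
  # noise off: exact proportionality to the per-nucleus reference
  per_nucleus <- NULL
  sums <- sapply(c(3, 6), function(n) {
    p <- simulation_params(n_cells = n, seed = 31, background_level = 0,
                           camera_noise_sd = 0, shot_noise = FALSE,
                           autofluorescence_density = 0,
                           image_shape = c(20, 220, 220))
    r <- render_section(p)
    sum(get_channel(r$stack, "dapi"))
  })
  expect_equal(sums[2] / sums[1], 2, tolerance = 0.02)

  # with shot noise the field total still matches n x reference within 5%
  # (additive read noise adds a clamp pedestal over the large extra-nuclear
  # area; the cell-count estimator removes it by background subtraction,
  # tested with estimate_cell_count)
  p <- simulation_params(n_cells = 10, seed = 32, background_level = 0,
                         camera_noise_sd = 0,
                         autofluorescence_density = 0,
                         image_shape = c(20, 256, 256))
  r <- render_section(p)
  ref <- sums[1] / 3   # per-nucleus reference from the noiseless render
  tot <- sum(get_channel(r$stack, "dapi"))
  expect_equal(tot / ref, 10, tolerance = 0.05)
})

test_that("nucleus placement failure names the density constraint", {
  p <- simulation_params(n_cells = 200, seed = 1,
                         image_shape = c(10, 64, 64))
  expect_error(simulate_spot_tables(p), "dense|placement")
})

test_that("bead fields encode the true chromatic transform", {
  # identity: per-bead inter-channel offsets vanish up to localization noise
  bf <- render_bead_field(list(), n_beads = 5, shot_noise = FALSE,
                          camera_noise_sd = 0, seed = 2)
  va <- get_channel(bf$stack, "far_red"); vb <- get_channel(bf$stack, "red")
  expect_equal(va, vb, tolerance = 1e-12)

  # pure translation moves every bead by the same offset
  tr <- channel_transform("red", dx = 2, dy = 0)
  bf <- render_bead_field(list(red = tr), n_beads = 4,
                          channels = c("far_red", "red"),
                          shot_noise = FALSE, camera_noise_sd = 0, seed = 2)
  va <- get_channel(bf$stack, "far_red"); vb <- get_channel(bf$stack, "red")
  # red channel bead sits at x - 2 in its own frame (transform maps back)
  expect_equal(va[, , 3:190], vb[, , 1:188], tolerance = 1e-9)

  # rotation + scale: offsets grow with distance from the rotation center
  tr <- channel_transform("red", rotation = 0.5 * pi / 180, scale = 1.001,
                          center = c(127.5, 127.5))
  bf <- render_bead_field(list(red = tr), n_beads = 50,
                          channels = c("far_red", "red"),
                          shot_noise = FALSE, camera_noise_sd = 0, seed = 6)
  pos <- cbind(bf$truth$x, bf$truth$y)
  moved <- apply_transform(pos, invert_transform(tr))
  off <- sqrt(rowSums((moved - pos)^2))
  rad <- sqrt(rowSums(sweep(pos, 2, c(127.5, 127.5))^2))
  expect_gt(cor(off, rad), 0.99)

  expect_error(render_bead_field(list(), n_beads = 2), "3")
})
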