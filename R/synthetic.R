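#' Simulation parameters for synthetic smFISH sections
#'
#' Defines the generative model used by [render_section()] and
#' [simulate_spot_tables()]: densely placed spherical nuclei (radius 3 um by
#' default), per-cell Bernoulli burst states per gene with controllable
#' pairwise coupling, 1 or 2 nascent spots (alleles) per active cell placed
#' uniformly inside the nucleus, anisotropic Gaussian point-spread rendering,
#' per-channel chromatic misalignment, cytoplasmic autofluorescent clutter,
#' and Poisson shot noise followed by Gaussian read noise. Defaults follow
#' the imaging configuration emulated throughout the package: 1 um z-step,
#' 20 slices, 110 nm/px in xy.
#'
#' @param image_shape integer `(z, y, x)` voxel counts (default `c(20, 256,
#'   256)`).
#' @param voxel_size_xy,voxel_size_z nm per px / per slice.
#' @param channels probe channel labels (1-3).
#' @param n_cells number of nuclei to place.
#' @param nuclear_radius nm (default 3000).
#' @param burst_prob per-gene probability that a cell shows nascent
#'   transcription (recycled to `length(channels)`).
#' @param coupling symmetric matrix of pairwise lifts over independence
#'   (1 = independent, <1 mutual exclusion, >1 co-bursting); scalar allowed.
#' @param spots_per_active_cell 1 or 2 (allele count).
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas in nm.
#' @param spot_amplitude peak signal photons per spot.
#' @param background_level uniform background photons per voxel.
#' @param autofluorescence_density clutter spots per 1000 um^3 of
#'   extra-nuclear volume.
#' @param autofluorescence_amplitude peak photons of clutter spots.
#' @param camera_noise_sd Gaussian read-noise sd (counts).
#' @param shot_noise apply Poisson noise (disable for exact-linearity
#'   tests).
#' @param chromatic_transforms named list of true `ChannelTransform`s
#'   (channel frame -> reference frame); missing channels get the identity.
#' @param dapi_label,dapi_intensity DAPI channel name and per-voxel nuclear
#'   intensity.
#' @param seed integer RNG seed; identical params + seed give bit-identical
#'   output.
#' @return validated list of class `SimulationParams`.
#' @export
simulation_params <- function(image_shape = c(20, 256, 256),
                              voxel_size_xy = 110, voxel_size_z = 1000,
                              channels = c("geneA", "geneB", "geneC"),
                              n_cells = 25, nuclear_radius = 3000,
                              burst_prob = 0.4, coupling = 1,
                              spots_per_active_cell = 2,
                              psf_sigma_xy = 140, psf_sigma_z = 700,
                              spot_amplitude = 200, background_level = 20,
                              autofluorescence_density = 2,
                              autofluorescence_amplitude = 60,
                              camera_noise_sd = 2, shot_noise = TRUE,
                              chromatic_transforms = list(),
                              dapi_label = "dapi", dapi_intensity = 100,
                              seed = 1L) {
  g <- length(channels)
  if (g < 1 || g > 3) stop("1 to 3 probe channels supported")
  burst_prob <- rep_len(burst_prob, g)
  if (any(burst_prob < 0 | burst_prob > 1))
    stop("burst_prob must lie in [0, 1]")
  if (length(coupling) == 1) {
    coupling <- matrix(coupling, g, g); diag(coupling) <- 1
  }
  coupling <- as.matrix(coupling)
  if (!isTRUE(all.equal(coupling, t(coupling))))
    stop("coupling must be symmetric")
  if (any(coupling < 0)) stop("coupling entries must be >= 0")
  if (!spots_per_active_cell %in% 1:2)
    stop("spots_per_active_cell must be 1 or 2 (allele count)")
  stopifnot(voxel_size_xy > 0, voxel_size_z > 0, nuclear_radius > 0,
            psf_sigma_xy > 0, psf_sigma_z > 0, spot_amplitude >= 0,
            background_level >= 0, camera_noise_sd >= 0, n_cells >= 1)
  structure(list(image_shape = as.integer(image_shape),
                 voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
                 channels = channels, n_cells = as.integer(n_cells),
                 nuclear_radius = nuclear_radius, burst_prob = burst_prob,
                 coupling = coupling,
                 spots_per_active_cell = as.integer(spots_per_active_cell),
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 spot_amplitude = spot_amplitude,
                 background_level = background_level,
                 autofluorescence_density = autofluorescence_density,
                 autofluorescence_amplitude = autofluorescence_amplitude,
                 camera_noise_sd = camera_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 chromatic_transforms = chromatic_transforms,
                 dapi_label = dapi_label, dapi_intensity = dapi_intensity,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# joint distribution over burst patterns for <= 3 genes with given marginals
# p_g, pairwise P(g & h) = c_gh p_g p_h, and triple co-activation closed by
# the product of pairwise lifts. Errors if the implied cell probabilities
# leave [0, 1].
.burst_joint <- function(p, coupling) {
  g <- length(p)
  pats <- as.matrix(expand.grid(rep(list(0:1), g)))
  pair <- function(i, j) coupling[i, j] * p[i] * p[j]
  prob <- numeric(nrow(pats))
  if (g == 1) {
    prob <- ifelse(pats[, 1] == 1, p[1], 1 - p[1])
  } else {
    p12 <- if (g >= 2) pair(1, 2) else 0
    if (g == 2) {
      prob[pats[, 1] == 1 & pats[, 2] == 1] <- p12
      prob[pats[, 1] == 1 & pats[, 2] == 0] <- p[1] - p12
      prob[pats[, 1] == 0 & pats[, 2] == 1] <- p[2] - p12
      prob[pats[, 1] == 0 & pats[, 2] == 0] <- 1 - p[1] - p[2] + p12
    } else {
      p13 <- pair(1, 3); p23 <- pair(2, 3)
      p123 <- p[1] * p[2] * p[3] * coupling[1, 2] * coupling[1, 3] *
        coupling[2, 3]
      for (r in seq_len(nrow(pats))) {
        a <- pats[r, ]
        # inclusion-exclusion over the genes that must be inactive
        on <- which(a == 1); off <- which(a == 0)
        tot <- 0
        for (s in 0:length(off)) {
          subs <- if (s == 0) list(integer(0)) else
            lapply(utils::combn(seq_along(off), s, simplify = FALSE),
                   function(k) off[k])
          for (sub in subs) {
            set <- sort(c(on, sub))
            pr <- switch(as.character(length(set)),
                         "0" = 1,
                         "1" = p[set],
                         "2" = pair(set[1], set[2]),
                         "3" = p123)
            tot <- tot + (-1)^s * pr
          }
        }
        prob[r] <- tot
      }
    }
  }
  if (any(prob < -1e-12) || any(prob > 1 + 1e-12))
    stop("invalid burst parameter set: implied joint probabilities outside ",
         "[0, 1] (check coupling against the marginals)")
  prob <- pmin(pmax(prob, 0), 1)
  list(patterns = pats, prob = prob / sum(prob))
}

#' Sample per-cell burst states
#'
#' Draws a cells x genes 0/1 matrix where gene `g` is active with marginal
#' probability `burst_probs[g]` and genes `g, h` are jointly active with
#' probability `coupling[g, h] * p_g * p_h` (coupling 1 = independence,
#' 0 = mutual exclusion); for three genes the triple-activation probability
#' is closed by the product of the pairwise lifts. Parameter sets implying
#' joint probabilities outside `[0, 1]` are rejected with an error.
#'
#' @param n_cells number of cells.
#' @param burst_probs per-gene marginal activation probabilities.
#' @param coupling symmetric lift matrix (scalar recycled off-diagonal).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return integer matrix `n_cells x length(burst_probs)`.
#' @export
sample_burst_states <- function(n_cells, burst_probs, coupling = 1,
                                seed = 1L) {
  g <- length(burst_probs)
  if (length(coupling) == 1) {
    coupling <- matrix(coupling, g, g); diag(coupling) <- 1
  }
  if (any(burst_probs < 0 | burst_probs > 1))
    stop("burst probabilities must lie in [0, 1]")
  jd <- .burst_joint(burst_probs, as.matrix(coupling))
  set.seed(seed)
  idx <- sample.int(nrow(jd$patterns), n_cells, replace = TRUE,
                    prob = jd$prob)
  m <- jd$patterns[idx, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Place n non-overlapping nucleus centers (nm) inside the field. "random"
# uses rejection sampling with a retry cap; "grid" places centers on a
# jittered grid whose spacing guarantees that spots in different nuclei are
# farther apart than `grid_gap` nm (used for large coordinate-level
# simulations).
.place_nuclei <- function(n, field_nm, radius, method = c("random", "grid"),
                          grid_gap = 1000, max_tries = 10000) {
  method <- match.arg(method)
  if (method == "grid") {
    pitch <- 2 * radius + grid_gap
    nx <- max(1, floor(field_nm[3] / pitch))
    ny <- max(1, floor(field_nm[2] / pitch))
    nz <- max(1, floor(field_nm[1] / pitch))
    if (nx * ny * nz < n)
      stop("nucleus placement failed: grid capacity ", nx * ny * nz,
           " below n_cells = ", n, " at this density")
    g <- expand.grid(z = seq_len(nz), y = seq_len(ny), x = seq_len(nx))
    g <- g[seq_len(n), ]
    jit <- matrix(stats::runif(3 * n, -grid_gap / 4, grid_gap / 4), n, 3)
    cbind(z = (g$z - 0.5) * pitch + jit[, 1],
          y = (g$y - 0.5) * pitch + jit[, 2],
          x = (g$x - 0.5) * pitch + jit[, 3])
  } else {
    centers <- matrix(NA_real_, n, 3)
    lo <- pmin(radius, field_nm / 2)
    placed <- 0; tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("nucleus placement failed after ", max_tries,
             " tries: n_cells = ", n, " too dense for a field of ",
             paste(round(field_nm / 1000, 1), collapse = " x "),
             " um with radius ", radius, " nm")
      cand <- stats::runif(3, lo, pmax(field_nm - lo, lo))
      if (placed > 0) {
        d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < (2 * radius)^2) next
      }
      placed <- placed + 1
      centers[placed, ] <- cand
    }
    colnames(centers) <- c("z", "y", "x")
    centers
  }
}

# uniform points inside a sphere (radius r, center nm vector c3 = (z,y,x))
.runif_sphere <- function(n, c3, r) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m <- m / sqrt(rowSums(m^2))
  u <- stats::runif(n)^(1 / 3)
  sweep(m * (u * r), 2, c3, "+")
}

#' Coordinate-level section simulation (ground truth only)
#'
#' Generates the full ground truth of a synthetic tissue section without
#' rendering voxel data: nucleus centers, per-cell burst states, and true
#' nascent-spot positions (uniform inside each nucleus sphere, one position
#' per active allele) in physical reference-frame nanometres. Used directly
#' for statistical calibration at large `n_cells`, and by [render_section()]
#' as the first stage of image synthesis.
#'
#' @param params a `SimulationParams`.
#' @param burst_states optional precomputed cells x genes matrix.
#' @param placement `"random"` (non-overlapping rejection sampling inside
#'   the image volume) or `"grid"` (jittered grid, any `n_cells`; spots of
#'   different nuclei are guaranteed farther apart than 1 um).
#' @return list of class `GroundTruth`: `cells` (nm centers + radius),
#'   `spots` (cell, channel, true nm center, amplitude), `burst_states`,
#'   `transforms`, `params`.
#' @export
simulate_spot_tables <- function(params, burst_states = NULL,
                                 placement = c("random", "grid")) {
  stopifnot(inherits(params, "SimulationParams"))
  placement <- match.arg(placement)
  g <- length(params$channels)
  if (is.null(burst_states))
    burst_states <- sample_burst_states(params$n_cells, params$burst_prob,
                                        params$coupling, params$seed)
  set.seed(params$seed + 1L)
  # sampled voxel extent: centers live on 0..(n-1) * voxel size, and the
  # placement margin keeps whole nuclei inside the sampled grid
  field_nm <- c((params$image_shape[1] - 1) * params$voxel_size_z,
                (params$image_shape[2] - 1) * params$voxel_size_xy,
                (params$image_shape[3] - 1) * params$voxel_size_xy)
  if (placement == "grid") {
    # grow the field so the jittered grid can hold n_cells nuclei
    pitch <- 2 * params$nuclear_radius + 1000
    side <- ceiling(params$n_cells^(1 / 3))
    field_nm <- pmax(field_nm, rep(side * pitch, 3))
  }
  centers <- .place_nuclei(params$n_cells, field_nm, params$nuclear_radius,
                           placement)
  cells <- data.frame(cell = seq_len(params$n_cells),
                      z_nm = centers[, 1], y_nm = centers[, 2],
                      x_nm = centers[, 3], radius = params$nuclear_radius)
  spots <- list()
  for (j in seq_len(g)) {
    active <- which(burst_states[, j] == 1)
    if (!length(active)) next
    n_sp <- params$spots_per_active_cell
    cell_id <- rep(active, each = n_sp)
    pos <- do.call(rbind, lapply(active, function(i)
      .runif_sphere(n_sp, centers[i, ], params$nuclear_radius)))
    spots[[j]] <- data.frame(cell = cell_id, channel = params$channels[j],
                             z_nm = pos[, 1], y_nm = pos[, 2],
                             x_nm = pos[, 3],
                             amplitude = params$spot_amplitude)
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(cell = integer(), channel = character(), z_nm = numeric(),
               y_nm = numeric(), x_nm = numeric(), amplitude = numeric())
  structure(list(cells = cells, spots = spots, burst_states = burst_states,
                 transforms = params$chromatic_transforms, params = params,
                 field_nm = field_nm),
            class = "GroundTruth")
}

#' Ground truth as detector-style spot tables
#'
#' Converts a `GroundTruth` into per-channel spot tables in the schema the
#' co-localization and distance stages consume, optionally adding Gaussian
#' localization noise to emulate fitting error.
#'
#' @param truth a `GroundTruth`.
#' @param localization_sd_nm isotropic per-axis jitter (0 = exact truth).
#' @return named list of spot-table data.frames (with `x_nm, y_nm, z_nm` and
#'   pixel coordinates in the reference frame).
#' @export
truth_spot_tables <- function(truth, localization_sd_nm = 0) {
  stopifnot(inherits(truth, "GroundTruth"))
  p <- truth$params
  sp <- truth$spots
  if (localization_sd_nm > 0 && nrow(sp)) {
    sp$z_nm <- sp$z_nm + stats::rnorm(nrow(sp), 0, localization_sd_nm)
    sp$y_nm <- sp$y_nm + stats::rnorm(nrow(sp), 0, localization_sd_nm)
    sp$x_nm <- sp$x_nm + stats::rnorm(nrow(sp), 0, localization_sd_nm)
  }
  out <- list()
  for (ch in p$channels) {
    s <- sp[sp$channel == ch, , drop = FALSE]
    out[[ch]] <- data.frame(channel = rep(ch, nrow(s)),
                            z = s$z_nm / p$voxel_size_z,
                            y = s$y_nm / p$voxel_size_xy,
                            x = s$x_nm / p$voxel_size_xy,
                            amplitude = s$amplitude,
                            sigma_xy = NA_real_, sigma_z = NA_real_,
                            background = 0, residual = 0,
                            accepted = TRUE, reason = NA_character_,
                            z_nm = s$z_nm, y_nm = s$y_nm, x_nm = s$x_nm,
                            section_id = NA_character_, in_roi = NA)
  }
  out
}

# add an anisotropic 3D Gaussian to vol (in place semantics via return);
# center (z, y, x) 0-based px, sigmas in px.
.render_spot <- function(vol, center, amp, sxy, sz) {
  d <- dim(vol)
  ez <- ceiling(4 * sz); exy <- ceiling(4 * sxy)
  zr <- max(1, floor(center[1]) - ez + 1):min(d[1], ceiling(center[1]) + ez + 1)
  yr <- max(1, floor(center[2]) - exy + 1):min(d[2], ceiling(center[2]) + exy + 1)
  xr <- max(1, floor(center[3]) - exy + 1):min(d[3], ceiling(center[3]) + exy + 1)
  if (!length(zr) || !length(yr) || !length(xr)) return(vol)
  gz <- exp(-((zr - 1) - center[1])^2 / (2 * sz^2))
  gy <- exp(-((yr - 1) - center[2])^2 / (2 * sxy^2))
  gx <- exp(-((xr - 1) - center[3])^2 / (2 * sxy^2))
  patch <- amp * outer(outer(gz, gy), gx)
  vol[zr, yr, xr] <- vol[zr, yr, xr] + patch
  vol
}

#' Render a synthetic multi-channel smFISH section
#'
#' Renders the ground truth of [simulate_spot_tables()] into an
#' `ImageStack`: nascent spots as anisotropic 3D Gaussians at their true
#' sub-voxel centers (each non-reference probe channel drawn after moving
#' the true reference-frame position into the channel frame through the
#' inverse of its true chromatic transform), autofluorescent clutter
#' outside the nuclei, a DAPI channel of filled spheres with uniform
#' per-nucleus intensity, a constant background, then Poisson shot noise
#' and additive Gaussian read noise.
#'
#' @param params a `SimulationParams`.
#' @param burst_states optional precomputed burst-state matrix.
#' @return list with `stack` (`ImageStack`, probe channels + DAPI) and
#'   `truth` (`GroundTruth`).
#' @export
render_section <- function(params, burst_states = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  truth <- simulate_spot_tables(params, burst_states, placement = "random")
  set.seed(params$seed + 2L)
  d <- params$image_shape
  g <- length(params$channels)
  sxy <- params$psf_sigma_xy / params$voxel_size_xy
  sz <- params$psf_sigma_z / params$voxel_size_z
  data <- array(0, c(g + 1, d))
  # autofluorescent clutter: uniform outside nuclei, per channel
  field_um3 <- prod(truth$field_nm) / 1e9
  n_af <- stats::rpois(g, params$autofluorescence_density * field_um3 / 1000)
  for (j in seq_len(g)) {
    ch <- params$channels[j]
    vol <- array(0, d)
    sp <- truth$spots[truth$spots$channel == ch, , drop = FALSE]
    tr <- params$chromatic_transforms[[ch]]
    if (nrow(sp)) {
      xy <- cbind(sp$x_nm / params$voxel_size_xy,
                  sp$y_nm / params$voxel_size_xy)
      if (!is.null(tr)) xy <- apply_transform(xy, invert_transform(tr))
      for (i in seq_len(nrow(sp)))
        vol <- .render_spot(vol, c(sp$z_nm[i] / params$voxel_size_z,
                                   xy[i, 2], xy[i, 1]),
                            sp$amplitude[i], sxy, sz)
    }
    if (n_af[j] > 0) {
      k <- 0; tries <- 0
      while (k < n_af[j] && tries < 50 * n_af[j]) {
        tries <- tries + 1
        pos <- stats::runif(3, 0, truth$field_nm)   # (z, y, x) nm
        d2 <- (truth$cells$z_nm - pos[1])^2 + (truth$cells$y_nm - pos[2])^2 +
          (truth$cells$x_nm - pos[3])^2
        if (min(d2) < params$nuclear_radius^2) next  # cytoplasmic only
        k <- k + 1
        vol <- .render_spot(vol, c(pos[1] / params$voxel_size_z,
                                   pos[2] / params$voxel_size_xy,
                                   pos[3] / params$voxel_size_xy),
                            params$autofluorescence_amplitude, sxy, sz)
      }
    }
    data[j, , , ] <- vol + params$background_level
  }
  # DAPI: filled spheres, uniform per-nucleus voxel intensity
  dapi <- array(0, d)
  zc <- ((seq_len(d[1]) - 1) * params$voxel_size_z)
  yc <- ((seq_len(d[2]) - 1) * params$voxel_size_xy)
  xc <- ((seq_len(d[3]) - 1) * params$voxel_size_xy)
  for (i in seq_len(nrow(truth$cells))) {
    cz <- truth$cells$z_nm[i]; cy <- truth$cells$y_nm[i]
    cx <- truth$cells$x_nm[i]; r <- truth$cells$radius[i]
    zi <- which(abs(zc - cz) <= r); yi <- which(abs(yc - cy) <= r)
    xi <- which(abs(xc - cx) <= r)
    if (!length(zi) || !length(yi) || !length(xi)) next
    m <- outer(outer((zc[zi] - cz)^2, (yc[yi] - cy)^2, "+"),
               (xc[xi] - cx)^2, "+") <= r^2
    dapi[zi, yi, xi] <- dapi[zi, yi, xi] + params$dapi_intensity * m
  }
  data[g + 1, , , ] <- dapi + params$background_level
  if (params$shot_noise)
    data[] <- stats::rpois(length(data), as.vector(data))
  if (params$camera_noise_sd > 0)
    data[] <- data + stats::rnorm(length(data), 0, params$camera_noise_sd)
  data[data < 0] <- 0
  stack <- image_stack(data, params$voxel_size_xy, params$voxel_size_z,
                       c(params$channels, params$dapi_label))
  list(stack = stack, truth = truth)
}

#' Render a synthetic multi-channel bead calibration field
#'
#' Places `n_beads` fiducial beads (visible in every channel) at random
#' well-separated positions and renders each non-reference channel after
#' displacing the true positions through the inverse of that channel's true
#' chromatic transform — the synthetic analogue of a multi-fluorophore bead
#' slide used to calibrate chromatic aberration.
#'
#' @param true_transforms named list of `ChannelTransform` for non-reference
#'   channels (channel frame -> reference frame).
#' @param n_beads number of beads (>= 3, or the similarity transform is
#'   unidentifiable).
#' @param channels channel labels; the first is the reference.
#' @param image_shape `(z, y, x)` voxels.
#' @param amplitude,background,camera_noise_sd,shot_noise imaging model.
#' @param psf_sigma_xy_px,psf_sigma_z_px PSF in pixel units.
#' @param min_separation_px minimum in-plane bead separation.
#' @param voxel_size_xy,voxel_size_z calibration (nm).
#' @param seed RNG seed.
#' @return list with `stack` (`ImageStack`) and `truth` (data.frame of true
#'   0-based reference-frame bead centers `z, y, x` in px).
#' @export
render_bead_field <- function(true_transforms, n_beads = 30,
                              channels = c("far_red", "red", "green"),
                              image_shape = c(8, 256, 256),
                              amplitude = 500, background = 10,
                              camera_noise_sd = 2, shot_noise = TRUE,
                              psf_sigma_xy_px = 1.3, psf_sigma_z_px = 0.8,
                              min_separation_px = 25,
                              voxel_size_xy = 110, voxel_size_z = 1000,
                              seed = 1L) {
  if (n_beads < 3)
    stop("n_beads must be >= 3: an in-plane similarity transform has 4 ",
         "degrees of freedom")
  set.seed(seed)
  d <- as.integer(image_shape)
  margin <- 12
  pos <- matrix(NA_real_, n_beads, 3)
  placed <- 0; tries <- 0
  while (placed < n_beads) {
    tries <- tries + 1
    if (tries > 20000)
      stop("bead placement failed: min_separation_px too large for field")
    cand <- c(stats::runif(1, 2, d[1] - 3),
              stats::runif(1, margin, d[2] - margin - 1),
              stats::runif(1, margin, d[3] - margin - 1))
    if (placed > 0) {
      dd <- (pos[seq_len(placed), 2] - cand[2])^2 +
        (pos[seq_len(placed), 3] - cand[3])^2
      if (min(dd) < min_separation_px^2) next
    }
    placed <- placed + 1
    pos[placed, ] <- cand
  }
  data <- array(0, c(length(channels), d))
  for (j in seq_along(channels)) {
    ch <- channels[j]
    vol <- array(0, d)
    tr <- true_transforms[[ch]]
    xy <- cbind(pos[, 3], pos[, 2])
    if (!is.null(tr) && j > 1) xy <- apply_transform(xy, invert_transform(tr))
    for (i in seq_len(n_beads))
      vol <- .render_spot(vol, c(pos[i, 1], xy[i, 2], xy[i, 1]),
                          amplitude, psf_sigma_xy_px, psf_sigma_z_px)
    data[j, , , ] <- vol + background
  }
  if (shot_noise) data[] <- stats::rpois(length(data), as.vector(data))
  if (camera_noise_sd > 0)
    data[] <- data + stats::rnorm(length(data), 0, camera_noise_sd)
  data[data < 0] <- 0
  stack <- image_stack(data, voxel_size_xy, voxel_size_z, channels)
  list(stack = stack,
       truth = data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3]))
}
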