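# nascentfish

Quantification of nascent transcription from multiplexed single-molecule
FISH (smFISH) image stacks of tissue sections.

Intron-targeting smFISH probes light up transcripts still attached to their
gene locus, so an actively bursting allele appears as a single
diffraction-limited nuclear spot. Imaging up to three probe channels plus
DAPI through a 3D stack of a tissue section, one can ask — cell by cell —
how often neighbouring genes of a cluster burst, whether they burst
*together* more or less often than chance, and how far apart the
co-transcribing loci sit at the nanoscale. `nascentfish` implements the
full analysis chain for that experiment, together with a synthetic-image
simulator with complete ground truth that makes every stage testable
without microscope data.

## What the pipeline computes

* **Spot calling**: per-slice Gaussian blur (σ = 1 px) + rolling-ball
  background subtraction (r = 15 px), greedy *max-not-mask* peak finding
  (mask spheroid 20 px × 6 slices, 5%-of-maximum stop rule), then
  constrained nonlinear least-squares 3D Gaussian refinement
  (20 × 20 × 6 window, center within 2 px / 2 slices of the seed) for
  sub-pixel centers, amplitudes and widths.
* **Chromatic registration**: multi-colour beads fitted per channel and
  matched to the far-red reference; a closed-form least-squares similarity
  transform (translation, rotation, scale) per channel, applied to spot
  *coordinates* (never by resampling images).
* **Co-localization**: cross-channel spots grouped greedily
  (closest-pair-first) within a 500 nm radius, searched in a 3.9 × 3.9 µm
  window, classified into **singles / doubles / triples**; expected
  co-localization under random chance from two null models
  (cell-level independence `E = n_A n_B / C`, and its spatial thinning by
  the same-nucleus proximity probability `p_s`, with a Monte-Carlo
  predictive interval).
* **Per-cell rates**: cell counts from the ratio of background-subtracted
  integrated DAPI intensity to a per-nucleus reference (dense tissue
  defeats nucleus segmentation), then nascent spots per cell per
  transcript and between-gene abundance ratios.
* **Inter-locus distances**: amplitude-vs-distance histograms of
  co-localized pairs, a 0–1 µm gate, a 1D Gaussian fit for the peak
  separation with a bootstrap standard error, and a triangle summary of
  the three pairwise peaks.
* **Group statistics**: per-section rates compared between genotypes by
  two-sided Mann–Whitney rank-sum and variance-ratio F tests, annotated
  `ns/*/**/***/****` (0.05/0.01/0.001/0.0001) with a variance star at
  p < 0.05.

The simulator (`simulation_params()`, `render_section()`,
`render_bead_field()`) generates nuclei as non-overlapping 3 µm spheres,
per-cell burst states with controllable inter-gene coupling, allele spots
placed uniformly in each nucleus, anisotropic Gaussian PSF rendering,
per-channel chromatic misalignment, autofluorescent clutter, and
Poisson–Gaussian camera noise — returning the full ground truth alongside
the `ImageStack`.

## Worked example

```r
library(nascentfish)

# simulate a two-gene section with known ground truth
params <- simulation_params(n_cells = 15, seed = 7,
                            channels = c("geneA", "geneB"),
                            burst_prob = c(0.5, 0.4), coupling = 1,
                            spot_amplitude = 400, background_level = 10,
                            autofluorescence_density = 0,
                            image_shape = c(16, 256, 256))
section <- render_section(params)
section$stack
#> ImageStack: 3 channel(s) [geneA, geneB, dapi], 16 z x 256 y x 256 x voxels
#>   calibration: 110.0 nm/px (xy), 1000.0 nm/slice (z)

# detect + refine spots in each probe channel, register to nm coordinates
dp <- default_config()$detection
spots <- lapply(c("geneA", "geneB"), function(ch) {
  s <- detect_spots(section$stack, ch, dp)
  register_spots(s[s$accepted, ], section$stack)
})
names(spots) <- c("geneA", "geneB")
sapply(spots, nrow)
#> geneA geneB
#>    11     7

# classify co-occurrence within 500 nm
coloc <- classify_cooccurrence(spots, coloc_params())
coloc
#> Co-localization result: 18 records
#>  channel total singles doubles triples
#>    geneA    11      11       0       0
#>    geneB     7       7       0       0

# compare with the random-chance expectation
expected_random_coloc(c(geneA = nrow(spots$geneA), geneB = nrow(spots$geneB)),
                      n_cells = params$n_cells, coloc_params(), seed = 1)
#> Random-chance co-localization expectation
#>   p_s (same-nucleus proximity) = 0.03094 +/- 0.00039
#>   geneA+geneB: E(a) = 5.133, E(b) = 0.159, 95% predictive [0, 1]
```

Eleven geneA and seven geneB sites were called; none co-localize, and the
spatial null model agrees: although ~5 cell-level co-occupancies would be
expected by chance, only ~0.16 of them should fall within 500 nm when
spots land uniformly in a 3 µm nucleus, so zero observed doubles sits
inside the predictive interval. Rates per cell, distance-peak fitting and
genotype comparisons continue from these objects (`summarize_section()`,
`pairwise_peak_report()`, `compare_groups()`); see the vignette in
`vignettes/` for the full methods account.

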