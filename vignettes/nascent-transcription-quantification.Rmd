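---
title: "Quantifying nascent transcription from multiplexed smFISH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nascent transcription from multiplexed smFISH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentfish)
```

## The measurement problem

Single-molecule FISH with intron-targeting probes marks *nascent*
transcripts: RNA still tethered to its gene locus. In a tissue section a
transcribing allele therefore appears as one diffraction-limited nuclear
spot per channel, and imaging up to three probe channels at once lets one
ask, cell by cell, whether neighbouring genes burst together. The
quantities of interest are (i) nascent-spot counts per cell, (ii) the
classification of co-occurring spots into **singles, doubles and triples**
within a proximity radius, compared with what random chance would produce,
and (iii) the **nanoscale distances** between co-transcribing loci,
measured across channels after correcting chromatic aberration.

`nascentfish` implements that pipeline for multi-channel 3D stacks
(default geometry: 1000 nm z-step, 20 slices, 110 nm/px in xy) and pairs it
with a simulator that produces the same kind of data with complete ground
truth, so that every stage is testable without microscope data.

## Processing chain

1. **Preprocess** (`preprocess_channel`): per-slice Gaussian blur
   (sigma 1 px) then per-slice rolling-ball background subtraction
   (radius 15 px), implemented as a grayscale opening with a non-flat ball
   element in compiled code. The opening is a lower envelope, so constant
   offsets are removed exactly and the output is non-negative.
2. **Peak candidates** (`find_peaks_max_not_mask`): greedy max-not-mask —
   repeatedly take the brightest remaining voxel and zero a spheroid of
   20 px (xy) by 6 slices (z) around it, stopping when the remaining
   maximum falls below 5% of the (preprocessed) volume maximum. The stop
   rule is evaluated on the preprocessed volume because that is the object
   being searched; ties break toward the lowest (z, y, x) index for
   determinism.
3. **Sub-pixel refinement** (`refine_gaussian3d`): nonlinear least-squares
   fit of `background + A * G(center; sigma_xy, sigma_z)` on a
   20 x 20 x 6 window of the *raw* volume, center constrained to 2 px (xy) /
   2 slices (z) of the seed. Fits pinned at the constraint, non-converging
   fits, and windows crossing the volume edge are rejected with explicit
   reasons. Sigma bounds (0.5-5 px xy, 0.5-3 slices z) exclude noise fits;
   both bounds are configurable.
4. **Registration** (`register_channels`, `estimate_transform`): beads
   visible in all channels are fitted like spots, matched to the reference
   channel (far-red by default, for its low background) by nearest
   neighbour within 5 px, and a closed-form least-squares similarity
   transform (translation, rotation, isotropic scale) is estimated per
   channel. Corrections are applied to fitted *coordinates*, never by
   resampling voxel data, so no interpolation bias enters the distance
   analysis. Only xy is corrected: with a 1 um z-step, axial chromatic
   registration is ill-posed.
5. **Co-localization** (`classify_cooccurrence`): spots from 2-3 channels
   are grouped greedily, globally-closest-pair first, within a 500 nm
   radius (candidates restricted to a 3.9 um search square); a
   third-channel spot joins only if within the radius of *all* members
   (clique rule, switchable to a chain rule). Each spot belongs to exactly
   one record; per-channel `singles + doubles + triples = total` is
   asserted on every run. Classification uses 2D-projected centers; the
   distance analysis uses the 3D fits — both frames are available
   explicitly.
6. **Random-chance expectation** (`expected_random_coloc`): two null
   models. Model (a) is cell-level independence,
   `E[doubles] = n_A n_B / C`. Model (b) thins model (a) by the
   probability `p_s` that two points placed uniformly in one nucleus
   sphere (radius 3 um) fall within the co-localization radius, estimated
   by Monte Carlo. Because an observed count is an integer, the function
   also returns a Monte-Carlo 95% *predictive* interval for the count
   under model (b) (hypergeometric cell overlap, binomial thinning); that
   interval, not a CI on the expectation, is what an observed count should
   fall into under independence.
7. **Per-cell rates** (`estimate_cell_count`, `summarize_section`): dense
   neural-tube tissue defeats nucleus segmentation, so cell counts come
   from the ratio of background-subtracted integrated DAPI intensity (sum
   projection) to a per-nucleus reference measured in a sparse region.
   Counts are kept real-valued — they divide spot counts, and rounding
   would bias rates. A transcript absent from a probe set is reported as
   not-measured, never as zero.
8. **Distance distributions** (`pairwise_peak_report`,
   `fit_distance_peak`): cross-channel pair distances are histogrammed
   against relative amplitude, gated to 0-1 um, and the gated histogram is
   fit to a 1D Gaussian by nonlinear least squares; the peak position is
   the separation estimate and its error is a bootstrap SE over pairs
   (1000 resamples by default, seeded). In triangle mode only triples
   contribute and the three pairwise peaks are drawn as a triangle with
   the first gene anchored at zero.
9. **Group statistics** (`compare_groups`): per-section rates are compared
   between genotypes with the two-sided Mann-Whitney rank-sum test
   (location) and a two-sided variance-ratio F test (spread), annotated
   `ns/*/**/***/****` at 0.05/0.01/0.001/0.0001 and a variance star at
   p < 0.05. No multiple-testing correction is applied by default,
   matching per-gene reporting conventions; a Benjamini-Hochberg option
   exists. The unit of analysis is the section.

## The simulator and what it does (not) emulate

`simulation_params()` + `render_section()` generate sections as
non-overlapping spherical nuclei (radius 3 um) in the imaged volume.
Each cell draws a burst state per gene: marginal activation probability
`burst_prob[g]`, pairwise co-activation `coupling[g,h] * p_g * p_h`
(coupling 1 = independence, 0 = exclusion), with three-way co-activation
closed by the product of pairwise lifts. Parameter sets implying joint
probabilities outside [0, 1] are rejected — note that coupling 0.5 is
feasible only for marginals up to 2 - sqrt(2) ~ 0.59. Active cells place 1
or 2 allele spots uniformly inside the nucleus sphere. Rendering uses an
anisotropic Gaussian PSF (defaults 140 nm xy, 700 nm z), applies each
channel's true chromatic transform in reverse to its spot coordinates,
adds uniform-intensity DAPI spheres, extra-nuclear autofluorescent clutter,
and Poisson shot noise followed by Gaussian read noise. For statistical
calibration at large cell numbers, `simulate_spot_tables(placement =
"grid")` skips rendering and places nuclei on a jittered grid whose
spacing guarantees spots of different nuclei are separated by more than
1 um, so within-nucleus proximity is the only co-localization mechanism.

Deliberately **not** emulated: realistic PSF physics (Gibson-Lanni),
optical sectioning, photobleaching, tissue-shaped nuclei, tiling. Passing
tests on this simulator therefore validates the *algorithms* —
localization accuracy, registration, grouping, calibration of the null
models and tests — not robustness to every artifact of real tissue. Two
consequences worth knowing:

* The classical intensity detector cannot distinguish autofluorescent
  clutter from real nascent spots (the published workflow used a trained
  classifier plus intron probes for that). Detection-quality checks are
  run on clutter-free, single-allele sections at amplitude/noise >= 10;
  with two alleles the published 20 px mask spheroid merges allele pairs
  closer than ~2 um, which is a property of the method, not a detector
  bug.
* Clamped read noise leaves a small positive pedestal over the large
  extra-nuclear area of a DAPI sum projection. Background subtraction
  from a nucleus-free region (as the intensity-ratio cell-count method
  prescribes) removes it; skipping that step biases cell counts by ~10%.

## Chosen conditions for the statistical checks

Numbers were fixed by power analysis before running the checks, and the
same conditions are used by `scripts/acceptance.R`:

* Random-chance calibration: coordinate-level sections, single allele,
  3D distance frame. Independence arm: 5000 cells, burst 0.7 (expected
  ~10 doubles per section under model (b), `p_s ~ 0.0042`). Exclusion arm:
  coupling 0.5 requires marginals <= 0.59, so 20000 cells at burst 0.5
  (observed ~11 vs expected ~21 — a decisive gap for integer counts).
* End-to-end cohort: 30 nuclei per 33 x 33 x 19 um stack, two alleles,
  amplitude 400 / background 10, light clutter (0.5 per 1000 um^3),
  8-10 sections per genotype, wild-type burst 0.4 vs mutant 0.6 for one
  gene of three. This gives a standardized effect of ~2 on per-cell rates,
  comfortably detectable by a rank-sum test at n >= 8 sections while the
  unchanged genes stay non-significant.
* Distance recovery: 500 pairs at a true 350 nm separation, 15 nm
  localization jitter per axis, chromatic shift of several pixels on one
  channel; the corrected analysis must land within 3 bootstrap SE
  (~2-3 nm) of truth and the uncorrected one must not. A self-comparison
  control (one spot set observed twice with 30 nm jitter) peaks at the
  localization noise floor, the analogue of an intron/exon same-gene
  control.

## Numerical choices and edge cases

* Histogram bin width for distance fitting defaults to 25 nm over the
  0-1 um gate; the fitted peak moves by less than one bin across 15-40 nm
  bins (asserted in tests). Fitting uses binned counts; a kernel-based
  alternative was considered and not used because the binned fit is the
  simpler, published-style estimator.
* Fewer than 10 gated distances: the median is reported with a warning
  instead of a fit; a non-converging Gaussian fit falls back to the
  histogram mode and is flagged.
* Degenerate (collinear) bead layouts make rotation/scale unidentifiable;
  the estimator warns and records a translation-only fallback.
* The "peak reference" amplitude axis of the 2D histograms is the
  geometric mean of the two members' amplitudes normalized by its median
  over pairs — a package convention, documented rather than inherited.
* Rank-sum p-values are exact for tie-free samples with combined n <= 20
  and use the tie-corrected normal approximation otherwise; the F test
  always reports the larger variance on top so F >= 1 with a two-sided p.
* Problem sizes in the test-suite (section counts, replicate counts, cell
  numbers) are the package's chosen verification conditions; they keep
  every property decisively testable on a single CPU.

## Known limitations

* The detector is intensity-based; fields dominated by clutter need
  either intron-probe-style specificity upstream or a trained classifier
  (out of scope here, the segmentation detector `segment_spots` exposes
  the same contract if one is added).
* Absolute transcript counting from spot intensities is out of scope, as
  is burst-kinetics inference; the data do not identify those.
* One chromatic transform per acquisition configuration is assumed;
  field-dependent (non-affine) distortion is not modelled.
* ImageJ binary `.roi` files are not parsed; convert to the JSON polygon
  format upstream.
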