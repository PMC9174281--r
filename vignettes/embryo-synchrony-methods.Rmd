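---
title: "Quantifying division synchrony in preimplantation embryos"
author: "EmbryoSynchrony authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying division synchrony in preimplantation embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EmbryoSynchrony)
```

## The problem and the model

Cleavage-stage embryos divide in rounds: the zygote splits into 2 cells,
those into 4, 8, 16 and 32. Within one embryo the blastomeres of a round do
not divide at the same instant, and the degree of that asynchrony carries
prognostic information: embryos whose 4-to-8-cell blastomeres (the "third
duration") divide unevenly are more likely to abort after transfer. The
package quantifies this with a single per-embryo statistic, the
coefficient of variation of the four third-round blastomere durations,

$$\mathrm{CV}_3 = \frac{s(d_1,\dots,d_4)}{\bar d},$$

with $s$ the sample (n − 1) standard deviation. An embryo is classed
*high-CV* (asynchronous) when $\mathrm{CV}_3 \ge 0.15$, with the boundary
included in the high class. The companion statistics are the normalized
second-duration difference $|d_1-d_2|/\bar d$ for the two 2-cell
blastomeres and the fourth-round CV over eight durations.

The sample-SD convention matters: the 0.15 cutoff shifts if a population
(n) denominator is used. We use the n − 1 form, the default of the
statistical environment the analysis stack is written in.

## From image stacks to durations

The measurement chain has four stages, each usable on its own:

1. **Nucleus detection** (`detectFrame`). A 3D fluorescence frame is
   median-filtered (half-width `denoiseRadius`, default 1 voxel),
   background-subtracted by grey opening with a cubic element
   (`backgroundRadius`, default 12 voxels — the rolling-ball analogue),
   optionally passed through clip-limited global histogram equalization,
   z-bias corrected, thresholded, and split into per-nucleus labels.
   Centroids are reported in isotropic units (1 unit = the x pixel pitch,
   0.8 µm by default); the z coordinate is stored pre-scaled by
   dz/dx = 2.5, so dividing it by 2.5 recovers the slice index.
2. **Lineage linking** (`linkTracks`). Frames are joined by minimum-cost
   one-to-one assignment of centroids (Jonker–Volgenant). A count increase
   posits a division: the parent and the sibling observation are chosen
   jointly to minimize the distance from the parent's last position to the
   midpoint of its two putative daughters, including the cost of re-routing
   any track whose successor the hypothesis claims. Division times are the
   midpoint of the flanking frames, so a 10-minute frame interval bounds the
   timing error at 5 minutes.
3. **Morphokinetics** (`countCurve`, `stageDurations`,
   `synchronyProfile`). Counts are aligned so the first persistent
   1-to-2 transition is t = 0, cleaned to a monotone curve, and divided
   into intra-stage (2, 4, 8, 16, 32 cells) and inter-stage (3, 5–7, 9–15,
   17–31) durations. Per-round blastomere durations feed the CV statistics.
4. **Outcome statistics** (`compareGroups`, `twoProportionTest`,
   `rocAnalysis`, `cohortReport`). The test-selection policy mirrors the
   study design: Lilliefors (estimated-parameter Kolmogorov–Smirnov)
   normality at α = 0.05 on both groups, F-test on variances, then
   Student's, Welch's or the Wilcoxon rank-sum test, all two-sided.
   Proportions use the Yates-corrected chi-square two-proportion test;
   correlation uses Spearman mid-ranks.

## Numerical and design choices

Where the measurement procedure leaves latitude, the package fixes the
following, chosen once and documented here.

**Count-curve cleaning.** The cleaned curve is the running maximum of the
raw counts followed by a centred 3-point median (ends passed through). The
running maximum removes transient undercounts (nuclei dimming through
mitosis); the median smooths residual jitter while preserving
monotonicity. Applying the median *before* the running maximum fails the
intended behaviour on a 1-frame dip such as raw counts 2, 3, 2, 4, which
should clean to 2, 3, 3, 4.

**First-mitosis debounce.** t = 0 requires the 1-to-2 transition to
persist at least 2 frames, so a single flickering detection cannot anchor
the time base. A curve that never shows a fresh transition (e.g. a
recording starting at 4 cells) has no alignment and raises an error.

**Thresholding.** The automatic threshold is Otsu's, applied recursively:
nuclei occupy well under 1% of a volume, and on such unbalanced histograms
a single Otsu split falls inside the background mode. Re-estimating on the
above-threshold voxels until the foreground fraction is below 5% places the
threshold between noise and signal; at that occupancy background speckle no
longer percolates under 26-connectivity and the minimum-component filter
(default 64 voxels) removes it.

**Equalization.** Clip-limited global equalization is implemented behind
the `equalize` flag but ships off. On sparse fluorescence volumes the
equalization map is estimated from a noise-dominated histogram; it
rank-flattens nucleus interiors and stretches background, which fragments
labels and degrades thresholding. It remains available for data whose
dynamic range genuinely compresses dim nuclei.

**z-bias correction.** Each slice containing signal (voxels above 15% of
the volume maximum, at least 10 of them) is rescaled so its 99th-percentile
foreground intensity matches the brightest slice, with the factor capped at
20. Signal-free slices are untouched, so empty and z-uniform volumes pass
through unchanged (up to a unit factor).

**Subdivision.** A label's length and width are the extents along the
first two principal axes of its voxel cloud, measured in isotropic units.
Labels exceeding 1.5 times the median length or width are re-split by a
marker-based watershed on the anisotropy-aware Euclidean distance
transform; markers are distance maxima separated by at least half the
median width. The loop runs until no candidate remains or 10 iterations.

**ROC cutoff selection.** Candidates are every observed score and every
midpoint between adjacent scores; prediction is positive (abort) at or
above the cutoff. The default criterion is accuracy, ties broken toward
higher specificity and then the lower cutoff; Youden's J is available. Note
that a midpoint just below an attained score produces the same confusion
matrix as the score itself, so the selected *value* depends on this
candidate convention even when the selected *classifier* does not.

**Degenerate inputs.** Coincident points give distance CV 0 by definition;
all-coincident shapes are an error for Procrustes (no shape); identical
constant groups give p = 1 with a degenerate flag; tied-everywhere count
comparisons report p = 1.

## The synthetic embryo generator

Tests and the acceptance script run on synthetic cohorts from
`simulateCohort`, built to have the statistical structure the analysis
assumes:

* **Lineage timing.** Blastomere durations are log-normal with per-round
  mean and CV — strictly positive, and the CV maps directly onto the
  parameterization. Defaults: 18 h for the first round, 12 h thereafter,
  baseline CV 0.05 (a synchronous embryo); the third-round CV is the
  experimental dial. These are placeholder calibrations on the plausible
  scale for mouse, not estimates of any real dataset.
* **Motion.** Nuclei follow a Gaussian random walk (0.5 µm per 10-minute
  frame) reflected at a 30 µm embryo sphere, with excluded volume: nuclei
  are impenetrable 4 µm spheres and overlapping pairs are relaxed apart.
  At division the daughters separate by 1.1 nucleus diameters along an
  axis drawn toward free space. Without excluded volume a daughter can
  spawn coincident with an unrelated nucleus, which is physically
  impossible and makes parent attribution ill-posed for any tracker.
* **Imaging.** Nuclei render as isotropic Gaussian blobs (σ = 2 µm, peak
  1) sampled on the 0.8 × 0.8 × 2.0 µm voxel grid, attenuated by
  exp(−0.01 per µm of depth), plus additive Gaussian noise (SD 0.05)
  clipped at zero.
* **Outcome.** Abort probability is logistic in the true third CV,
  centred at 0.10 with slope 40, so embryos at or beyond the 0.15 cutoff
  have high abort odds. Both parameters are arguments.

What the generator does *not* emulate: fluorescence bleaching and focus
drift, cell death and fragmentation, mitotic nuclear-envelope breakdown
(nuclei simply persist to the division instant), chromosome-segregation
errors, and optical blur beyond a Gaussian. Passing tests therefore
demonstrate correct recovery under the stated model, not performance on
real microscopy; on real data the manual-correction pathway
(`applyManualCorrections`) exists precisely because detection errs.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 60 embryos for
parameter recovery (true third-CV grid 0–0.30), 4 embryos for
division-time recovery, and 20 rendered frames of 128 × 128 × 64 voxels
(2–16 nuclei) for detection accuracy. These sizes give stable statistics —
the recovery correlation and MAE change in the third decimal between
seeds — while a full run stays in the minutes range on one core.

## Known limitations

* Tracking assumes one embryo per observation table and tolerates at most
  2 consecutive frames of missing detections before flagging the embryo
  unanalyzable, mirroring the exclusion of uninterpretable recordings.
* Identity through the 16-to-32 transition is only as good as the
  fourth-duration statistic requires; no attempt is made to assign
  ICM/trophectoderm fate from positions.
* The Procrustes correspondence search is exhaustive only to n = 8
  landmarks; beyond that a greedy nearest-landmark initialization is used,
  which assumes modest rotations between configurations.
* Morphometric descriptors (distance CV, motility, Procrustes distance)
  have no published numeric anchors; they are validated against internal
  oracles and invariances only.
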