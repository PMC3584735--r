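---
title: "Quantifying HER2 amplification from dual-probe FISH images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HER2 amplification from dual-probe FISH images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishratio)
```

## The measurement problem

In dual-probe HER2 FISH, a breast-cancer tissue section is hybridized with a
Spectrum Orange probe against the *HER2* locus and a Spectrum Green probe
against the chromosome-17 centromere (CEP17), with a DAPI counterstain
marking nuclei. Each scorable nucleus shows a small number of orange and
green spots; the clinically decisive quantity is the ratio of average HER2
to average CEP17 copy number,

$$ r = \frac{\sum_i h_i}{\sum_i c_i}, $$

where $h_i$ and $c_i$ are the spot counts of sampling unit $i$. A case is
called **nonamplified** when $r < 1.8$, **amplified** when $r > 2.2$, and
**equivocal** in the closed band $[1.8, 2.2]$; equivocal cases with
$r \ge 2.0$ are flagged as potential candidates for targeted therapy. The
band edges are inclusive on both sides: a case at exactly 2.2 is borderline
equivocal, not amplified. Dividing the pooled totals is algebraically
identical to dividing the per-unit averages and avoids divisions by zero in
sparse units.

fishratio implements two samplers over this model:

* the **tile-sampling classifier** counts spots inside non-overlapping
  71-pixel squares placed where the counterstain is densest, rejecting
  tiles with under 40% nuclear coverage or with at most one fluorescent
  signal, and rejecting cases with fewer than 32 accepted tiles; and
* the **nuclei-sampling classifier** segments individual DAPI nuclei,
  accepts those with area between 12 and 400 µm², sufficient roundness, and
  at least one signal of each color, and supports the five human-correction
  edits (add, select, delete, split, merge), recomputing the ratio after
  every edit.

## Spot detection

Both channels pass through the same enhancement chain before any gate is
applied: Gaussian smoothing (σ = 0.1 µm), a white top-hat with a disc
structuring element, and Laplacian sharpening clipped at zero. Two
numerical choices here deserve explanation.

*Top-hat element size.* The disc radius defaults to 1.0 µm. Single probe
signals are 0.2–0.5 µm across and pass untouched, while nuclear-scale
background (~9 µm) is removed. The radius is deliberately larger than the
largest single spot because homogeneously staining regions (HSR) — fused
clusters of HER2 signal roughly 1–2 µm across — must also survive the
filter: area-mode counting (below) is impossible if the morphology erases
cluster interiors.

*Sharpening instead of a pure second-derivative response.* The final step
is $\max(0,\, t - \nabla^2 t)$ on the top-hat output $t$. A pure
Laplacian-of-Gaussian response of a compact object concentrates at its rim,
which would destroy the correspondence between an object's thresholded
area and its physical area; the sharpening form keeps blob support intact
(flat backgrounds still map to zero, and a blob's maximum stays at its
centroid), so area gates and HSR area-mode both operate on meaningful
areas. Morphology is computed on a replicate-padded raster so image borders
introduce no artificial response.

A spot is then a connected component of the enhanced image at or above
`intensity_frac` × the channel's *reference maximum*, with thresholded
area at least `min_area_um2`; components whose centroids fall closer than
`min_distance_um` are merged into one spot (single-linkage, conserving
total signal). The validated channel defaults are 0.05 µm² / 0.8 µm / 33%
for HER2 and 0.18 µm² / 0.5 µm / 30% for CEP17. Two interpretation
decisions were open:

* The percentage intensity threshold is taken as *relative* — the 99.9th
  percentile of positive enhanced intensities serves as a robust maximum —
  since an absolute camera level would not transfer across exposures.
* The distance gate *merges* near objects rather than discarding the
  weaker one; merging conserves total signal and matches how a human
  scores an unresolved doublet.

Detection runs inside the counterstain mask only: signal outside nuclei is
artifactual, and both classifiers sample nuclear material. The mask itself
is Otsu-thresholded smoothed DAPI with holes filled and specks under 2 µm²
removed.

### HSR area mode

When HER2 amplification presents as HSR, individual spots cannot be
resolved and counting switches to signal area: an object whose area
exceeds `hsr_factor` (default 4) times the reference single-spot area is
converted to `round(area / ref_area)` spot-equivalents (at least 2), and
the case is QC-flagged `hsr_mode_used`. The reference area is the median
area of non-cluster spots in the same case, falling back to 0.15 µm² when
fewer than five isolated spots exist. The converted equivalents are
approximate — thresholded cluster area grows with blur and threshold
choice — but amplified-with-HSR cases sit far above the 2.2 boundary, so
the category call is insensitive to this approximation.

## Tile placement

Candidate tile origins form a stride-8 lattice united with the exact
tiling lattice of stride `tile_px`; candidates are ranked by descending
mask coverage, ties broken row-major, and accepted greedily under
non-overlap — a deterministic realization of "as much nuclear material and
as little empty space as possible". Greedy selection can occasionally be
blocked below the plain exact-tiling grid, so the placement keeps
whichever of the two covers more mask (ties favor greedy). Zero-coverage
candidates are never emitted. Spots are assigned to tiles by half-open
pixel boxes, so a spot on a shared border is counted exactly once. The
coverage boundary is inclusive (a tile at exactly 40% is kept), and "only
one fluorescent signal" is implemented as *total signal ≤ 1*: a
zero-signal tile cannot inform either average, so it is equally rejected.

## Nucleus segmentation and editing

Connected mask components become nuclei directly unless their shape
indicates touching cells — solidity below 0.9 or area above 1.5× the
expected single-nucleus area (64 µm² by default) — in which case the
component is split by seeded region growing on the smoothed distance
transform, with seeds at distance maxima at least 2 µm apart. Roundness is
circularity $4\pi A / P^2$ with an acceptance threshold of 0.60; the
signal-quality gate (at least one spot of each color) mirrors the nucleus
eligibility rule a technologist applies during manual scoring.
Border-touching regions are never auto-accepted. Cases need at least 20
accepted nuclei — the manual-scoring minimum; the automated analogue is
not separately standardized, so the default mirrors it and is
configurable.

The five correction edits operate on a label raster and a replayable
journal. `add` rasterizes a user polygon into a `user_added` nucleus and
deliberately bypasses all gates — the interactive phase exists precisely
to override the classifier; it may claim background pixels and pixels of
deleted nuclei. `split` carves the region along a polyline and reassigns
the carved pixels to the nearest part, so split/merge sequences conserve
spot counts exactly. Every edit triggers a result recomputation; invalid
edits fail with an explanatory error and leave the state untouched.

## The synthetic-field generator

Real accessioned specimens are not distributable, so validation runs on
synthetic fields that emulate the study's imaging conditions: 1088 × 880
pixel 8-bit channels at a default calibration of 0.16 µm/px (the capture
calibration is not standardized; 0.16 µm/px makes a 71-px tile ≈ 11.4 µm,
the size of one to two nuclei, and is prominently configurable). Fields
contain elliptical nuclei (equivalent diameter 9 ± 1 µm), per-nucleus
planted spot positions, optional HSR clusters, optical blur (0.1 µm), and
additive Gaussian noise (σ = 3 grey levels), with 8-bit quantization
applied last so noise statistics are honest.

Design points that matter for interpreting validation results:

* **Per-nucleus counts are zero-truncated Poisson**, with the rate solved
  so the mean equals the configured λ (`ztpois_rate()`). Every tumor
  nucleus carries at least one copy of HER2 and of chromosome 17; a zero
  observed count in real data is a detection artifact, not biology. This
  also keeps the ≥1-of-each acceptance gate from biasing the accepted-set
  ratio away from the planted ratio.
* **Planted truth is what was rendered.** Same-channel spots are kept at
  least 1.2× the channel merge distance apart, field-wide, so the planted
  count equals the detectable count; in the rare event a position cannot
  be placed, the ground-truth count is decremented rather than left
  inconsistent. The planted case ratio is the ratio of realized totals.
* **Cohort presets**: nonamplified (λ_H = λ_C = 2), amplified (λ_C = 2,
  12-copy HSR clusters in 80% of nuclei, λ_H = 8 in the remainder),
  amplified-without-HSR (λ_H = 8, λ_C = 2), and equivocal (λ_H = 4,
  λ_C = 2, with cases redrawn until the realized ratio lies inside
  [1.8, 2.2], making the planted label equivocal by construction).
  Cohort cases default to one field of 60 nuclei; field pooling is linear
  and exercised separately.

What the generator does *not* emulate: stromal texture, autofluorescence
gradients, sectioning artifacts, dense nuclear packing beyond the
configurable overlap fraction, or aneuploid populations (a λ_C knob exists
but defaults off). Passing synthetic validation therefore demonstrates
correctness of the counting and sampling machinery under controlled truth,
not robustness to every tissue-quality failure mode — the same caveat the
interactive correction phase exists to address on real material.

## Validation experiments and problem sizes

The test suite recovers every configured engine parameter purely from
behavior: bisection over the classifier recovers the 1.8 and 2.2
boundaries; sweeps recover the 71-px tile side, the 32-tile case-rejection
boundary, the 40% coverage boundary, the 12 and 400 µm² nucleus gates, the
HER2 merge distance (largest still-fused separation, 0.79 µm on a 0.01 µm
sweep), and the CEP17 minimum area (0.18 µm² on a 0.01 µm² grid). Spot
counts are checked against an independent brute-force oracle (threshold,
4-connected components, area filter, transitive centroid merge) on 200
random fields. Ratio recovery uses 60-nucleus cases at 880 × 800 px (25
seeds per target ratio in {1, 2, 3, 5}, error ≤ 0.2 required in ≥ 90%),
and the cohort experiment analyzes 32 full-size nonamplified cases at a
fixed seed, requiring full concordance with the planted labels. These
sizes were chosen to exercise full-scale geometry where it matters (the
cohort) while keeping the sweep-style experiments compact.

## Known limitations

* HSR spot-equivalents are approximate (see above); ratios of HSR cases
  are upper-bounded usefully for categorization but are not copy-number
  estimates.
* Segmentation accuracy degrades with heavy nuclear overlap, as it does
  for the interactive workflow this package emulates; the watershed
  splitter is tuned for moderate (≤ 30%) overlap.
* No chromatic registration, deconvolution, or z-stack handling; channels
  are assumed co-registered.
* The mixed-cell-population ratio-estimation refinement referenced by the
  original system is proprietary and is not reimplemented.
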