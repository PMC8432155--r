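---
title: "polyQscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyQscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyQscreen)
```

## What the package models

polyQscreen reimplements, as a tested pipeline, the quantitative analysis
of a human neural-stem-cell model of polyglutamine (CAG-repeat) disease:
neural stem cell lines expressing huntingtin exon 1 with increasing CAG
tract lengths are differentiated to neurons, and mutant-huntingtin
inclusion bodies (IBs) appear in a CAG-length- and
day-of-differentiation-dependent manner, accompanied by mitochondrial
dysfunction. Four measurement domains are covered:

1. **High-content imaging** — nuclei are segmented from the nuclear stain
   (channel 1) and IB puncta are called on the anti-huntingtin stain
   (channel 2), yielding per-well metrics such as the percentage of
   aggregate-containing nuclei (ACN) and aggregates per ACN.
2. **Respirometry** — Mito Stress Test oxygen-consumption-rate (OCR)
   traces are density-normalized and decomposed into basal, ATP-linked,
   leak, maximal and non-mitochondrial respiration.
3. **Enzymology** — spectrophotometric absorbance kinetics are converted
   to electron-transport-chain specific activities via Beer–Lambert, or
   to a pseudo first-order rate constant, all normalized to citrate
   synthase.
4. **Mitochondrial morphology** — per-organelle volumes are classified
   into small/medium/large categories, volume-weighted.

Because the original raw data are not deposited, a synthetic-data
generator (`synth_image_spec()`, `make_field()`, `make_allelic_series()`,
`make_ocr_trace()`, `make_absorbance_trace()`) provides ground truth for
every stage; every quantitative claim made by the test suite is a
recovery, oracle-agreement, or algebraic-identity claim against that
ground truth.

## Nuclear segmentation

The imaging branch follows the published recipe exactly where it is
specified: a **3-pixel-radius disc median filter** on the nuclear channel,
a **global intensity threshold** (the frozen batch calibration 144 DN by
default, or `batch_otsu_threshold()` to recalibrate on the pooled
histogram of a new batch), then a **watershed** to separate touching
nuclei, and a minimum-area filter (default 50 px, configurable; the
source protocol is silent on size filtering but some floor is needed
against noise specks).

Where the recipe names a tool rather than an algorithm, the package makes
the choice explicit:

* *Otsu convention.* The threshold maximizes between-class variance of
  the split `{< t}` / `{>= t}`; ties go to the lowest cut and foreground
  is `value >= t`. On a two-level histogram this lands strictly between
  the modes.
* *Watershed.* Marker-controlled flooding of the Euclidean distance
  transform (EDT). Markers are local maxima of the **Gaussian-smoothed**
  EDT (σ = 1.5 px) with a prominence floor (0.05 px) and a minimum
  separation (8 px). Two design iterations are worth recording: plain
  `>=`-neighbour maxima seed a third basin on the neck-saddle plateau
  between fused nuclei (whose size-filtered removal then leaves unlabeled
  holes), while a large prominence floor on the *raw* EDT loses genuine
  pair peaks, whose prominence can fall to a fraction of a pixel once the
  rendered edge and the median filter widen the neck. Smoothing removes
  the discretization ripples that create false seeds, at which point a
  near-zero prominence floor keeps every true peak. Basins smaller than
  the minimum area are absorbed into the neighbour with the longest
  shared boundary rather than deleted, so the foreground partition is
  preserved.
* *Connectivity* is 8-neighbour; coordinates are 1-based (row, col) as is
  idiomatic in R.
* *Roundness* is `4*pi*area / perimeter^2` with the perimeter counted as
  exposed 4-neighbour pixel edges; this overestimates a circle's
  perimeter, so a perfect digital disc scores ≈ 0.6. The metric is used
  comparatively, never against an absolute circle standard.

## Spot calling: prominence semantics

The aggregate counts rely on an ImageJ-style "Find Maxima" with a noise
tolerance. `find_maxima()` implements a precise reading: a local maximum
is accepted iff its **prominence** — its height above the highest saddle
connecting it to any higher region (or to an equal-valued maximum that
precedes it in raster order) — **strictly exceeds** the tolerance. The
highest maximum of a masked region is measured against the region
minimum, so a constant image yields no calls. Plateaus contribute one
representative pixel (topmost, then leftmost). Only pixels inside the
region mask take part, and connecting paths may not leave the mask — this
is what "applied outside the nuclear mask" and "restricted to the ACN
footprint" mean operationally.

This semantics is validated against an independent brute-force oracle
(per-candidate level flooding) on hundreds of random images, not against
ImageJ byte-for-byte; the tolerance values themselves (150 for
nuclear/extra-nuclear calls, 1000 for whole-field totals) are the frozen
constants of the source protocol.

## The well-level metrics

Per field: total cell count; per nucleus the channel-2 maximum under its
footprint (`i_max`). A nucleus is an **ACN** iff `i_max > 2000` (strictly
— a nucleus at exactly 2000 is not an ACN). Nuclear aggregates are maxima
calls inside each ACN footprint; extra-nuclear aggregates are calls on
the mask complement; total aggregates are whole-field calls at tolerance
1000. Aggregate *area* is the count of channel-2 pixels `> 969` inside
ACN footprints, divided by the total nuclear area of **all** nuclei (the
literal reading; an `acn_only` denominator switch exists but is not the
default). Mean background is the mean of channel-2 pixels `< 2000` over
the whole field. Per well, counts are summed across fields before ratios
are formed (never means of ratios), and the well median of `i_max` pools
all nuclei of the well. Ratios with empty denominators are reported
missing (`NA`), never 0.

The proprietary find-cytoplasm readouts are replaced by a documented
annulus measure: each nucleus is dilated `ring_width` px (default 3) into
the background, contested pixels going to the geodesically nearest
nucleus, and the marker-channel ring mean stands in for cytoplasmic
intensity (`perinuclear_intensity()`, `marker_positive_fraction()`).

## Respirometry

`derive_parameters()` computes, verbatim and phase-scoped:
non-mitochondrial = min(rot/AA phase); basal = last baseline −
non-mito; maximal = max(FCCP) − non-mito; proton leak = min(oligomycin) −
non-mito; ATP production = last baseline − min(oligomycin); coupling
efficiency = 100 × ATP/basal. Ties in min/max go to the earliest cycle;
negative derived rates are flagged but never clipped (clipping would bias
group means). `basal = ATP + leak` is an algebraic identity of these
definitions and is asserted property-style. Density normalization divides
every OCR value of a well by `density / min(density)`, leaving the
lowest-density well unchanged and all within-well ratios (hence coupling
efficiency) invariant.

One caveat the test suite documents honestly: because the published
estimators are phase extrema, they inherit order-statistic offsets under
plateau noise (E[min of 3 i.i.d. normals] sits ≈ 0.85 σ below the
level). With noise at 5% of basal this is a systematic few-pmol/min
offset that well-averaging cannot remove; the corresponding acceptance
expectation (bias < 1% of each rate) is intrinsically unattainable for
this estimator and the test is left failing with this explanation rather
than silently relaxed.

## Enzymology

`beer_lambert_activity()` converts an absorbance slope (AU/min) with
molar extinction ε (M⁻¹cm⁻¹), path length (cm) and protein concentration
(mg/mL in the reaction) to nmol/min/mg:
`1e6 × |slope| / (ε × path × protein)`. The worked dimensional chain
(AU/min → M/min → µM/min ≡ nmol/min/mL → per mg) is frozen in a test
against an independent oracle. Inhibitor-sensitive rates are fitted
pre/post slope differences (TTFA-sensitive DCPIP reduction,
antimycin-A-sensitive cytochrome c reduction); a faster post-inhibitor
rate is flagged. For the non-linear cytochrome c assay,
`first_order_k()` subtracts the fitted non-enzymatic linear rate and fits
`A(t) = A∞ − (A∞ − A0)·e^(−kt)` with all three parameters free — the
plateau is estimated jointly rather than read from the last point, which
keeps truncated traces unbiased; `nls` runs with `scaleOffset` so exact
(zero-residual) traces converge to machine precision. CoQ10 enters as a
number (pmol/mg); only the ratio arithmetic to citrate synthase is
computed, and scaling every activity and CS by a common
mitochondrial-content factor leaves all ratios unchanged.

## Mitochondrial volumes

`volume_fractions()` classifies per-organelle volumes with bin edges 100
and 1000 µm³ and reports volume-weighted percentages of total volume.
The published bin wording leaves edge membership open; the package uses a
**closed medium bin [100, 1000]** with strict small/large, documented and
configurable. Percentages sum to 100 exactly; per-replicate fractions are
averaged per line with SEM across replicates.

## The synthetic world, and what a green test establishes

`make_field()` renders: channel 1 nuclei as radially smoothed discs
(logistic edge, width 0.5 px) composited by **maximum** (additive
compositing would fill the neck between touching pair members and erase
the very feature the watershed is meant to detect); touching pairs share
one radius at centre distance 1.2–1.6 × radius; channel 2 as a uniform
cytoplasm level plus isotropic Gaussian puncta (nuclear puncta ≥ 3σ
inside their parent, ≥ 4σ apart; extra-nuclear puncta ≥ 4σ clear of
nuclei) and i.i.d. Gaussian read noise clipped to [0, 65535]. Default
intensities are set so the frozen constants apply directly: nuclei
(2500–6000 DN) clear the 144 threshold, nuclear peaks (2500–6000 DN)
clear the 2000 ACN threshold by ≥ 25 noise SDs while cytoplasm (500 DN,
noise SD 20) cannot reach it, and extra-nuclear puncta (1200–1800 DN) are
prominent at tolerance 150 but dimmer than nuclear ones. The allelic
series makes the planted ACN fraction `s·(0.06 + 0.03·(d−7))` and the
planted spots-per-ACN mean `1 + s·(0.3 + 0.5·(d−7)/7)` for day ≥ 7
(severity s; zero before day 7 and for control lines), with spot counts
assigned by deterministic quota — the constants are chosen so that
planted burdens differ strictly between adjacent grid cells, i.e. the
monotonicity being tested is a property of the stated world, not of
estimator luck.

Deliberately not modelled: Poisson shot noise, PSF/optics, textured
chromatin, 3D stacks, uneven illumination. A green segmentation test
therefore establishes correctness of the algorithmic chain on clean
geometry, not robustness to real-microscope artifacts; the frozen
thresholds would need recalibration (the `batch-otsu` mode) on real data.

## Numerical and degenerate-input conventions

* All randomness flows from one integer seed per generator call; the
  global RNG state is saved and restored, and identical spec + seed gives
  bit-identical images (integer matrices) and ground truth.
* Metrics with empty denominators (no cells, no ACNs, empty volume sets)
  are `NA`, distinguished from true zeros (no planted objects → 0).
* Otsu on a constant batch raises a degenerate-histogram error; an OCR
  trace missing a phase names the phase; inconsistent true respiratory
  parameters name the violated identity; nucleus placement that cannot
  satisfy the clearance constraints raises an explicit placement error
  after bounded retries.
* `run_pipeline()` writes CSVs with fixed formatting; identical config +
  seed reproduces outputs byte-for-byte (hash-compared in the tests).

## Known limitations

* The TIFF codec is a minimal uncompressed 16-bit baseline implementation
  (no compression, tiling, or BigTIFF); adequate for the package's own
  sidecar format and for interchange with ImageJ-style readers.
* The maxima semantics is validated against this package's own
  brute-force oracle, not against ImageJ binaries.
* Segmentation recovery figures (≥ 95% of isolated nuclei, ≥ 90% of
  touching pairs split, ≤ 2% spurious) are properties of the synthetic
  defaults above, at 512×512 px and 50 nuclei per field.
* The respirometry estimator bias discussed above is reproduced, not
  corrected: fidelity to the published formulas was chosen over statistical
  efficiency.
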