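---
title: "Quantifying Notch/Bazooka clusters at the SOP daughter interface"
author: "sopquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Notch/Bazooka clusters at the SOP daughter interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopquant)
```

## The measurement problem

After the asymmetric division of a *Drosophila* sensory organ precursor
(SOP), Notch signalling between the pIIa and pIIb daughters is organised at
their new shared interface, where the receptor and the polarity protein
Bazooka concentrate in small bright clusters (0.03-0.2 µm² puncta).
`sopquant` implements the complete quantification chain used to study this
system on live two-channel confocal stacks:

1. **Interface intensity over time** — kymographs from a wide line across
   the interface, with reference-region photobleaching correction.
2. **Cluster counting** — a deterministic re-implementation of the
   inter-nuclear counting macro (nucleus segmentation, ovoid search region,
   Rényi-entropy autothreshold, particle analysis, calibrated size and
   intensity filters).
3. **Colocalisation of cluster tracks** — Costes autothresholds and
   thresholded Manders coefficients on two-channel kymographs.
4. **FRAP** — single-exponential recovery fits yielding the half-time and
   mobile fraction, and group ratios.
5. **Region quantification** — fixed-size apical/lateral interface ROIs
   normalised to epidermal references.
6. **Statistics** — the F-test-then-t-test convention with significance
   stars.

Because no raw imaging is publicly deposited for this system, the package
ships a first-class synthetic-data generator with planted ground truth;
every stage is validated end to end against what was planted.

## Interface kymographs and bleaching correction

A line of width 30 px (the default) is traced across the pIIa/pIIb
interface on a z-projection that sums three slices 0.5 µm apart
(`sum_project()`). `build_kymograph()` samples the line at 1-px arc-length
spacing and averages across the width; a 20-px band around the interface
column (`interface_profile()`) gives the raw per-frame intensity.

Photobleaching is corrected with three reference regions around the cell:
the per-frame correction factor is `bg_mean(t0) / bg_mean(t)` and the
corrected series is then normalised to `bg_mean(t0)`
(`correct_and_normalize()`). Because signal and reference share the frame's
illumination, multiplying every frame by any positive scalar series leaves
the normalised series unchanged (verified to 1e-9 relative in the tests).

Choices where the protocol leaves room:

* **Width aggregation is the mean**, not the sum, matching the common
  wide-line plot-profile behaviour; with width 1 the kymograph reduces to
  the single-pixel profile.
* **The 20-px band is centred on the per-frame argmax column**, smoothed
  over time with a running median — the original band was drawn by hand.
  A caller-supplied centre overrides this.
* **The apical mean is the mean of the three region means** (not the
  pooled-pixel mean); the two differ only when regions have unequal areas.
* **t0 is the first supplied frame**; anaphase onset is identified by the
  caller, not detected from cell shape.

## The cluster-counting macro

`count_timecourse()` runs, per frame: Otsu segmentation of the two nuclei
(two largest 8-connected components, holes filled), a quality-control check,
an ovoid search region, Rényi-entropy autothresholding inside it, particle
analysis, and the calibrated filters.

* **QC.** Frames are excluded (status, zero clusters) when the nuclei are
  too close (minimum boundary gap < 3 px) or stacked axially rather than
  face to face (xy bounding-box overlap > 0.3 with axial offset > 1.5 µm).
  The thresholds are package defaults — the protocol names the two failure
  modes without numbers — and are exposed as arguments.
* **Ovoid.** A filled ellipse centred between the nuclear centroids, major
  axis along the centroid line: the semi-major axis is the maximal axial
  pixel extent plus a 3-px margin, the semi-minor axis the smallest value
  containing every nucleus pixel. This deterministic construction contains
  both nuclei by definition; subtracting them leaves the inter-nuclear
  search region.
* **Rényi-entropy threshold.** `renyi_threshold()` implements the
  three-order combination of Sahoo, Wilkins and Yeager: candidate
  thresholds maximising the summed background/foreground Rényi entropies at
  α = 1/2, 1 (Shannon limit) and 2 are blended with β-weights chosen by
  whether consecutive candidates fall within 5 gray levels. The histogram
  has 256 equal-width bins over the min-max range of the ROI pixels; pixels
  strictly above the returned level are foreground. The implementation is
  vectorised over cumulative sums and is checked in the tests against an
  independent per-threshold brute-force oracle (exact agreement on 100
  random histograms).
* **Particles and filters.** 8-connected components above threshold inside
  the ROI; each particle carries its pixel count, area, and the mean of the
  *original* intensities. The filters keep areas in [0.03, 0.2] µm²
  (inclusive; a 1e-9 µm² tolerance absorbs the binary representation of the
  decimal bounds) and mean intensities of at least
  `0.2654 × apical mean + 227.6` a.u. Mean (not integrated) intensity is
  used; the filter is idempotent and monotone in its parameters.

The apical mean driving the intensity threshold is an input (typically the
bleach-corrected apical series at the same frame), keeping the stages
orthogonal.

## Colocalisation on kymographs

`kymo_coloc()` applies `costes_autothreshold()` — orthogonal
(total-least-squares) regression of channel 2 on channel 1, then a
downward scan of T1 through the distinct channel-1 values with
`T2 = a·T1 + b`, stopping at the largest T1 whose below-threshold pixels
are uncorrelated (r ≤ 0) or too few (< 10) — followed by
`manders_above_threshold()`:

$$tM_1 = \frac{\sum_i \mathrm{ch1}_i\,[\mathrm{ch2}_i > T_2]}{\sum_i \mathrm{ch1}_i},
\qquad
tM_2 = \frac{\sum_i \mathrm{ch2}_i\,[\mathrm{ch1}_i > T_1]}{\sum_i \mathrm{ch2}_i}.$$

Both coefficients are reported with their mean as the headline value, since
a single per-kymograph coefficient is ambiguous between the two directions.
The PSF setting (4.0 px) enters only as the block size of the optional
Costes block-randomisation significance test (blocks of channel 1 are
shuffled; p is the fraction of shuffles whose Pearson correlation reaches
the observed one). Two numerical notes: candidates whose below-threshold
set has not yet reached 10 pixels are skipped rather than treated as a
stop, which keeps the scan well-defined for anticorrelated channels; and
orthogonal regression is not exactly equivariant under rescaling one axis,
so rescaling a channel moves the thresholds slightly — the Manders
coefficients themselves stay put to within 0.02 on the test fixtures.

## FRAP

`fit_recovery()` fits the minimal model yielding the two reported
quantities,

$$I(t) = I_\mathrm{post} + (I_\mathrm{plateau} - I_\mathrm{post})\,
         (1 - e^{-(t - t_\mathrm{bleach})/\tau}),$$

by Levenberg-Marquardt least squares, with `t1/2 = τ ln 2` and mobile
fraction `(I_plateau − I_post)/(I_pre − I_post)` (clipped to [0, 1] with a
warning). Initial guesses come from the first post-bleach frame, the last
three frames, and the time to half recovery. A flat post-bleach trace is
reported as mobile fraction 0 with undefined τ rather than a spurious fit.
No acquisition-bleaching correction is applied inside the fit; callers may
pre-correct. `group_ratio()` compares groups as ratios of means —
`mean(1/t1/2)` for recovery speed and `mean(mf)` for the mobile pool.

At 5% noise (of the bleach dynamic range) and 2-s sampling of 60 recovery
frames, the fit recovers τ with a median error near the 10% mark — this is
the information limit of a single-exponential fit under those conditions,
not an estimator defect; the estimator is unbiased.

## Region quantification

Apical measurements sum three planes at the adherens-junction level;
lateral measurements sum **all** planes 3-6 µm below the apical plane
(inclusive; seven planes at 0.5-µm steps). The protocol sentence is
ambiguous about the lateral plane count, so the full window is the default
with `lateral_planes` as an override. The mean is taken in a 1 × 3 µm
(apical) or 1 × 4 µm (lateral) rectangle whose long axis follows the
caller-supplied interface direction, and normalised to the mean of
neighbouring epidermal interface values.

## Statistics

`f_then_t()` runs a two-sided F test of variance equality and then a
pooled-variance Student's t test when the F test does not reject at 0.05,
or Welch's t test when it does (the standard spreadsheet workflow the
convention describes leaves the failed-F branch unstated). Stars: `ns`
p ≥ 0.05, `*` p ≤ 0.05, `**` p ≤ 0.01, `***` p ≤ 0.001 — the strongest
label wins, so exactly 0.05 is `*`. Under the null the empirical type-I
rate over 2,000 simulated pairs (n = 10) sits at the nominal 0.05 in the
test suite. No multiple-testing correction is applied, matching the
reporting convention.

## The synthetic-data generator

`generate_timelapse()` renders the study geometry — two nuclear ellipses
flanking a bright interface in a 256 × 256 px field at 0.05 µm/px, nine
z-slices 0.5 µm apart — plus planted puncta, exponential photobleaching and
a shot/read noise model (`Poisson(I·s)/s + N(0, σ)`). Design choices:

* **Puncta** occupy the `round(area/px²)` pixel centres nearest their
  centroid with a Gaussian radial profile (σ = equivalent radius), so the
  rendered connected area matches the requested area to within half a
  pixel (well inside the 15% contract) and detection is not confounded by
  rendering error.
* **Intensity scale.** Background ~100 a.u., apical reference ~500 a.u.,
  punctum peaks 2000-3000 a.u., so the printed intensity-threshold formula
  (intercept 227.6 a.u.) is exercised at realistic magnitudes. The absolute
  a.u. scale of the original instrument is unknowable from the printed
  formula alone; this scale is a stated choice, not a reconstruction.
* **Coloc kymographs** place Gaussian tracks (truncated at 3σ) on a spaced
  lattice so tracks never overlap, share a `co_fraction` of positions
  between channels, and quantise intensities to integer counts over zero
  background, as a photon-counting detector would. This makes the
  identical-support and disjoint-support limits exact and keeps the Costes
  candidate scan cheap.
* **FRAP traces** follow the single-exponential model exactly before noise,
  with 5 pre-bleach and 60 post-bleach frames at 2-s intervals.

What the generator does **not** emulate: optics-accurate PSFs, 3-D
deconvolution ground truth, cell-shape dynamics, drifting interfaces,
autofluorescence gradients, or detector nonlinearity. Passing the recovery
suites therefore demonstrates the correctness of the computations under the
stated imaging model, not robustness to every artefact of real microscopy.

## Problem sizes and determinism

The validation suites use 100 seeded 256 × 256 scenes for count recovery
(0-10 planted puncta per scene, shot noise plus 15 a.u. read noise),
100 random histograms for the threshold oracle, 50 seeded noisy traces for
FRAP, and 2,000 null pairs for the type-I rate. Every random quantity is
generated under an explicit seed through the acquisition model, and
identical seeds reproduce stacks bit for bit.

## Known limitations

* Nucleus segmentation assumes exactly two nuclei dominate the nuclear
  channel; crowded fields need caller-supplied ROIs.
* The Costes scan inherits the known fragility of orthogonal regression for
  anticorrelated or near-constant channels; degenerate cases stop the scan
  and are reported rather than extrapolated.
* The interface column tracker follows the argmax ridge; it does not
  register lateral drift of the line itself across frames.
* Star thresholds and the F-test branching reproduce a fixed reporting
  convention; they are not a recommendation for new study designs.
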