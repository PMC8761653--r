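---
title: "Estimating glycocalyx thickness from sidestream dark-field video: models and methods"
author: "glyx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating glycocalyx thickness from sidestream dark-field video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyx)
```

## The measurement problem

Sidestream dark-field (SDF) videomicroscopy images the microcirculation with
green light (~540 nm) that haemoglobin absorbs, so flowing red-blood-cell
(RBC) columns appear as dark bands on a bright background.  The endothelial
glycocalyx lining the vessel wall excludes RBC from a boundary zone next to
the wall; RBC only transiently lateralise into it.  Its thickness is
therefore estimated *indirectly* from the statistics of RBC column widths
observed over a short clip (conventionally 40 frames):

* **P50** — the median of the pooled RBC column-width distribution;
* **Dperf** (perfused diameter) — the outer limit of RBC lateral excursion,
  obtained by extrapolating the cumulative width distribution;
* **PBR** (perfused boundary region) — `(Dperf − P50) / 2`.

A *larger* PBR means RBC penetrate closer to the wall, i.e. a *thinner*
glycocalyx.  Alongside PBR the pipeline reports valid vessel density (VVD,
µm of valid 10 µm segments per mm² of field) and the percentage of segments
with RBC present in all frames (% RBC filling), both measures of perfusion.
The identity `Dperf = 2·PBR + P50` holds by construction and is asserted
throughout the package to machine precision.

## Pipeline

1. **Frame quality control** (`frame_qc`).  Rigid displacement of each frame
   from the stack's pixelwise median frame is estimated by FFT
   cross-correlation after demeaning; the search is confined to a window
   around zero displacement because layouts with near-periodic vessel
   spacing produce correlation side lobes at the spacing, and a distant peak
   is only accepted when it clearly dominates (a genuinely displaced frame).
   Sharpness is gradient energy; the default floor adapts to half the median
   across frames.  Only accepted frames are analysed.
2. **Vessel detection** (`detect_vessels`).  The frame is inverted,
   Gaussian-smoothed and thresholded (Otsu); connected components become
   vessel candidates.  Within a component the centerline is traced by
   binning along the component's dominant image axis and taking the
   intensity-weighted transverse centre per bin; tip columns whose contrast
   falls below half the component median are trimmed, and the centre track
   is smoothed with a spline (the per-bin jitter is pixel noise whereas real
   centerlines are smooth at the multi-micrometre scale).  Local diameter is
   read as the full width at half depth (FWHD) of the transverse intensity
   profile.  Vessels whose median diameter reaches 30 µm are excluded,
   matching the instrument's working range.
3. **Segmentation** (`partition_segments`).  Centerlines are cut into
   consecutive 10 µm segments from the start; a trailing remainder below
   10 µm is discarded so every segment carries exactly 20 minor markers at
   0.5 µm spacing.
4. **Validity** (`assess_validity`).  Each minor marker is probed with a
   transverse profile; its relative depth is `(background − minimum) /
   background` with the background taken from an annulus 2–4 vessel radii
   out, on the min–max-normalised frame (normalisation makes the decision
   invariant to affine intensity rescaling).  A marker is sufficient at
   depth ≥ 0.3 (configurable — the vendor's criterion is not public), and a
   segment is valid when *strictly more than* 60% of markers are
   sufficient: 13/20 is valid, 12/20 is not.
5. **Column measurement** (`measure_column`, `segment_profile`).  Per
   accepted frame, the transverse profile averaged over the segment's
   markers yields the column width (FWHD), the minimal width (width at 80%
   depth), the lateral position (midpoint of the half-depth crossings) and a
   signal-to-noise ratio (profile depth over the annulus noise).  A
   measurement is *filled* at SNR ≥ 3; unfilled frames carry width 0 and
   are excluded from distributions, as are profiles truncated by the
   sampling window.  Because the column can be wider in later frames than
   on the detection frame — the excursion envelope extends to Dperf — the
   probing radius is sized from the pixelwise *minimum* over accepted
   frames, which darkens every pixel the column ever covered.
6. **Distributions** (`width_distribution`, `median_p50`,
   `perfused_diameter`).  Widths are pooled per segment (and per diameter
   class per site).  P50 and quartiles use type-7 linear interpolation.  For
   Dperf, widths are regressed on their Weibull plotting positions
   `i/(n+1)` restricted to the inter-quartile span, and the fitted line is
   evaluated at cumulative fraction 1.0.  Regressing width on fraction
   (exact design points) rather than fraction on width avoids an
   errors-in-variables slope attenuation, and the `i/(n+1)` positions make
   the extrapolated endpoint unbiased for samples from a uniform excursion
   law, for which `E[w(i)] = lo + i·range/(n+1)` is exactly linear in the
   plotting position.  A distribution with zero inter-quartile range is
   degenerate: Dperf is set to P50, PBR to 0, and the result is flagged.
7. **Reporting** (`summarize_site`, `classify_diameter`).  Dperf rounded to
   the nearest micrometre assigns the class (5–9, 10–19, 20–25 µm;
   otherwise excluded).  Class-level figures come from the pooled class
   distribution; the headline 5–25 µm figures from the pool of all
   classified segments.

## Cohort statistics

Three recording sites per subject are averaged (`aggregate_subjects`).
On the per-subject means:

* **Tolerance intervals** (`tolerance_interval`): central 95% empirical
  quantile limits (type 7), each with a 95% CI from 2,500 nonparametric
  bootstrap resamples of subjects.  This central-quantile reading is chosen
  because reference tolerance limits for these parameters lie strictly
  inside the observed min–max; an order-statistic (Wilks) variant is
  available behind `method = "wilks"`.
* **Variance components** (`variance_components`): the one-way
  random-intercept model `y_ij = µ + a_i + e_ij` fitted by REML.  The
  profiled REML criterion for this model has a closed form, which the
  package optimises directly (L-BFGS-B, analytic method-of-moments start;
  on balanced data with interior estimates the result equals the classical
  ANOVA estimators, a property the tests assert at 1e-6 and cross-check
  against lme4).  Wald SEs come from the numerical Hessian; the CIs are
  deliberately unconstrained and may cross zero, while point estimates are
  truncated at zero.
* **Covariate screening** (`covariate_screen`): simple linear regression
  for continuous covariates, one-way ANOVA for categorical ones, Tukey
  pairwise comparisons only when the ANOVA p < 0.05, and no multiplicity
  correction across the screen (a Holm option would be easy to add, but
  unadjusted reporting is the convention this screen mirrors).
* **Normality** (`normality_check`): Lilliefors-corrected
  Kolmogorov–Smirnov test, report-only.  The correction is used because the
  normal parameters are estimated from the sample; without it the test is
  far too conservative.

## What the synthetic generator emulates

`generate_scene` renders dark vessel bands with trapezoidal transverse
profiles whose FWHD equals the modelled column width *exactly* (a linear
edge ramp of 2 px; widths are defined perpendicular to the centerline, and
the raster accounts for the local tangent).  Per frame, each vessel draws a
column width and a lateral centre offset uniform within the band the width
leaves free inside the true perfused diameter.  Two excursion laws are
provided:

* `"uniform"` (default): widths uniform on `[P50 − 2·PBR, P50 + 2·PBR]`.
  Median P50, maximum Dperf, and a *linear* cumulative distribution — the
  one family for which the straight-line inter-quartile extrapolation of
  the CDF is a consistent estimator of Dperf.  With any strictly concave
  CDF near its upper endpoint (e.g. triangular), a straight line through
  the inter-quartile span provably extrapolates below the endpoint
  (for the symmetric triangular law it reaches `P50 + 0.59·s` rather than
  `P50 + s`), so "recovery of generator truth" would be testing the
  generator's tail shape, not the pipeline.  The uniform default makes the
  generator's truth identifiable by the declared estimator.
* `"triangular"`: symmetric triangular with median P50 and support capped
  at Dperf, kept for sensitivity studies; its closed-form CDF is verified
  in the tests.

Gaussian intensity noise (clipped to `[0, 1]`) and per-frame integer jitter
exercise the SNR logic and frame QC.  `generate_cohort` simulates
`y_ij = µ + a_i + e_ij` with a prescribed inter-individual variance
fraction per parameter, plus subject covariates and optional linear
covariate effects; the default parameter table encodes published reference
means, SDs and variance partitions for healthy sedated cats, and the
`dperf` column is derived as `2·pbr_5_25 + median_p50` rather than drawn,
preserving the structural identity.

**What the generator does not emulate:** optical physics of haemoglobin
absorption, depth-of-field and scattering blur, non-rigid tissue motion,
vessel branching and tortuosity beyond a mild sine, plasma gaps within a
column, and wall artefacts.  Passing recovery tests therefore demonstrates
the *estimators* are correct and well calibrated on scenes satisfying their
geometric assumptions — not that the pipeline matches the proprietary
instrument on real tissue.

### Study conditions used by the recovery experiments

The scene experiments use the cohort reference operating point: true
Dperf 11.78 µm and true PBR 2.39 µm (hence true P50 7.00 µm), 40 frames,
1 µm/px, background 0.85, contrast depth 0.5 and noise SD 0.02 (column SNR
≈ 20), mild curvature (1 px amplitude).  Independence matters more than
raw segment count: all segments of one vessel share the same per-frame
width draws, so the experiments use many short vessels (15 µm, one segment
each) — 50 scenes of 4 vessels, 200 independent segments.  Density
recovery uses noiseless 1 mm² fields whose planned valid-segment count
averages 17.3 (i.e. 173 µm/mm²); vessel lengths are `10k + 5` µm so the
planned count `k` is robust to the ~1–2 px tip erosion of detection.
Statistical recovery simulates 101 subjects × 3 sites, averaged over 50
seeded replicates.  The test suite runs the same experiments at reduced
size (e.g. 120 segments) chosen to keep each check's Monte-Carlo error
well inside its assertion tolerance.

## Numerical choices and degenerate inputs

* Widths and diameters interpolate the half-depth crossings linearly;
  sub-pixel accuracy follows from the linear edge ramp.
* The background annulus is 2–4 vessel radii out; samples falling outside
  the frame clamp to the border (background in non-pathological fields)
  while the core ±2 radii must be imaged.
* `floor((L + 1e-6)/10)` counts segments, so an exactly-30 µm centerline
  yields 3 segments despite floating-point arc summation.
* Uniform frames yield no vessels (not an error); saturated or black
  frames additionally warn.  All-rejected stacks are marked unanalyzable
  and excluded with a logged reason, as are unreadable recordings.
* Negative PBR from an inconsistent fit (Dperf < P50) is returned with a
  warning, never clamped, so systematic bias remains visible in QC.
* Ties and constant samples: a constant width distribution is degenerate
  (PBR 0); a constant cohort parameter gives zero-width tolerance limits;
  a constant sample is flagged non-testable for normality.

## Known limitations

* Centerline tracing assumes vessels are locally single-valued along their
  dominant image axis (within ±45°); hairpins and self-crossings are out of
  scope, as is non-rigid motion correction.
* Validity is assessed on the first accepted frame only, following the
  convention that segments are defined on the first frame.
* Whether VVD should be normalised by the full field or by a tissue mask
  is instrument-specific; the full field is the default and
  `field_area_mm2` overrides it.
* The width CDF is count-weighted; an intensity-weighted variant is a
  plausible alternative reading of the instrument's description and would
  slightly reweight wide columns.
* AVI containers are not read; convert recordings to multi-page TIFF or
  PNG sequences.
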