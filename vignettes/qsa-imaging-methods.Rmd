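---
title: "Standard-addition quantification for line-scan MSI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-addition quantification for line-scan MSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsaMSI)
```

# The quantification problem

A liquid-extraction MSI probe (nano-DESI and relatives) continuously
extracts analytes from the tissue into a flowing solvent and ionizes them
by electrospray. The measured intensity of an analyte at pixel $p$ is

$$ I(p) = g \, s(p) \, C(p), $$

where $g$ is the instrument response (gain), $C(p)$ the *detected
concentration* — the analyte concentration in the probe solvent, i.e.
tissue concentration times an unknown extraction efficiency — and
$s(p) \in (0, 1]$ a pixel-specific ion-suppression (matrix) factor. Because
$s$ varies across tissue types, raw (even TIC-normalized) ion images
confound concentration with suppression. Three calibration strategies
differ in how they handle $s$:

* **qIS** — a labeled internal standard at constant concentration
  $C_{IS}$ in the solvent is ionized from the same pixel, so
  $C = (I_a / I_{IS}) \, C_{IS}$: $s$ cancels in the ratio.
* **qSA** — known amounts $x$ of the *unlabeled* analyte are added to the
  solvent. They share the pixel's suppression, so the response is affine,
  $y = g s (C + x)$, and the x-intercept magnitude $a/b$ of the fitted
  line recovers $C$ whatever $s$ is (any common rescaling of the
  responses cancels in $a/b$).
* **qEC** — an external calibration $y = g x$ measured off tissue (no
  matrix, $s = 1$) is inverted at the tissue response $g s C$, returning
  $sC$: biased low by exactly the suppression factor. This is the
  mechanism behind external calibration "underestimating" in imaging.

The package's central statistic, per calibration line, is

$$ \hat C = a/b, \qquad
   s_{\hat C} = \frac{s_{y/x}}{b}
   \sqrt{\frac{1}{n} + \frac{\bar y^{\,2}}{b^2 S_{xx}}}, $$

the standard uncertainty of an extrapolated x-intercept, carrying both
slope and intercept error. `fit_line()` returns an `sa_fit` object (an
ordinary least-squares fit by `stats::lm` plus the summary statistics this
formula needs); `qsa_concentration()` applies the formula and flags
non-quantifiable cases (nonpositive slope) and negative intercepts
instead of erroring, because a quantitative image must keep going
pixel by pixel.

# From spectra to images

**Alignment.** All centroids from all scans are pooled, sorted by m/z, and
clustered greedily against the running intensity-weighted centroid with a
5 ppm window (configurable). Two peaks resolved within one spectrum are
never merged — they are distinct ions by definition. The tolerance is half
the worst-case spacing the simulator's ±2 ppm m/z jitter can produce, so
alignment is unambiguous on simulated data; equivalence with any
particular vendor alignment implementation is not claimed, only the
tolerance behavior.

**TIC normalization.** Each centroid intensity is divided by its scan's
total ion count (all centroids, aligned or not), which cancels global
ionization fluctuations. A zero-TIC scan becomes an all-NaN "empty pixel"
and is excluded from block averages downstream (at least 4 of 8 pixels
must be valid; otherwise the block is flagged `EMPTY`).

**The sliding reading frame.** With three alternating solvents (zero, low,
high addition), every window of three adjacent lines containing one line
per solvent contributes one row of the output image; windows advance one
line at a time (150 µm output spacing; a non-overlapping mode with 450 µm
spacing is available). Along the scan, 8-pixel block averages form the
three calibration points; the output pixel is therefore
$8 \times 20\,\mu m = 160\,\mu m$ wide at the reference geometry
(0.04 mm/s stage speed, 1.96 scans/s). Per output pixel the three block
means give $\hat C$ and $s_{\hat C}$; the 8 within-block pixels serve as
pure-error replicates for a lack-of-fit F test at $\alpha = 0.05$.
Failing pixels keep their concentration but carry the `LOF_FAIL` flag —
with only three x-levels there is no way to distinguish curvature from
within-window tissue heterogeneity, so flagging (not dropping) keeps the
decision with the analyst.

**Touchdown (spot) mode.** For spot quantification the probe rests on one
location until the extractable signal decays to 1% of its maximum
(`detect_touchdown()`), the spectra are sliced to at most 12 s from onset,
and TIC-normalized responses are summed over the window. The qSA
regression uses the integrated on-tissue responses against added
concentration across all solvents *without* subtracting the solvent-only
baseline: during the touchdown the additions are ionized from the tissue
contact and share its suppression, so their in-window contribution is
precisely the regression slope that standard addition relies on.
Subtracting the (unsuppressed) pre-touchdown baseline would remove
$g x T$ from a window contribution of $g s x T$ and drive the slope to
$g(s-1)T \le 0$, destroying the x-intercept. The pre-touchdown segment
(10 s ending 2 s before onset, configurable) is instead used as what it
is: the solvent-only external calibration for qEC.

# The simulator as the validation instrument

No public line-scan dataset with known per-pixel truth exists, so the
package ships a simulator whose outputs exercise every downstream stage.
Design choices, and what they do and do not emulate:

* **Response model.** Analyte and IS intensities follow
  $g\,s(p)\,(C(p)+x)$ exactly; suppression acts identically on endogenous
  analyte, added standard and IS at a pixel. This is the assumption that
  makes qSA and qIS unbiased and qEC biased, so simulation recovery tests
  are tests *of the estimator*, not of the assumption.
* **Spatial fields.** Concentration, suppression and background
  modulation are sums of Gaussian bumps with *physical* correlation
  lengths (1.5–4 mm at 20 × 150 µm pixels), the scale of anatomical
  structures: adjacent 150 µm lines sample nearly the same tissue, which
  is what makes a three-line window a meaningful calibration. The
  suppression field is rank-transformed to a uniform marginal on its
  requested range (default [0.3, 1]), keeping the spatial pattern smooth
  while making the field's mean and quantiles exact.
* **Concentration floor.** Analyte maps span
  $[\,c_{max}/5,\; c_{max}\,]$ (default $c_{max} = 20$ µM): small polar
  metabolites such as amino acids are present throughout brain tissue,
  with white matter a few-fold below the gray-matter peak, not absent.
* **TIC composition.** 40 background matrix ions with lognormal base
  intensities carry the TIC; a single analyte is ~0.2% of it (gain 200
  counts/µM). Real scans hold hundreds of features, so the TIC is much
  steadier than any individual channel; with too few background ions the
  TIC's own noise leaks into every normalized response, and with too
  large an analyte share the standard additions inflate the TIC of
  high-addition lines and bias the x-intercept upward by several percent.
* **Noise.** Mean-one multiplicative lognormal noise (CV parameter,
  default 10% — a free parameter, not an empirical claim) plus an
  optional additive Gaussian floor, independent per centroid per scan;
  m/z jitter uniform within ±2 ppm. Not simulated: chromatographic peak
  shapes, isotope patterns, adduct equilibria, detector saturation,
  spatially correlated noise. Passing recovery tests therefore shows the
  estimators are correct under the stated response model, not that real
  tissue obeys it.

# Numerical and design notes

* Ties in peak-to-feature assignment (equal ppm distance to two
  centroids) go to the lower-m/z feature; deterministic by construction.
* Lines of unequal scan count are truncated to the common minimum with a
  warning; empty pixels propagate as NaN.
* `fit_line()` requires two distinct x values; with $n = 2$ the residual
  sd is 0 by convention. The lack-of-fit p-value exists only when an
  x-level is replicated ($\ge 3$ levels, $n >$ levels) and is computed as
  the F test of the line against the per-level-means model.
* With three x-levels and CV-10% noise the extrapolation sd, evaluated by
  10,000-curve Monte Carlo, agrees with the empirical x-intercept spread
  to within ~5% (median of per-curve formula values vs empirical sd); the
  formula's own estimate $s_{y/x}$ makes individual values noisy, so the
  median, not the mean, is the calibrated summary.
* Problem sizes used by the validation suite: phantoms of 48 lines ×
  96 pixels (the height matches a ~7 mm tissue section at 150 µm line
  spacing) for recovery studies, smaller rasters for unit tests, and
  10,000 replicates for Monte-Carlo calibrations — sizes chosen so the
  whole suite documents the method at interactive timescales.
* Under those study conditions (uniform [0.3, 1] suppression, CV 10%,
  additions 0/1×/2× of the mean map concentration) the qSA image's
  median relative error against window-averaged truth is typically 7–9%
  across seeds (occasionally slightly above 10% on an unlucky phantom);
  qIS, evaluated at the same 160 µm output resolution, is ~3.5%, and the
  qEC median fold change equals the mean suppression factor within 0.05.
  qIS is compared at matched resolution because method comparisons are
  only meaningful at a common spatial scale — natively qIS carries the
  full per-pixel ratio noise (~14% CV) that block averaging removes.
* Method comparison across regions replaces factorial rank ANOVA with
  per-ROI two-sided Mann–Whitney tests plus Holm correction
  (`compare_roi_table()`): the per-ROI question ("do the two methods
  disagree here?") is the actionable one, and the procedure is fully
  specified. Paired per-analyte comparisons screen normality with
  Shapiro–Wilk at $\alpha = 0.05$ and fall back to the signed-rank test.
* Relative-concentration mode: when the scheme's units are
  `mg_per_mL_relative` (tissue-extract additions instead of pure
  standards), images are reported in mg tissue/mL per pixel; conversion
  to µM is a post-hoc multiplication by the analyte's concentration in
  the extract, when known. `stock_concentration()` does the mg/mL
  arithmetic for extract stocks.

# Known limitations

* Within-window tissue heterogeneity (the three lines sample tissue
  150 µm apart) is accepted as method error; no correction is attempted.
  It is the dominant error term when suppression or concentration
  gradients are steep at the line spacing.
* The lack-of-fit QC is over-sensitive when measurement noise is very
  small relative to spatial heterogeneity (pure error underestimates the
  model error); flagged fractions of tens of percent on near-noiseless
  simulations are expected and are a property of the design, not a bug.
* Detected concentrations are concentrations in the probe solvent;
  conversion to absolute tissue concentrations needs the extraction
  efficiency, which the method does not estimate.
* One mzML file per line is the canonical layout; multi-line files are
  supported only through the manifest produced by `export_mzml()`.
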