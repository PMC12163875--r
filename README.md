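# qsaMSI — standard-addition quantification for line-scan MSI

In mass spectrometry imaging (MSI) every pixel is its own chemical
microenvironment: co-extracted molecules suppress the ionization of an
analyte by a factor that varies across the tissue, so raw ion images are
not concentration maps. The usual remedy — an isotopically labeled internal
standard (IS) per analyte in the extraction solvent — is expensive and often
unavailable. **qsaMSI** implements quantification by *standard addition*
(qSA) for liquid-extraction line-scan MSI (e.g. pneumatically assisted
nano-DESI): known, increasing amounts of the unlabeled analyte ride in the
extraction solvent of alternating line scans, experience the same per-pixel
suppression as the endogenous analyte, and the regression of response
against added concentration is extrapolated to zero response. The magnitude
of the negative x-intercept is the *detected concentration* (analyte
concentration in the probe solvent).

For a calibration line `y = a + b x` fitted by least squares over the
added concentrations `x`, each pixel reports

    C = a / b
    s_C = (s_yx / b) * sqrt(1/n + ybar^2 / (b^2 * Sxx))

the standard x-extrapolation uncertainty, which propagates both slope and
intercept errors. Internal-standard (qIS, one-point ratio calibration) and
external-calibration (qEC, solvent-only curve) comparators are included:
under multiplicative suppression `s`, qSA and qIS are unbiased while qEC
recovers `s * C` — it underestimates wherever ions are suppressed.

The package covers the full workflow:

* **Simulator** (`make_phantom()`, `simulate_linescans()`, `export_mzml()`)
  — line-scan datasets with known concentration maps, a spatially smooth
  ion-suppression field, solvent-borne standard additions, an IS channel,
  background matrix ions, and seeded noise; the ground truth every
  downstream stage is validated against.
* **IO** (`read_mzml()`, `read_linescans()`, `load_scheme()`,
  `compute_geometry()`) — centroided mzML in/out via `mzR`, YAML/JSON
  solvent schemes, pixel geometry from stage speed and scan rate.
* **Feature cube** (`align_features()`, `tic_normalize()`, `build_cube()`,
  `extract_chronogram()`) — 5 ppm feature alignment, TIC normalization,
  the `[line x scan x feature]` data cube.
* **Touchdown (spot) quantification** (`detect_touchdown()`,
  `slice_window()`, `touchdown_record()`, `run_touchdown_study()`) — qIS,
  six-point qSA with eq-style uncertainties, and qEC per analyte.
* **Imaging** (`sliding_qsa()`, `qis_image()`, `percentile_clip()`) —
  sliding-reading-frame standard addition: 8-pixel block averages from
  three adjacent lines (one per solvent) form each regression; output
  pixels are 160 × 150 µm at the default geometry, with per-pixel sd and
  QC flags (negative slope, negative concentration, lack of fit, empty).
* **Comparison** (`median_fold_change()`, `roi_extract()`,
  `compare_methods()`, `paired_method_test()`) — ROI statistics and
  method-comparison tests.
* **Pipeline** (`run_pipeline()`, `inst/cli/qsamsi.R`) — simulate →
  quantify → ROI from one YAML config, with a seeded run manifest.

## Worked example

```r
library(qsaMSI)

ph  <- make_phantom(n_lines = 48, width_px = 96, n_analytes = 1, seed = 7)
m   <- round(mean(ph$analytes$Glu$true_conc_map), 2)    # 12.21 uM
sch <- solvent_scheme(list(
  s1 = list(added = c(Glu = 0),     is = c(IS = 10)),
  s2 = list(added = c(Glu = m),     is = c(IS = 10)),
  s3 = list(added = c(Glu = 2 * m), is = c(IS = 10))))
lss  <- simulate_linescans(ph, sch, rep(c("s1", "s2", "s3"), 16),
                           noise_model(multiplicative_cv = 0.1, seed = 7))
cube <- build_cube(lss, align_features(lss), sch,
                   compute_geometry(0.04, 1.96, 150))
img  <- sliding_qsa(cube, 148.0604, sch)
img
#> Quantitative image: 46 x 12 pixels ( 150 x 163.265 um )
#>   units: uM; 552/552 quantified pixels
#>   conc 5/50/95%: 5.459 / 12.22 / 18.98
plot(img, pct = 99)   # display capped at the 99th percentile
```

The printed raster is the detected-concentration image: 46 overlapping
three-line windows by 12 eight-pixel blocks, each pixel the extrapolated
x-intercept of its own three-point standard-addition line. All 552 pixels
report a concentration here; `summary(img)` shows 460 are unflagged and 92
carry the lack-of-fit QC flag (kept, but excluded from error summaries).
The 5th–95th percentile span (5.5–19.0 µM) tracks the phantom's true map
(4–20 µM detected concentration), and comparing `img$conc` with the
window-averaged `true_conc_map` gives a median relative error of about 8%
at 10% per-scan noise.

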