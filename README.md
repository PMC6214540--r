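# adipoquant

Quantitative MRI of abdominal adipose tissue in R: T1 relaxometry, fat
fraction, fat volumetry and paired cohort statistics.

Obesity interventions such as bariatric surgery are usually judged by
weight and fat-volume changes, but quantitative MRI parameters of the
adipose tissue itself — the T1 relaxation time and the proton-density
fat fraction (PDFF) of visceral (VAT) and subcutaneous (SAT) fat — can
change within weeks of surgery and may act as non-invasive tissue
biomarkers. adipoquant implements the full analysis chain needed to
measure them at 1.5 T, for imaging scientists and clinical researchers
who want a tested, scriptable alternative to one-off in-house tools.

## What it computes

* **T1 mapping** — fits the saturation-corrected magnitude
  inversion-recovery model
  `S(TI) = S0 * sqrt((1 - 2 e^(-TI/T1) + e^(-TSAT/T1))^2 + C^2)`
  to multi-TI data (`fit_ir`, `fit_t1_map`), and summarises ROIs by mean
  T1 and the coefficient of variation `CV = sigma/mu * 100` (`roi_t1`).
* **Water–fat separation** — fits the single-peak Dixon model
  `S(TE) = sqrt(W^2 + F^2 + 2 W F cos(2 pi df TE)) * e^(-TE/T2*)`
  to multi-echo data (`fit_dixon`, `roi_ff`), reporting
  `FF = F/(W+F) * 100` and T2\*, with an explicit prior to resolve the
  water–fat swap ambiguity of magnitude data.
* **Fat segmentation and volumetry** — k-means body detection, an
  active-contour inner SAT boundary, seeded region growing for the VAT
  compartment, manual contour correction, Gaussian-mixture histogram
  fat quantification, and slice-stack volumetry
  `V = sum(A_k) * (ST + ISG) / 10^4` litres (`segment_slices`,
  `histogram_fat_area`, `total_vat_volume`).
* **Cohort statistics** — per-subject percent changes, Shapiro–Wilk
  gated one-sample t / Wilcoxon signed-rank tests against 0 %, 95 % CIs,
  significance stars and direction counts (`cohort_summary`).
* **Synthetic ground truth** — an abdominal phantom generator with known
  T1/T2\*/FF per tissue and analytic VAT volume, simulated through the
  same forward models with Rician noise (`make_phantom`,
  `simulate_ir_series`, `simulate_dixon_series`, `simulate_in_opposed`,
  `make_cohort`), so every stage can be validated without patient data.

## Worked example

```r
library(adipoquant)

ph <- make_phantom(96, 96, 2, seed = 42)
ph
#> Synthetic abdominal phantom
#>   grid: 96 x 96 x 2, pixel 4 mm, slice 10 mm + 0.5 mm gap
#>   true VAT volume: 0.2712 L

ir <- simulate_ir_series(ph, acquisition_spec("inversion_recovery",
                                              noise_sigma = 1.6, seed = 42))
vat_px <- which(ph$labels[, , 1] == 2L, arr.ind = TRUE) - 1L
roi_t1(ir, roi(0L, vat_px, "VAT"))
#> ROI T1 (pixelwise): mean 305.4 ms, SD 3.99 ms, CV 1.31% (n = 812)

dx <- simulate_dixon_series(ph, acquisition_spec("multiecho_dixon",
                                                 noise_sigma = 1.6, seed = 42))
roi_ff(dx, roi(0L, vat_px, "VAT"))
#> ROI fat fraction (mean-signal): 84.99% (SD 0.00), T2* 20.00 ms (n = 812)

io <- simulate_in_opposed(ph, acquisition_spec("in_opposed",
                                               noise_sigma = 1.6, seed = 42))
total_vat_volume(io, segment_slices(io, seed = 1))
#> Total VAT volume: 0.2723 L over 2 slices (ST 10.0 mm + gap 0.5 mm)
```

The ground-truth tissue values here are T1 = 305 ms and FF = 85 % in
VAT, and the phantom's analytic VAT volume is 0.2712 L: the ROI
relaxometry lands on the true T1 within its ~1.3 % coefficient of
variation, the mean-signal fat-fraction fit is accurate to a few
hundredths of a point, and the segmented, histogram-quantified volume is
0.4 % from truth.

A paired 23-subject cohort under post-surgery study conditions:

```r
cohort_summary(make_cohort(23, seed = 42))
#> Paired cohort change report (n = 23)
#>
#> parameter     M0 (mean+/-SD)  M1 (mean+/-SD)  change % [95% CI]      test        p
#> BMI [kg/m2]    45.79+/-7.36     42.45+/-6.71     -7.3 [ -7.9, -6.6]         t 3.28e-17 ***
#> V_VAT-T [L]     5.53+/-2.35      4.93+/-2.04    -10.3 [-12.5, -8.1]         t 2.66e-09 ***
#> T1_VAT [ms]   306.11+/-9.67    317.96+/-17.05    +3.9 [ +1.7, +6.0]         t  0.00109 **
#> T1_SAT [ms]   283.90+/-6.58    280.90+/-7.36     -1.0 [ -2.1, +0.0]         t   0.0533
#> FF_VAT [%]     85.45+/-2.60     83.38+/-4.58     -2.5 [ -4.0, -1.0]         t  0.00248 **
#> FF_SAT [%]     85.73+/-1.99     85.54+/-2.21     -0.2 [ -0.9, +0.5]         t    0.529
```

Each row reports both timepoints, the mean per-subject percent change
with its 95 % CI, and the normality-gated test: here BMI and visceral
fat volume drop sharply, visceral T1 rises and visceral FF falls, while
both subcutaneous parameters stay flat — the expected pattern one month
after surgery. Real cohort tables (CSV or xlsx, long or wide layout) are
read with `read_cohort_table()`; `run_pipeline()` drives the whole
simulate–fit–segment–report chain and writes a checksummed manifest.

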