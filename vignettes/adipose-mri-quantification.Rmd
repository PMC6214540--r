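---
title: "Quantitative MRI of abdominal adipose tissue: models, methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI of abdominal adipose tissue: models, methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## Scope

adipoquant implements the image-analysis chain used to monitor abdominal
adipose tissue quantitatively at 1.5 T: pixelwise and ROI-level T1
relaxometry from inversion-recovery series, proton-density fat fraction
(PDFF) and T2\* estimation from multi-echo gradient-echo (Dixon) series,
semi-automatic segmentation of axial abdominal slices into subcutaneous
(SAT) and visceral (VAT) fat with histogram-based fat volumetry, and
paired-cohort percent-change statistics. Because patient image data of
this kind is essentially never redistributable, the package ships a
synthetic abdominal phantom generator with exact ground truth; every
stage is validated against it.

## Signal models

### Inversion recovery with saturation correction

A magnitude inversion-recovery acquisition with a finite saturation
interval $T_{SAT}$ is modelled as

$$ S(TI) = S_0 \sqrt{\left(1 - 2e^{-TI/T_1} + e^{-T_{SAT}/T_1}\right)^2 + C^2}. $$

$S_0$ is a calibration constant in signal units, $C$ a dimensionless
noise-floor constant (the floor in signal units is $S_0 C$), and
$T_{SAT}$ defaults to 4500 ms. With $C = 0$ and $T_{SAT} \to \infty$
this is the ideal magnitude IR curve with its null at $TI = T_1 \ln 2$.
`fit_ir()` minimises the residual sum of squares over $(S_0, T_1, C)$
with bounded Levenberg–Marquardt steps (minpack.lm) and a multi-start
over $T_1 \in \{100, 300, 800\}$ ms, bounds $T_1 \in [50, 3000]$ ms,
$C \ge 0$, relative tolerance $10^{-10}$. The multi-start matters: the
objective has boundary traps when the floor dominates, and the test
suite holds the fitter to an exhaustive 1-ms grid search with $S_0$ and
$C$ profiled out.

Fits that do not converge, or whose floor exceeds five times the
amplitude (no usable $T_1$ information), are flagged and excluded from
ROI statistics. ROI T1 is reported in two conventions: *pixelwise*
(default; fit every pixel, summarise mean, SD and the coefficient of
variation $CV = \sigma/\mu \times 100$, the standard reliability measure
for ROI relaxometry) and *mean-signal* (average the ROI signal per TI
and fit once; SD/CV are then undefined and flagged). Both are exposed
because both are in routine use and they agree exactly on homogeneous
regions; pixelwise is the default since it also yields the reliability
estimate.

### Single-peak water–fat model

Multi-echo magnitude signals are modelled with one water and one lipid
resonance separated by $\Delta f$ and a common effective decay:

$$ S(TE) = \left| S_W + e^{\,i 2\pi \Delta f\, TE} S_F \right| e^{-TE/T_2^*}
         = \sqrt{W^2 + F^2 + 2WF\cos(2\pi \Delta f\, TE)}\; e^{-TE/T_2^*}, $$

valid when the complex amplitudes share an arbitrary common phase. Echo
times are handled in milliseconds throughout the interface and converted
exactly once for the phase term — the classic source of 1000-fold phase
errors. $\Delta f$ defaults to the 4.7 ppm − 1.3 ppm shift at 1.5 T,
$3.4 \times 42.577 \times 1.5 \approx 217$ Hz (conventionally quoted
rounded to 220 Hz; `chemical_shift_offset()` computes both).

The fat fraction is $FF = F/(W+F) \times 100$. Magnitude data cannot
tell $W$ from $F$ — swapping them reproduces the signal exactly — so
`fit_dixon()` resolves the ambiguity with an explicit prior, default
*fat-dominant* ($F \ge W$), which is the correct choice inside adipose
ROIs; a water-dominant and a keep-as-fitted option exist. The default
single-peak model is a deliberate simplification (multi-peak fat spectra
are out of scope); it is known to underestimate FF slightly in real
tissue, which is acceptable here because the package targets paired
longitudinal contrasts.

ROI fat fraction defaults to the *mean-signal* convention (average the
ROI per echo, fit once), with a pixelwise mode for maps.

## Segmentation and volumetry

Segmentation operates on the fat-bright in-phase image of a dual-echo
series (TE 2.3/4.6 ms at 1.5 T; the in-phase echo is auto-selected from
the metadata as the echo whose water–fat phase is closest to a multiple
of $2\pi$):

1. **Body detection** — k-means (k = 2) on intensities, keep the largest
   connected component, fill holes, trace the outer contour (EBImage
   primitives). Deterministic for a fixed seed.
2. **Inner SAT boundary** — a closed active contour initialised 2.5 px
   inside the outer boundary (i.e. inside the homogeneous SAT ring) and
   evolved under elastic smoothing, attraction to the gradient-magnitude
   ridge, and an inward balloon pressure that switches off where the
   normalised edge strength exceeds 0.22. The contour sweeps inwards
   until it locks onto the fat-to-lean transition at the ring's inner
   edge. Defaults (120 points, smoothness 0.25, edge weight 1.2, balloon
   step 0.35 px, at most 400 iterations, 0.02 px convergence) were set
   on phantoms with clean ring geometry; heavier smoothing produces
   shorter, smoother contours, a property the tests check. Non-converged
   contours are returned flagged rather than discarded.
3. **VAT candidate region** — region growing from user seeds under a
   homogeneity criterion ($|I - \mu_{seed}| \le 0.2\,\mu_{seed}$),
   constrained to the inner-SAT interior. Seeds that grow sub-threshold
   (lean) regions are excluded and flagged; with no seeds the whole
   interior is used. The region may be loose because quantification is
   histogram based.
4. **Manual correction** — `apply_correction()` replaces a contour arc
   with a redrawn segment whose endpoints must lie on the contour;
   results are re-validated as closed and simple, and the operation is
   idempotent.
5. **Histogram fat quantification** — the intensity histogram of the
   candidate region is decomposed into a lean and a fat component by a
   two-component Gaussian mixture (mclust); the fat area is the sum of
   fat responsibilities times the pixel area, so partial-volume pixels
   count fractionally. Decompositions with component separation under 2
   pooled SDs, or near-discrete histograms, fall back to threshold
   rules; an absolute sanity cut (component mean at least 0.8 of the
   image's bright-fat reference, the 0.9 quantile of foreground
   intensities) stops an all-lean region from being split into a fake
   fat peak. Flags mark every fallback.
6. **Volumetry** — per-slice fat areas are stacked as
   $V = \sum_k A_k \,(ST + ISG) / 10^4$ litres with slice thickness
   10 mm and interslice gap 0.5 mm by default. The gap is included so a
   contiguous stack represents the full scanned extent; the factor is
   configurable. The anatomical slice range (e.g. diaphragm to femoral
   heads) is a user input, as in practice.

Total SAT volumetry is deliberately not offered: subcutaneous fat
commonly exceeds the field of view in obese subjects, making the
measurement ill-defined.

## Cohort statistics

Per-subject percent change is $(M1 - M0)/M0 \times 100$; the cohort
change is the **mean of per-subject changes**, not the ratio of cohort
means. (The two differ: with baseline 45.4 and follow-up 42.4 the ratio
of means gives −6.6 % while the per-subject mean is what a paired
analysis reports.) Each parameter's change vector passes a Shapiro–Wilk
gate at $\alpha = 0.05$: normal-looking vectors get a two-sided
one-sample t-test against 0 %, others a two-sided one-sample Wilcoxon
signed-rank test against a 0 % median (zeros dropped; exact p for
n ≤ 25 without ties, else the normal approximation with continuity
correction — the suite checks the exact branch against full $2^n$
enumeration). A t-based 95 % CI of the mean change is always reported,
and significance bands are starred as * (p < 0.05), ** (p < 0.01),
*** (p < 0.001). Direction counts ($n_+, n_-, n_0$) treat values as
equal after rounding to one decimal, matching typical table precision.
No multiplicity correction is applied across the six parameters, by
design.

## The synthetic phantom and what it does (not) show

`make_phantom()` builds an elliptical body cross-section with an annular
SAT ring (18 % of the elliptical radius), non-overlapping circular VAT
blobs (default four per slice, radius one twelfth of the grid), lean
interior tissue and a small posterior bone structure, on a default
96×96 grid at 4 mm pixels, 10 mm slices with 0.5 mm gaps. Default
tissue parameters are chosen from measured abdominal values at 1.5 T:
T1 285 ms (SAT) and 305 ms (VAT), fat fractions 86 %/85 %, lean T1
900 ms with FF 10 %, T2\* 20 ms for fat (a conventional value;
configurable since it is rarely reported). The analytic VAT volume —
voxel count × footprint × (thickness + gap) — is stored as the
volumetry oracle.

All three acquisitions are simulated from the corresponding forward
models, then degraded with Rician noise, $|(x + n_1) + i n_2|$ with
Gaussian $n_1, n_2$ — the correct magnitude-MRI noise model. The default
scale $\sigma = 1.6$ gives SNR ≈ 50 in subcutaneous fat. All seeds are
explicit arguments; there is no hidden global state.

`make_cohort()` draws paired 23-subject cohorts. Baseline means and SDs
per parameter (BMI 45.4 ± 5.7 kg/m², VAT volume 5.94 ± 2.24 L, T1
303.7 ± 9.7 / 283.2 ± 8.2 ms, FF 85.7 ± 2.8 / 86.1 ± 1.8 %) and mean
percent shifts (−6.8, −10.9, +4.4, −0.9, −2.6, −0.2) are the published
study conditions for a one-month post-bariatric-surgery contrast. The
intra-individual shift SDs are *not* published; they were derived once
from the reported significance levels and direction counts (e.g. the
visceral-T1 shift SD of 4.5 pp makes roughly 18–19 of 23 subjects
increase and puts the one-sample t-test near p < 0.001, both as
reported) and are documented defaults, not fitting targets.

What passing on phantoms shows — and what it does not: the phantom has
piecewise-constant tissue, convex geometry, no motion, no bias field, no
partial-volume gradients beyond pixelisation and no physiological
heterogeneity. Recovery results on it validate the estimators and the
pipeline plumbing, not in-vivo accuracy. One visible consequence: the
phantom's ROI T1 coefficient of variation (~1.3 % in VAT at default
noise) sits at the very bottom of the 1.3–4.8 % range seen in vivo,
where tissue heterogeneity adds variance that pure noise does not.

## Numerical choices and degenerate inputs

* Both fitters are bounded Levenberg–Marquardt with multi-start;
  convergence tolerances $10^{-10}$ relative. On valid numeric input
  they never throw: all-zero or non-finite signals return flagged
  degenerate results.
* Oracle tests compare `fit_ir()` against a 1-ms T1 grid (amplitude and
  floor profiled by clipped linear least squares on squared signals) and
  `fit_dixon()` against a 0.1-pp × 0.1-ms (FF, T2\*) grid with the
  amplitude profiled analytically.
* The six-TI protocol identifies T1 uniquely on [100, 2000] ms; the
  suite verifies this numerically on normalised signal vectors.
* Fat-fraction estimates are clamped to [0, 100] by the non-negativity
  of the fitted amplitudes, never by post-hoc clipping.
* Region-growing and k-means segmentation are deterministic given the
  documented seeds.
* Wilcoxon zero-handling: zeros are dropped before ranking; an all-zero
  change vector returns p = 1 with a flag.

## Problem sizes used in the shipped validation

The test suite and the acceptance script validate on 96×96 phantoms
with one or two slices, 20 random phantoms for volumetry recovery, 50
random instances per fitter for the grid-oracle comparisons, and 200
replicate 23-subject cohorts for the cohort statistics; these sizes give
Monte-Carlo error well below the tolerances being checked while keeping
a full run in tens of seconds on a single CPU.

## Known limitations

* Single-peak fat model: absolute FF is biased low relative to
  multi-peak references; longitudinal contrasts are less affected.
* Magnitude-only fitting: the water–fat swap is resolved by prior
  knowledge, not by phase information; T1 bias of PDFF is not corrected.
* No B1/inversion-efficiency correction in T1 mapping.
* The segmentation defaults assume a closed, roughly convex SAT ring
  with fat-bright contrast; pathological anatomy will need parameter
  changes and manual correction.
* File IO covers NIfTI volumes with JSON sidecars (and CSV/xlsx cohort
  tables); DICOM series must be converted upstream.
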