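---
title: "Estimating BMD and BMC from multifidus CT texture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating BMD and BMC from multifidus CT texture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Muscle quality and bone health decline together: sarcopenia and osteoporosis
share risk factors, and the texture of the deep paraspinal stabilizers — the
multifidus in particular — carries information about the skeleton around
them. `mfxbmd` implements an opportunistic-screening pipeline that quantifies
multifidus texture on one axial CT slice per side and regresses DXA-measured
bone mineral content (BMC, g) and areal density (BMD, g/cm²) at the total
lumbar spine and total hip on those texture features. CT scans acquired for
any clinical indication can then yield a bone-health estimate without an
extra DXA visit.

Because the clinical cohort this kind of study rests on is private, the
package ships a synthetic cohort generator whose output exercises every
stage under a *known* ground truth. All statements below about accuracy are
statements about that synthetic system, verified by the test suite and the
acceptance script; none are claims about clinical data.

## Region of interest

The ROI contract is: a hand-drawn polygon enclosing the bulk of the muscle,
intersected with an HU threshold window. A pixel belongs to the ROI exactly
when its center lies inside the polygon (even-odd rule) and its value is
within the window, inclusive on both ends. Coordinates are 0-based
`(row, col)` with rows increasing downward — this has to be pinned down
because it defines what "horizontal" and "vertical" co-occurrence mean.

The default window is **[-29, 150] HU**, the prevailing skeletal-muscle
convention; it strips both fat (≈ -100 HU) and bone from the drawn region.
The window is a parameter (`hu_window`) because reasonable alternatives
exist (e.g. lean-muscle windows excluding myosteatosis). An ROI that ends up
empty is an explicit error, never a silent zero-feature row.

## The 45-feature texture vector

Each ROI yields 45 features with a fixed index layout:

* **j = 1..5 — intensity histogram**: mean, standard deviation (denominator
  n−1), skewness `m₃/m₂^{3/2}`, kurtosis `m₄/m₂²` (non-excess, so a normal
  field gives ≈ 3; central moments with denominator n), and Shannon entropy
  in bits over a 64-bin equal-width histogram.
* **j = 5 + n + 5(m−1) + 20(l−1) — GLCM statistics**: statistic
  n ∈ {contrast, correlation, energy, homogeneity, variance}, gray-level
  count index m ∈ {16, 32, 64, 128}, direction l ∈ {horizontal, vertical}.
  This grid contributes 2 × 4 × 5 = 40 features; the combined map is a
  bijection onto 1..45, verified by test.

Per-case features fuse the two sides: entries 1–45 are the left ROI, 46–90
the right, giving the 90-feature bilateral design.

Choices the feature definitions had to fix:

* **Quantization** is per-ROI min–max into equal-width bins; the ROI maximum
  maps into the top bin and a constant ROI maps to bin 0. A consequence worth
  knowing: adding a constant to all ROI HU values changes only the histogram
  mean — every GLCM feature, and the histogram entropy (whose bins use the
  same min–max convention), is shift-invariant. That invariance is tested.
  An alternative — binning entropy over the fixed HU window — would tie
  entropy to absolute HU calibration and break the invariance; we prefer the
  calibration-robust convention and document it here.
* **Co-occurrence matrices are nonsymmetric**: ordered pairs at offset
  distance 1 — `(r, c) → (r, c+1)` horizontally, `(r, c) → (r+1, c)`
  vertically — with both pixels inside the mask; the transpose is *not*
  added. Counts normalize to probabilities by the total pair count.
* **GLCM statistic formulas** follow the standard co-occurrence definitions:
  contrast `Σ p(i,j)(i−j)²`, correlation
  `Σ p(i,j)(i−μᵢ)(j−μⱼ)/(σᵢσⱼ)`, energy `Σ p(i,j)²`, homogeneity
  `Σ p(i,j)/(1+|i−j|)`, and variance taken as the row-marginal variance
  `Σ p(i,j)(i−μᵢ)²` — the most common single-matrix reading of "variance"
  (sum-variance is a documented alternative we did not adopt). Indices are
  the 0-based gray levels.
* **Degenerate inputs** are defined, not errors: a constant ROI has sd,
  skewness, kurtosis and entropy 0 and a point-mass GLCM whose correlation
  is reported as 0 with a `degenerate` flag (its marginal sds vanish).
* **Directions**: the horizontal/vertical grid is the operating definition;
  a `directions = "diag"` option computes the 45°/135° offsets instead for
  sensitivity analyses, since texture-angle conventions vary between
  descriptions of this family of methods.

## Regression models

Two linear families predict each DXA target from the features
(`ŷ = Σ w_j x_j + b`):

* **OLS** on internally standardized features (center and population-sd
  scale stored in the model). Rank-deficient designs — including n ≤ J —
  return the SVD minimum-norm solution, flagged and warned about.
* **LASSO**: minimize `(1/2n) Σ (yᵢ − ŷᵢ)² + λ Σ |w_j|` by cyclic
  coordinate descent with exact soft-threshold updates, the bias
  unpenalized. Standardization matters here: the features span wildly
  different magnitudes (HU means near 50 vs energies below 1), and the ℓ₁
  penalty is not scale-invariant.

Numerical contract of the solver:

* Convergence when the largest per-sweep weight change drops below
  `tol = 1e-7`; penalties at or above the analytic null bound
  `λ_max = max_j |x_jᵀ y| / n` short-circuit to the exactly-zero solution
  (KKT). Cold starts at small penalties run a warm-started path down from
  `λ_max` (pathwise coordinate descent); active-set cycling with confirming
  full sweeps accelerates the interior.
* Feature tables at small n contain *near-duplicate columns* (the same GLCM
  statistic at nested quantization levels correlates > 0.9999 across
  cases). There coordinate descent converges in objective and predictions
  long before the weight-change criterion can trigger, while weight mass
  shuffles between duplicates at a per-sweep contraction rate ≈ 1. A guard
  stops such fits — flagged `crawl_stopped` — after 500 consecutive sweeps
  below `10000 × tol`; sustaining that pattern requires a contraction rate
  above 0.986, i.e. a numerically non-identifiable direction. On
  well-conditioned designs the solver matches an independent
  coordinate-descent implementation run at 10⁻¹⁴ threshold to ~10⁻⁹.
* λ is chosen by k-fold cross-validated MSE (default k = 5) over a
  log-spaced grid from `λ_max` down two decades when n < J (where the
  unpenalized limit is not unique) and three otherwise; ties break to the
  first grid index. The study never states how its penalty was set, so CV is
  our choice. Folds are assigned at *case* level: in the per-scan 45-feature
  design both sides of a case always share a fold, so no case leaks across
  the train/test split.

Four separate models are fitted, one per target (lumbar BMC/BMD, hip
BMC/BMD), rather than one multi-task model — the readout of interest is
per-target.

## Evaluation

The readout is the Pearson correlation and the mean squared error between
model estimates and the DXA reference, in raw target units (so BMC MSEs are
in g² and BMD MSEs in (g/cm²)², which is why they sit on very different
scales). Both an **in-sample** and a **cross-validated** mode are always
computed and reported side by side: reported correlations in this literature
often do not state which mode they are, and the honest artifact shows both.
Cross-validated values assemble out-of-fold predictions over all cases and
evaluate once; with LASSO models the penalty is re-selected inside each
training fold (nested CV), so the reported r is free of selection leakage.
Constant predictions have undefined correlation and are reported as r = 0
with a degenerate flag.

## The synthetic cohort

`generate_cohort()` emulates the analyzable study cohort:

* **Metadata**: age ~ N(63.12, 10.16²) y truncated to [18, 100], BMI ~
  N(24.09, 4.45²) truncated to [12, 60], CT–DXA interval ~ N(7.13, 6.12²) d
  truncated at 0, male fraction 115/248. Exclusion flags are independent
  Bernoulli draws, default rate 0 because the emulated cohort is the
  post-exclusion one; the selection-funnel demo (analysis/02) switches on
  funnel-proportioned rates.
* **Latent texture triple** per case, uniform over muscle-plausible ranges:
  base HU ∈ [20, 70], interior noise sd ∈ [5, 25] HU, spatial correlation
  length ∈ [0.8, 2.5] px. Both sides of a case share the triple; rendering
  noise differs by side.
* **Slices**: a blob with an irregular harmonic-modulated boundary
  (exercising masked, non-rectangular GLCM computation) on a fat-range
  background (−100 HU), interior = base HU + a correlated Gaussian field
  (white noise convolved with a Gaussian kernel of sd = correlation length,
  normalized so the marginal sd is exact). The stored "hand-drawn"
  annotation polygon is the blob boundary dilated by 12%, mimicking a
  generous manual trace that the HU threshold then trims.
* **DXA truth**: `target = bias + W·latent + N(0, σ)` with a stored 4×3
  weight matrix, per-target intercepts and noise sds. Intercepts and weights
  put targets on clinically plausible scales (lumbar BMC ≈ 55 g, BMDs ≈
  1.1 g/cm²) and the noise sds set the latent-level signal-to-noise so that
  texture–DXA correlations come out moderate-to-strong (r ≈ 0.7) and the
  per-target MSE magnitudes sit on the orders clinical reports print
  (BMC MSEs of order 1 g², BMD MSEs of order 10⁻² (g/cm²)²). These scales
  are a modeling choice, fixed once — the real cohort's DXA distributions
  are not public.

What the generator does **not** emulate: anatomy (no vertebrae, no multiple
muscles), 3D volumes, scanner effects (beam hardening, kernel dependence,
dose), segmentation ambiguity, or correlated exclusion mechanisms. Passing
tests therefore demonstrate that the pipeline's *computational* contracts
hold and that the regression machinery recovers known truths through the
rendering bottleneck — not that clinical accuracy would match.

Because the DXA truth is linear in the *latent* parameters, not in the
features, the feature→target association is attenuated realistically by
rendering and estimation noise: the latent base HU is recovered by the
histogram-mean feature at r ≈ 0.98, the noise and correlation-length
parameters more weakly through the sd and GLCM features.

## Problem sizes and determinism

The test suite runs cohorts of 12–30 rendered cases (32–48 px slices) plus
feature-level regression cohorts at the study scale (n = 395, J = 90); the
acceptance script and the analysis workflow run the full 395-case rendered
cohort at 64 px. Every random step — cohort generation, slice rendering,
fold assignment — flows from explicit integer seeds, and the pipeline's
`results.json` is byte-identical across reruns of the same config and seed.
The oracle-equivalence tests compare the vectorized GLCM against a
brute-force pair enumeration on 200+ random masked images, and the LASSO
against both its analytic limits (OLS at λ = 0, exact zeros at λ ≥ λ_max)
and an independent implementation.

## Known limitations

* One slice per side per case; multi-level (T12–S1) aggregation is left to
  the caller, as the underlying study's per-level protocol is ambiguous.
* Only offset distance 1 and two directions per configuration; no
  run-length or other radiomics families.
* The minimum-norm OLS fit at n < J is reported for completeness but is an
  interpolator; use the LASSO results in that regime.
* Histogram entropy depends on the 64-bin choice; it is fixed, documented
  and tested rather than configurable.
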