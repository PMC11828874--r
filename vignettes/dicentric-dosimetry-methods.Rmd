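---
title: "Methods: dicentric dose estimation and ILC scoring"
author: "biodoseilc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dicentric dose estimation and ILC scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodoseilc)
```

## The problem

After an overexposure to ionising radiation, the frequency of dicentric
chromosomes in peripheral blood lymphocytes is the standard biological
dosimeter: dicentrics are nearly specific to ionising radiation, their
background frequency is low, and their yield per cell grows smoothly with
dose. A laboratory scores metaphases from a patient sample, counts
dicentrics per cell, and inverts a previously established *dose-effect
(calibration) curve* to report a dose with a 95% confidence interval.
Because networks of laboratories must produce *comparable* estimates in a
mass-casualty event, they run blinded interlaboratory comparisons (ILCs):
an organiser irradiates blood at known ("reference") doses, distributes
coded samples, and scores the returned estimates.

This package implements that whole computational chain — curve fitting,
inverse dose estimation with uncertainty, dispersion statistics, dose-
definition conversion, and ILC scoring — together with a synthetic-data
generator that reproduces the statistical structure of a high-dose
cobalt-60 exercise, so that every stage can be validated end to end
without access to laboratory scoring data.

## The dose-effect model

For low-LET radiation the expected dicentric yield per cell is linear-
quadratic in the absorbed dose $D$:

$$Y(D) = C + \alpha D + \beta D^2,$$

with background $C$ (dicentrics/cell), $\alpha$ (Gy$^{-1}$) the
single-track and $\beta$ (Gy$^{-2}$) the two-track coefficient. Under an
acute homogeneous whole-body exposure, per-cell counts are Poisson, so the
per-dose totals $X_i$ over $N_i$ cells satisfy
$X_i \sim \text{Poisson}\{N_i\,Y(D_i)\}$.

`fit_lq_curve()` maximises this Poisson likelihood on the per-dose
sufficient statistics $(N_i, X_i)$ with the *identity* link — the field
convention for dicentric curves, because the curve itself, not its
logarithm, is the quantity laboratories exchange. Numerically the fit is
iteratively reweighted least squares with the coefficients constrained to
the non-negative orthant; when a coefficient drifts to the boundary
(typically $C$ when no dicentrics are scored at 0 Gy) IRLS only converges
linearly, so a bounded quasi-Newton step on the deviance finishes the
fit and boundary coefficients are then pinned by an active-set rule with
a KKT check. Convergence is declared at a relative deviance change below
$10^{-10}$ (cap 100 IRLS iterations, then the bounded refinement). The
coefficient covariance is the inverse observed Fisher information at the
optimum, with zero rows/columns for coefficients estimated on the
boundary; deviance and residual degrees of freedom are reported, and an
optional quasi-likelihood inflation (`overdispersion = TRUE`) scales the
covariance by deviance/df when the calibration data show lack of fit
(off by default — how participants handle calibration overdispersion is
lab-specific).

The fitter is cross-checked in the test suite against two independent
routes: `glm(family = poisson(link = "identity"))` on interior optima,
and a brute-force likelihood grid on a small design.

## Dose estimation and its uncertainty

The point estimate inverts the curve at the observed yield
$\bar y = X/N$: the non-negative root of
$\beta D^2 + \alpha D + (C - \bar y) = 0$ (`invert_dose()`), zero when
the yield does not exceed background.

Two interval methods are implemented, mirroring the split observed among
biodosimetry software:

* **`curve_plus_yield`** (default): a Merkle-style combination. Exact
  (Garwood) chi-square limits on the Poisson yield are taken at 83%
  confidence, the fitted curve is bracketed by its delta-method envelope
  $\hat Y(D) \pm z_{0.83}\sqrt{g^\top\Sigma g}$ with $g = (1, D, D^2)$,
  and the dose limits are the crossings of the sample's yield limits
  with the *opposite* envelope bounds, found by root bisection on
  $[0,\,3\times$ max calibration dose$]$ to $10^{-6}$ Gy. Combining two
  83% bands targets roughly 95% overall confidence.
* **`yield_only`**: inversion of the exact Poisson yield limits at the
  full 95%, ignoring curve error — the behaviour of software that does
  not propagate curve uncertainty.

Exact Poisson limits are used rather than a normal approximation because
triage-mode samples of ~200 cells carry few dicentrics at low dose.
Estimates beyond the curve's maximum calibration dose are permitted but
always flagged `extrapolated` (extrapolation is discouraged in practice
and a documented source of bias in real exercises).

**A coverage caveat that matters.** The 83%/83% combination reaches its
nominal ~95% only when curve error and yield error are of comparable
size: the per-side miss probability is approximately
$\Phi\{-z_{0.83}(\sigma_c+\sigma_y)/\sqrt{\sigma_c^2+\sigma_y^2}\}$,
which is 2.6% per side when $\sigma_c = \sigma_y$ but grows toward 8.5%
as either source dominates. With a well-powered calibration (hundreds to
thousands of cells per dose) and a 200-cell blind sample, the curve error
is several times smaller than the yield error and the empirical coverage
of the 95% interval sits near 91% — the acceptance script measures
exactly this. This is a property of the field-standard construction, not
of this implementation (which reproduces ~94% coverage when the two error
sources are balanced); users wanting guaranteed nominal coverage can
raise `merkle.level`.

## Dispersion statistics

Homogeneous acute exposure implies Poisson scoring, tested per sample via
the dispersion index $\delta = \sigma^2/\mu$ of the per-cell counts
(sample variance, $N-1$ denominator — the manual convention; the index is
always computed from the full count spectrum, never from $(N, X)$ alone)
and the Papworth statistic

$$u = (\delta - 1)\sqrt{\frac{N-1}{2\,(1 - 1/X)}},$$

approximately standard normal under the Poisson null; $u > 1.96$ flags
significant overdispersion at $P < 0.05$. Both the one-sided
overdispersion flag and the two-sided flag (needed to discuss
underdispersion) are reported. At $N = 200$ and mean yields around 0.6
the null distribution of $u$ is visibly right-skewed (Kolmogorov–Smirnov
distance to the normal ≈ 0.026), so the one-sided false-positive rate is
close to 3.3% rather than the nominal 2.5%; the acceptance script
measures this rate. `mean_dispersion()` averages laboratories with equal
weight, regardless of cells scored.

## Dose definitions and conversion

Reference doses may be stated as *air kerma free in air* (what the beam
delivers, measured without the sample) or as *absorbed dose to blood*
inside the collection tube (obtained from radiation-transport
calculation); for this cobalt-60 geometry blood dose exceeds air kerma by
about 5.7%. `dose_conversion_table()` packages the three anchor pairs
2.56→2.71, 3.41→3.60, 4.54→4.80 Gy; between anchors the factor is
interpolated linearly in air kerma, outside them the nearest factor is
applied unchanged, and the blood→kerma direction inverts the forward map
numerically (round trip to $10^{-10}$ Gy). Conversions involving dose to
water are deliberately unsupported and fail loudly — the water/blood
relation is geometry-specific and not part of the packaged table; for
*comparison* purposes dose-to-water calibrations are matched to the
dose-to-blood reference coordinate (the in-medium quantity), which is how
mixed-definition exercises group them.

## ILC scoring

`evaluate_ilc()` judges each submission against the reference dose under
one or more comparison modes: `air_kerma`, `dose_to_blood`, or `matching`
(each laboratory compared to the coordinate matching its own calibration
definition). Per laboratory and sample it reports deviation, whether the
95% CI contains the reference, the Z-score
$z = (\hat D - D_{\mathrm{ref}})/\sigma_p$ with the conventional flags
($|z| > 1.96$ questionable, $|z| > 3$ unsatisfactory), the clinical
triage category (< 1 Gy low; 1–2 Gy, closed interval, medium; > 2 Gy
high), and a ±1 Gy band check (closed comparison). Per laboratory it
applies the two-condition systematic-bias rule — all samples deviating
with one sign *and* at least two CIs excluding the reference — and a
strict ranking check; across samples it reports Pearson correlations of
the labs' estimates, which expose laboratory-level effects.

The Z-score denominator is pluggable because proficiency-testing
practice varies: `robust` (default; 1.4826 × MAD of the participants'
estimates per sample), `ci` (each lab's own interval half-width / 1.96),
or `fixed` (a fraction of the reference dose). The choice is recorded in
the report. Identical estimates make the robust spread zero, which
propagates as an explicit error rather than an infinite Z.

## The synthetic generator: what it emulates, what it does not

`ilc_config()` + `simulate_ilc()` generate a full blinded exercise. The
defaults are the study conditions: three blind doses at 2.56/3.41/4.54 Gy
air kerma (2.71/3.60/4.80 Gy to blood), 14 laboratories, manual curve
coefficients drawn uniformly from $\alpha \in [0.01, 0.069]$ Gy$^{-1}$
and $\beta \in [0.031, 0.097]$ Gy$^{-2}$, background
$C \in [5\times10^{-4}, 2\times10^{-3}]$ (typical field values —
published exercises rarely print backgrounds), 200 cells per manual
blind sample and 3500 per semi-automatic one (so a full exercise scores
metaphases on the order of the tens of thousands a real semi-automatic
campaign reports), 9 calibration doses from 0 to 5 Gy with cells ramping
down from 5000 to 500 (high-dose points need fewer cells), and a 9:5
split of air-kerma vs dose-to-water calibrations. Semi-automatic scoring
draws its per-cell counts from a gamma-mixed Poisson (negative binomial)
with variance/mean in [1.05, 1.15]; any model matching the first two
moments is admissible for dispersion-level analyses, and the mixed
Poisson is the standard choice. Published coefficient ranges for
semi-automatic curves are typographically suspect (the same interval
0.003–0.026 printed for both $\alpha$ and $\beta$), so both ranges are
independent configuration fields rather than hard-coded.

Per-laboratory sub-streams are seeded deterministically from the master
seed, so a lab's data do not depend on how many labs are simulated — a
property the tests rely on. A lab's blind sample is generated at the
blind dose *expressed in the lab's own dose definition* and multiplied by
its `bias_factor`, which is how the generator reproduces both the
definition-mismatch mechanism (air-kerma labs underestimate dose-to-blood
references by ~5.7% of dose) and injectable laboratory bias.

The generator does **not** emulate metaphase image quality, culture
failure, slide-preparation problems, scorer-to-scorer variability within
a laboratory, partial-body exposure, or dose-rate effects. Passing tests
therefore demonstrate the correctness of the statistical chain under the
stated count models, not robustness to those real-world factors.

## Numerical and design choices

* Fitting uses per-dose totals, not per-cell records — the Poisson
  likelihood depends only on $(N_i, X_i)$.
* Replicate rows at one dose are pooled before fitting.
* CI root-finding: bisection to $10^{-6}$ Gy on $[0, 3\times$ max
  calibration dose$]$; bounds that would exceed that range are truncated
  with a warning.
* A yield at or below background gives dose 0 with a zero lower bound
  (the upper bound is still computed).
* Ties in a laboratory's estimates count as an incorrect ranking.
* Triage boundaries 1 and 2 Gy belong to the middle category.
* The ±1 Gy band check is closed (≤).
* Irradiation media and temperatures vary between laboratories' curve
  setups; no correction is applied for them (none is established).

## Problem sizes used by the tests and acceptance script

The test suite fits a few hundred simulated calibrations (120–500
replicates per property), checks CI coverage with 2000
fit-plus-estimate replicates, the U-test null with 5000 samples of 200
cells, and the bias rule over 200 simulated 14-laboratory exercises —
sizes chosen to keep Monte-Carlo standard errors a few per mille while
the whole suite runs in about a minute. `scripts/acceptance.R` recomputes
the same quantities from scratch at those sizes.

## Known limitations

* Whole-body acute exposure only: no Dolphin/contaminated-Poisson
  partial-body estimation, no G-function protraction correction, no
  Bayesian dose estimation.
* The Merkle-style interval inherits the coverage dependence on the
  error ratio described above.
* Curves are linear-quadratic only (no linear-only high-LET fits, no
  higher-order terms).
* The air-kerma/blood conversion table is geometry-specific; supplying
  your own anchors is supported and recommended for other setups.
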