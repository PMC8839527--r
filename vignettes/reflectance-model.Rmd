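---
title: "A five-parameter reflectance model for Baltic coastal waters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-parameter reflectance model for Baltic coastal waters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balticRrs)
```

## The model and its assumptions

`balticRrs` implements a semi-empirical model of remote-sensing
reflectance just below the sea surface, R_rs(λ) [sr⁻¹], for optically
complex coastal (Case 2) water at four bands: 420, 488, 555 and 620 nm.
The model is *semi*-empirical in the usual sense: the link between
reflectance and the inherent optical properties is the standard
radiative-transfer approximation

$$R_{rs}(\lambda) = \frac{f}{Q}(\lambda)\,
  \frac{b_b(\lambda)}{a(\lambda) + b_b(\lambda)},$$

while the links between the IOPs and the biogeochemical drivers are
purely statistical regressions calibrated on southern-Baltic station
data. The drivers are chlorophyll a (mg m⁻³), the sum of accessory
pigments ΣC (mg m⁻³), suspended particulate matter SPM (g m⁻³), its
inorganic fraction SPM_inorg (g m⁻³), and CDOM absorption at the 400 nm
reference wavelength (m⁻¹).

Assumptions worth making explicit:

* **Locality.** The regression constants are a local calibration for
  southern-Baltic coastal water; nothing in the functional forms
  guarantees transferability to other basins.
* **Band discreteness.** The model exists only at the four calibration
  bands. Requests at any other wavelength are errors, never
  interpolations; `nearest_band()` is provided solely for mapping
  radiometer channels onto bands (ties break toward the shorter
  wavelength, deterministically).
* **Additive budgets.** Total absorption is the exact sum
  a_ph + a_d + a_CDOM + a_w and total backscattering b_bp + b_bw; the
  pure-water terms are fixed constants with no temperature or salinity
  dependence.
* **f/Q as a per-band constant.** The radiance-distribution factor is
  treated as one number per band (0.07–0.13 sr⁻¹, increasing with
  wavelength), absorbing illumination geometry; the package does no
  radiative-transfer computation.

## Component models and their parameters

Two-parameter forms (the five-parameter model uses these):

$$a_{ph} = G\,\mathrm{Chl}^{F} e^{H\,\Sigma C/\mathrm{Chl}},\qquad
  a_{d} = K\,\mathrm{SPM}^{J} e^{L\,f_i},\qquad
  b_{bp} = C\,\mathrm{SPM}^{B} e^{D\,f_i},$$

with $f_i = \mathrm{SPM_{inorg}}/\mathrm{SPM} \in [0,1]$. The
exponential factors multiply the power law by between 1 and $e^{H}$ (or
$e^{L}$, $e^{D}$) as the composition ratio sweeps its range — a
second-order correction for *what kind* of material is present, on top
of *how much*. Single-driver power-law forms are kept alongside with
their own published constants (`one_param_coefficients()`).

The CDOM spectrum model is a quadratic in $u = \log_{10} a_{CDOM}(400)$:

$$a_{CDOM}(\lambda) = 10^{-M u^2 + N u - P}.$$

Two numerical points about this form:

* **Argument choice.** The quadratic acts on the *logarithm* of the
  driver. The alternative reading (quadratic in the raw driver) would
  make a_CDOM grow between 400 and 420 nm, which CDOM absorption spectra
  never do; the log-argument form reproduces the expected spectral decay
  and is adopted throughout.
* **Limited monotonicity.** A downward parabola in $u$ has a vertex at
  $u = N/2M$; at the red bands this sits near a_CDOM(400) ≈ 2.4–3.3 m⁻¹,
  so the fitted curve is increasing only over the observed coastal range
  and must not be extrapolated far beyond it.
* **Zero driver.** At a_CDOM(400) = 0 the model returns exactly 0, the
  continuous limit as $u \to -\infty$, avoiding log-of-zero.

Degenerate composition ratios are defined as 0/0 = 0 (no material, no
correction) while a positive numerator over a zero denominator is a
domain error: silent infinities would otherwise leak into the
exponentials.

The shipped constants live in `default_coefficients()`; they are the
single source of truth for the five-parameter model. Two published
inconsistencies are handled deliberately: the non-algal exponent at
420 nm is taken from the coefficient table (0.807) rather than the
slightly different equation text (0.809), and the one-parameter a_d
coefficient at 620 nm (0.002) — which breaks the monotone trend of the
other bands and disagrees with the two-parameter value by almost an
order of magnitude — is retained as printed for the one-parameter model
but flagged in its documentation and never used by the five-parameter
chain.

## Calibration

All fits are ordinary least squares after a log10 transform: power laws
become straight lines, the CDOM model becomes a quadratic polynomial,
and the residual-ratio corrections become straight lines in the
covariate after a natural-log transform. Log-space fitting matches the
multiplicative error structure of these quantities (they span orders of
magnitude) and makes noiseless closure exact. Observations that are
missing or non-positive are dropped *and counted*; nothing non-positive
ever reaches a logarithm. Composition covariates outside [0, 2] (pigment
ratio) or [0, 1] (inorganic fraction) are excluded as physically
implausible, with the exclusions reported.

`calibrate_all()` offers two procedures:

* **`"two_step"`** (default): fit the one-parameter power law, then fit
  an exponential to the ratio calculated/measured against the
  composition covariate, then compose (divide the coefficient by the
  prefactor, negate the rate, keep the exponent). This mirrors how such
  calibrations are historically built and reported. It is, however, not
  an exact estimator: the step-1 slope absorbs the in-sample covariance
  between the log-driver and the covariate, so even on noiseless data
  the recovered constants are only approximate (≈1% at n = 500 under the
  default population).
* **`"joint"`**: a single three-regressor OLS of log10(y) on
  [log10(driver), covariate]. On noiseless forward-model data this
  returns the generating constants to machine precision, which makes it
  the right tool for closure experiments; on noisy data it is also the
  statistically efficient choice.

The empirical f/Q per band is the per-station value
$R_{rs}(a+b_b)/b_b$ aggregated by the **median** (default). The
aggregation statistic is genuinely an open choice — nothing in the
source calibration states whether a mean or median was used — and the
median is preferred here because lognormal radiometric noise produces
heavy right tails that a mean chases. The mean remains available by
argument.

Fitted rate constants (D, H, L) may legitimately come out near or even
below zero on noisy data — the residual fits behind them are weak
(determination coefficients of a few percent are typical for the
particle families) — so the coefficient container accepts any finite
rate while still requiring positive power-law constants, water terms and
f/Q.

## Error statistics

Both error families are computed from measured/calculated pairs:
arithmetic (relative mean error ⟨ε⟩ and its standard deviation σ_ε) and
logarithmic (mean log error ⟨ε⟩_g, the standard error factor
x = 10^σ_log, and the asymmetric bounds σ₊ = x − 1, σ₋ = 1/x − 1).
Standard deviations use the population (1/N) denominator, matching the
convention of the published error tables this layout follows; a
sample-SD option exists but is off by default (for the N ≈ 10²–10⁴ used
here the difference is negligible). Statistics are held as fractions
internally and rendered ×100 in tables. Pairs with non-positive measured
values are excluded with a count — log statistics force positivity, and
the arithmetic ones follow the same filter so both describe the same
sample.

## The synthetic station generator

`generate_dataset()` emulates the statistical structure of a
southern-Baltic coastal cruise dataset so that calibration and error
statistics are testable end to end without field data:

* chlorophyll a, SPM and a_CDOM(400) are lognormal (medians 5 mg m⁻³,
  1.5 g m⁻³ and 1.0 m⁻¹; log10 spreads 0.4, 0.35 and 0.2), spanning the
  orders of magnitude seen in coastal populations;
* the inorganic SPM fraction is Beta(2, 3) (mean 0.4, full support in
  [0, 1]);
* the pigment ratio ΣC/Chl a is a truncated normal (0.35 ± 0.1 on
  [0.05, 1]);
* measured IOPs are forward-model values times 10^(σz) with σ = 0.14 by
  default — a standard error factor of 10^0.14 ≈ 1.38, in the range
  observed for coastal IOP regressions;
* radiometry is generated consistently: the station's true reflectance
  from the forward model, L_u = R_rs·E_d (with optional lognormal
  noise), E_u = Q·L_u with Q = 4 sr, and E_d varying lognormally around
  its scale to emulate changing illumination. The recorded reflectance
  column is L_u/E_d row-wise, so the defining ratio holds identically.

The marginals were calibrated once, analytically, so that the generated
absorption budget at 420 nm reproduces the observed Baltic split of
non-water absorption — on average about 68% CDOM, 20% phytoplankton and
12% non-algal particles. That CDOM dominance in the blue is the defining
optical feature of Baltic coastal water, and a synthetic population that
failed it would exercise the model in the wrong regime.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: cross-correlations between constituents
beyond the two structural couplings (pigments scale with chlorophyll,
inorganic matter with SPM); seasonal and spatial structure, upwelling
events, river plumes; depth structure (surface snapshot only);
non-lognormal outliers, instrument drift, or correlated errors between
quantities measured by the same instrument. Parameter-recovery results
on synthetic data are therefore a *necessary* check of the fitting
machinery, not evidence that the published constants are optimal for any
real station set.

Every stochastic routine takes an explicit seed, restores the caller's
RNG state, and two runs with identical parameters and seed are
byte-identical.

## Problem sizes and tolerances

The test suite uses n = 200–500 stations for calibration checks,
n = 1000 for the absorption-budget check (the mean CDOM share is then
within ±5 percentage points of its target), and n = 10⁴ where a law of
large numbers is asserted (the standard error factor recovers 10^σ
within 2%). Noiseless closure is asserted at 10⁻⁸ with the joint fit;
stochastic recovery is asserted against analytic OLS standard errors
(4·SE), not arbitrary percentages — rate constants on a narrow covariate
are intrinsically weakly identified, and a flat relative tolerance would
either mask that or fail spuriously. Exact identities (budget
additivity, the f/Q round trip through the forward model) are asserted
at 10⁻¹².

## Known limitations

* Four fixed bands; no spectral interpolation or hyperspectral support.
* A per-band constant f/Q; no dependence on sun angle or sea state.
* No uncertainty propagation beyond OLS standard errors, and no
  hypothesis tests or confidence intervals on the error statistics.
* The one-parameter a_d model at 620 nm carries a published coefficient
  that is almost certainly misprinted (see above); it is faithfully
  reproduced but should not be trusted quantitatively.
* Calibration assumes multiplicative, log-symmetric measurement error;
  additive noise floors (relevant for very clear water) are not
  modelled.
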