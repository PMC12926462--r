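---
title: "Methods: isotope-derived iWUE along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-derived iWUE along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isowue)
library(dplyr)
```

## The model

Leaf tissue discriminates against ¹³C during CO₂ uptake, and the strength
of that discrimination records the ratio of intercellular to atmospheric
CO₂ over the leaf's lifetime. `isowue` turns a measured leaf δ¹³C into
intrinsic water-use efficiency through a chain of closed-form inversions:

1. **Discrimination.** Δ¹³C = (δₐ − δₚ)/(1 + δₚ/1000), with δₐ the δ¹³C of
   atmospheric CO₂ and δₚ that of the leaf (`discrimination()`).
2. **Environment.** Atmospheric pressure follows the international
   standard atmosphere, P(z) = P₀(1 − 0.0065 z / 288.15)^5.2561
   (`barometric_pressure()`); the CO₂ compensation point in the absence of
   dark respiration is Γ\* = Γ\*₂₅ · (P/P₀) · exp(ΔHₐ(T − 298)/(R·T·298))
   (`gamma_star()`), with ΔHₐ = 37 830 J mol⁻¹.
3. **Inversion to CO₂.** Four formulations:
   * *simple* C₃: Cᵢ = Cₐ(Δ − a)/(b − a), with a = 4.4 ‰ (diffusion in
     air) and b = 29 ‰ (Rubisco carboxylation);
   * *photoresp* C₃: adds the photorespiratory correction f′·Γ\*/pCₐ with
     f′ = 12 ‰;
   * *mesophyll* C₃: additionally resolves the drawdown from the
     intercellular space to the chloroplast through the conductance ratio
     g_sc/g_m = 0.79 and the mesophyll diffusion fractionation
     a_m = 1.8 ‰, returning C_c;
   * C₄: Δ = a + (b₄ + (b₃ − s)φ − a)·Cᵢ/Cₐ with b₃ = 30 ‰, b₄ = −5.7 ‰,
     s = 1.8 ‰ and bundle-sheath leakiness φ = 0.21.
4. **iWUE.** iWUE = (Cₐ − Cᵢ)/1.6 µmol CO₂ mol⁻¹ H₂O (Cᵢ replaced by C_c
   under the mesophyll formulation); 1.6 is the H₂O:CO₂ diffusivity ratio.

All constants live in one registry (`iwue_constants()`) and every batch
result records the atmospheric values used.

### Design choices in the equation chain

Several quantities the chain needs are not fixed by the measurement
context and had to be set as package defaults:

* **δ¹³C of air and Cₐ** default to −8.5 ‰ and 415 ppm — approximate
  global means for a 2021 growing season — and are arguments of every
  entry point. Site-resolved values should be supplied when available.
* **Γ\*₂₅** defaults to 42.75 µmol mol⁻¹, a standard leaf-physiology
  reference value; it is configurable because published estimates vary by
  a few percent.
* **Temperature entering Γ\*** is the site's mean annual temperature
  converted to kelvin (column configurable). For a growing-season-
  integrated proxy such as leaf δ¹³C this is the least-committal choice;
  users with growing-season temperatures can point `temp_col` at them.
* **Sign of the photorespiratory term.** The term f′·Γ\*/pCₐ is often
  typeset with a minus sign inside the Cᵢ inversion, which corresponds to
  a forward model in which photorespiration *increases* discrimination.
  The physically conventional forward model is
  Δ = a + (b − a)Cᵢ/Cₐ − f′·Γ\*/pCₐ, whose inversion *adds* the term. The
  package defaults to the latter (`photoresp_sign = "model"`) and offers
  the literal typeset sign (`"printed"`) as a switch; each convention
  round-trips exactly with its own forward model.
* **Unit harmonisation.** Γ\* (µmol mol⁻¹) is converted to a partial
  pressure via P before division by pCₐ, making the correction a
  dimensionless ‰-scale term. Because pCₐ carries the same P, the
  pressure cancels in the ratio and enters only through Γ\* itself (which
  scales with P/P₀).
* **The mesophyll inversion.** The formulation solves
  Δ = a + (b − a)Cᵢ/Cₐ − (g_sc/g_m)(b − a_m)(Cₐ − Cᵢ)/Cₐ − f′Γ\*/pCₐ for
  Cᵢ and then applies the drawdown C_c = Cᵢ − (g_sc/g_m)(Cₐ − Cᵢ), which
  follows from A = g_sc(Cₐ − Cᵢ) and Cᵢ − C_c = A/g_m. Two exact
  contracts pin the algebra down: as g_sc/g_m → 0 the result converges to
  the photorespiratory formulation, and C_c < Cᵢ within the formulation
  whenever b > a_m. Note that *across* formulations the mesophyll-inferred
  concentration at a given Δ is higher than the simple-model Cᵢ — part of
  the observed discrimination is attributed to the mesophyll step rather
  than to stomatal closure — so mesophyll-formulation iWUE is
  systematically lower.
* **Out-of-range results.** A C₄ leaf with Δ outside
  [a + (b₄ + (b₃ − s)φ − a), a] = [0.222, 4.4] ‰ (or a C₃ leaf outside its
  band) implies Cᵢ/Cₐ outside [0, 1]. Such rows are flagged
  (`in_range = FALSE`) and retained with a warning; `drop_out_of_range =
  TRUE` removes them. Values are never clamped, because clamping would
  silently move samples onto the model boundary and bias any downstream
  trend.

## The synthetic transect generator

`simulate_transect()` produces datasets with the statistical structure the
analysis assumes, so every downstream stage can be tested against a known
truth without any external data.

* **Layout.** 98 sites uniform over 40–3800 m (no site-placement law is
  assumed); six 1 m² plots per site; one to three dominant species per
  site with three replicate leaves each — a typical design for grassland
  transect surveys.
* **Climate.** MAT (7.6–23.6 °C) and VPD (0.2–1.3 kPa) decrease, MAP
  (730–1760 mm) and aridity index (0.4–1.7) increase linearly with
  elevation, each plus *bounded uniform* noise with half-width 0.16 of the
  envelope span. Uniform noise is a deliberate choice: it guarantees the
  generated marginals stay inside the stated envelopes for every seed,
  while leaving enough elevation-independent variation that collinearity
  diagnostics are meaningful rather than degenerate. Setting
  `climate_noise_frac = 0` makes the covariates exactly collinear with
  elevation, which the tests use to exercise the VIF screen's
  infinite-VIF path.
* **True iWUE.** Per sample,
  iWUE = intercept + slope·(z − z₀)/1000 + β_VPD·(VPD − E[VPD|z]) +
  species intercept + residual, with defaults: C₃ intercept 65 and slope
  +20 µmol mol⁻¹ km⁻¹; C₄ intercept 150 and slope −5; β_VPD = −15 (C₃)
  and +15 (C₄) µmol mol⁻¹ kPa⁻¹; species SD 8; residual SD 6. The slope
  multiplies elevation and the VPD term multiplies only the VPD *anomaly*
  (departure from its elevation expectation), so the configured slope is
  the total elevational trend — exactly what the mixed model estimates —
  while the anomaly term gives the attribution stage a genuine,
  pathway-antisymmetric VPD signal to recover. The C₃ trend magnitude
  corresponds to leaf δ¹³C rising by roughly 1.9 ‰ per 1000 m; the C₄
  intercept keeps the implied discrimination safely inside the narrow
  valid C₄ band.
* **Observation model.** True iWUE → Cᵢ (inverse of the iWUE definition)
  → Δ via the pathway's forward discrimination model (the same
  formulation later used for inversion) → leaf δ¹³C. At zero noise the
  full chain is an exact identity, which the tests verify at 10⁻⁹
  relative tolerance. Draws implying Cᵢ/Cₐ outside [0, 1] are resampled
  (new residual, up to 100 rounds) and flagged if any persist.
* **δ¹⁸O** is phenomenological: a quadratic in elevation peaking at
  1800 m plus Gaussian noise. No Péclet or source-water model is claimed;
  the column exists as a covariate with the right hump shape.
* **Stoichiometry.** Leaf C rises and leaf N and P fall with elevation
  (P faster than N), so C:P and N:P increase along the gradient; soil
  organic carbon, total N and soil C:N drift upward. These loadings are
  moderate by construction so the stoichiometric covariates correlate
  with elevation without re-triggering the collinearity screen.
* **Determinism.** All randomness flows from a single integer seed;
  stages draw from fixed offsets of it (sites +0, community +1, isotopes
  +2), so each stage and the whole simulation are bit-reproducible.

What passing recovery tests on these data shows — and does not show: the
generator encodes linear trends, Gaussian species effects and independent
residuals. Real transect data have spatial autocorrelation, species
turnover along the gradient, elevation-dependent replicate counts and
measurement error in the covariates, none of which are simulated. Recovery
here validates the *machinery* (the equation chain, the estimators, the
attribution pipeline), not the field inference itself.

## Trend estimation

`fit_trend_lmm()` fits `response ~ elevation + (1 | species)` by REML via
`lme4`, treating dominant-species identity as a random intercept (random
slopes are available but off by default, since a random intercept is the
most parsimonious structure consistent with per-species baseline
differences). Fixed-effect p-values use the Satterthwaite approximation
(`lmerTest`), and the choice is recorded in the fit metadata. Missing
rows are removed listwise with a count message. Singular fits (zero
estimated species variance) return with a warning rather than failing,
and in that case the fixed estimates coincide with ordinary least
squares.

Variance explained is decomposed as

* R²_marginal = σ²_fixed / (σ²_fixed + σ²_species + σ²_resid),
* R²_conditional = (σ²_fixed + σ²_species) / (σ²_fixed + σ²_species + σ²_resid),

with σ²_fixed the variance of the fixed-effect linear predictor
(`r2_components()`, `r2_nakagawa()`). By construction
R²_marginal ≤ R²_conditional and both lie in [0, 1].

## Driver attribution

`vif_screen()` iteratively computes VIF_j = 1/(1 − R²_j) from regressing
each feature on the others and drops the single highest-VIF feature while
any VIF ≥ 10, recomputing after each drop. Dropping one feature at a time
is the standard conservative rule and makes the procedure deterministic;
features are processed in alphabetical order so exact ties (e.g. a
duplicated column, which yields infinite VIFs) resolve reproducibly, and
the outcome is invariant to the column order of the input. On the default
synthetic transect the screen typically removes `elevation_m` itself: the
four climate covariates jointly predict elevation with R² > 0.9, so the
screen — correctly — refuses to keep both. The remaining climate
variables carry the elevational signal.

`fit_attribution()` fits gradient-boosted regression trees (XGBoost) with
conservative defaults — depth 3, learning rate 0.1, subsample and column
subsample 0.8, minimum child weight 3, up to 500 rounds with early
stopping (patience 25) on a seeded 80/20 split — all recorded in the
result object. SHAP values come from the exact TreeSHAP algorithm
(`predict(..., predcontrib = TRUE)`); per observation they sum to the
prediction minus the base value, which the tests assert. Importance is
the mean absolute SHAP value per feature. The *direction* of a feature's
effect is summarised as the sign of the Spearman correlation between the
feature's values and its SHAP values — a monotone summary of the
dependence plot that is robust to the curvature boosted trees produce.
Models are fitted separately per pathway, since the scientific question
is precisely whether drivers act with opposite signs in C₃ and C₄
grasses.

## Numerical choices and degenerate inputs

* Round-trip identities (forward discrimination vs inversion) hold to
  10⁻⁹ relative tolerance; the inversions are single linear solves, so
  the error is pure floating-point noise.
* Degenerate constant sets (b = a; the C₄ slope b₄ + (b₃ − s)φ − a = 0,
  i.e. φ ≈ 0.358 at the other defaults; a zero mesophyll denominator) are
  rejected with explicit errors at a √ε threshold rather than producing
  huge finite values.
* Isotope ratios must be positive; δₚ = −1000 ‰ (a zero ratio) is
  rejected before the division in the discrimination formula.
* Leaf δ¹³C outside [−40, −5] ‰ triggers a plausibility warning but is
  processed, because screening is the caller's decision.
* The all-zero community and the all-zero weight vector are errors for
  the Shannon index and the community-weighted mean; an empty plot
  contributes a zero count to mean species richness.

## Problem sizes used by the test suite

The recovery studies run at the generator's default size (98 sites,
~600 leaves). Coverage of the true C₃ slope is assessed over 50
independent transects; single-driver attribution recovery over 20
seeded datasets of 250 observations; round-trip identities over 1000
random parameter draws. These sizes give the binomial checks (e.g.
"coverage ≥ 90 %", "ranked first in ≥ 95 %") enough resolution to fail
informatively while keeping the default suite fast.

## Known limitations

* φ (bundle-sheath leakiness) is fixed at 0.21; in the field it varies
  with light and temperature. The constant is exposed in
  `iwue_constants()` so sensitivity sweeps over its plausible range are
  one `purrr::map()` away, but no environment-dependent leakiness model
  is provided.
* f′ and g_sc/g_m carry literature uncertainties (±4 ‰, ±0.07); the
  defaults are the central values, and sweeps over the bounds are the
  user's responsibility.
* The mixed models are Gaussian with a single random factor; no crossed
  or nested random effects, and no generalised responses.
* δ¹⁸O is carried as a covariate only — no mechanistic evaporative
  enrichment model.
* SHAP interaction values and hyperparameter search are deliberately out
  of scope; the attribution defaults favour reproducibility over squeezed
  predictive accuracy.
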