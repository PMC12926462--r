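# isowue

Derive and explain the intrinsic water-use efficiency (iWUE) of C₃ and C₄
grassland plants from leaf carbon isotopes along elevational gradients.

## The problem

Leaf δ¹³C integrates the balance between photosynthetic CO₂ demand and
stomatal supply over the life of the leaf, which makes it a scalable proxy
for intrinsic water-use efficiency — the ratio of net assimilation *A* to
stomatal conductance to water *g*<sub>s</sub>. Along mountain transects,
temperature, precipitation, vapour pressure deficit (VPD) and atmospheric
pressure co-vary over short distances, and C₃ and C₄ grasses respond to
that joint gradient in opposite ways. `isowue` implements the full
analysis pipeline for such a transect study:

1. **Physiology** — the carbon isotope discrimination equation chain.
   Discrimination is
   Δ¹³C = (δ¹³C<sub>a</sub> − δ¹³C<sub>p</sub>) / (1 + δ¹³C<sub>p</sub>/1000),
   inverted to the intercellular CO₂ mole fraction with, for C₃ leaves,

   - *simple*: Δ = a + (b − a)·C<sub>i</sub>/C<sub>a</sub>
   - *photoresp*: Δ = a + (b − a)·C<sub>i</sub>/C<sub>a</sub> − f′·Γ\*/pC<sub>a</sub>
   - *mesophyll*: the same with the CO₂ drawdown from the intercellular
     space to the chloroplast resolved through g<sub>sc</sub>/g<sub>m</sub>
     and (b − a<sub>m</sub>), yielding C<sub>c</sub>

   and for C₄ leaves the bundle-sheath leakiness model
   Δ = a + (b₄ + (b₃ − s)φ − a)·C<sub>i</sub>/C<sub>a</sub>.
   Γ\* is temperature- and pressure-corrected via an Arrhenius response and
   the barometric pressure profile P(z), and finally
   iWUE = (C<sub>a</sub> − C<sub>i</sub>)/1.6 (µmol CO₂ mol⁻¹ H₂O).
2. **Synthetic transect generator** — a seeded simulator of a ~98-site
   grassland transect (40–3800 m) with climate envelopes, species random
   effects, pathway-specific elevational iWUE trends and stoichiometric
   covariates, with the ground truth stored for recovery tests.
3. **Community metrics** — Shannon–Wiener diversity, mean per-plot species
   richness, and community-weighted trait means.
4. **Trend estimation** — REML linear mixed models with a species random
   intercept, and the variance-decomposition (marginal/conditional)
   R² of Nakagawa type.
5. **Driver attribution** — iterative VIF screening (threshold 10),
   gradient-boosted regression trees, and TreeSHAP values; importance is
   the mean |SHAP| per feature and each feature's direction of effect is
   the sign of the rank correlation between its values and its SHAP
   values.

All user-facing functions are data-frame-first and return tibbles, so the
stages chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(isowue)
library(dplyr)

sim <- simulate_transect(transect_config(seed = 1))   # 98 sites, 597 leaves
tbl <- compute_iwue(sim$data)                         # delta13C -> iWUE

summarise_d13c_by_pathway(tbl)
#>   pathway     n mean_d13c sd_d13c
#> 1 C3        378     -27.2   1.86
#> 2 C4        219     -11.0   0.159

fit_pathway_trends(tbl)$C3
#> <iwue_lmm> iwue ~ elevation_km + (1 | species_id)
#>   n = 378 observations, 12 groups (species_id); REML, p-values: Satterthwaite (lmerTest)
#>          term estimate std_error     df statistic    p_value conf_low conf_high
#>   (Intercept)    63.43    2.3362  13.39     27.15  4.218e-13    58.40     68.47
#>  elevation_km    19.66    0.3724 367.41     52.78 1.346e-173    18.92     20.39
#>   R2 marginal = 0.775, conditional = 0.907
```

C₃ leaves are strongly depleted relative to C₄ leaves (δ¹³C −27.2 ‰ vs
−11.0 ‰), and C₃ iWUE rises by ≈ 19.7 µmol mol⁻¹ per 1000 m of elevation
(the generator's true trend is 20); elevation alone explains 78 % of the
variance and elevation plus species identity 91 %. The C₄ subset gives a
weak negative trend (−5.5 per 1000 m, truth −5). Driver attribution on
the C₃ subset ranks VPD first (mean |SHAP| 6.4 µmol mol⁻¹) with a negative
dependence sign, matching the simulated ground truth:

```r
fit_attribution(filter(tbl, pathway == "C3"), seed = 1)
#> <iwue_attribution> iwue ~ 11 features, n = 378, seed = 1
#>   feature importance dependence_rho dependence_sign rank
#>   vpd_kpa      6.359         -0.971              -1    1
#>     mat_c      5.557         -0.913              -1    2
#>        ai      2.057          0.883               1    3
#>   ...
```

`run_pipeline("out/")` chains all stages and writes per-stage CSV
artifacts plus a manifest recording every constant, seed and file hash.

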