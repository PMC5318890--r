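# lakexergy

Ecosystem-health assessment of shallow eutrophic lakes from plankton
monitoring data, for limnologists and water-quality analysts. The package
computes two thermodynamic community indicators, explains them with a
gradient-boosted regression-tree model, and maps them across the basin:

* **Eco-exergy density** `Ex` (kJ/L) — the work energy stored in the
  plankton community's biomass and genetic information, relative to
  detritus:

  `Ex = 18.7 × [β_alg·f_phy·ΣC_phy + f_zoo·(β_pro·ΣC_pro + β_rot·ΣC_rot + β_cla·ΣC_cla + β_cop·ΣC_cop)]`

  with wet biomass `C` in mg/L, conversion factors `f_phy = 0.16`,
  `f_zoo = 0.06`, group weighting factors β = 20 / 39 / 163 / 232 / 232
  (algae, protozoa, rotifers, cladocerans, copepods) and 18.7 kJ/g the
  chemical exergy of detritus.
* **Specific eco-exergy** `Ex_sp = Ex / C_total` (kJ/g) — the
  biomass-weighted mean β times 18.7; the community's mean development
  level. High `Ex` with low `Ex_sp` signals eutrophication.

Around the indicators, the package provides the full analysis chain:

* three-tier handling of below-detection-limit records (drop / half-LOD
  substitution / truncated-normal imputation from Normal(LOD/2, LOD/4)
  clamped to [0, LOD]);
* Pearson-correlation screening of collinear predictors (`|R| > 0.7`,
  `p < 0.05`, preference-ordered thinning);
* a from-scratch gradient boosting machine (Gaussian loss, best-first
  trees, 1500 iterations, interaction depth 5, learning rate 0.005,
  5-fold CV iteration selection), with Friedman-style relative influence
  and exact data-average partial dependence (one and two variables);
* model adequacy: `R²`, NSE, RSR, PBIAS with the gate NSE > 0.5,
  RSR ≤ 0.7, |PBIAS| ≤ 25 (`NSE = 1 − RSR²` holds exactly);
* inverse-distance-weighted interpolation of station values onto a grid;
* a seeded synthetic survey generator (33 stations × 12 months, published
  marginal statistics and censoring rates, known nonlinear
  abiotic-to-biomass response functions) so every stage is testable
  against ground truth.

## Worked example

```r
library(lakexergy)

community <- data.frame(
  taxon = c("phytoplankton", "protozoa", "rotifera", "cladocera", "copepoda"),
  group = c("algae", "protozoa", "rotifera", "cladocera", "copepoda"),
  wet_biomass_mg_per_L = c(12, 0.4, 0.2, 1.1, 0.9))

ex <- eco_exergy_density(community)   # J/L
sp <- specific_eco_exergy(community)  # kJ/g
cat(sprintf("eco-exergy: %.2f J/L = %.3f kJ/L\n", ex, ex / 1000))
cat(sprintf("specific eco-exergy: %.1f kJ/g\n", sp))
#> eco-exergy: 1292.77 J/L = 1.293 kJ/L
#> specific eco-exergy: 622.7 kJ/g
```

1.29 kJ/L is a typical cool-season community; 622.7 kJ/g sits between the
all-algae floor (18.7 × 20 = 374 kJ/g) and the copepod ceiling
(18.7 × 232 = 4338.4 kJ/g), reflecting the zooplankton share of converted
biomass.

A full synthetic campaign, fitted and mapped end to end:

```r
res <- run_pipeline(run_config(seed = 1), "run_out")
res$adequacy$Ex_kJ_per_L      # NSE/RSR/PBIAS report for eco-exergy
res$influence$Ex_kJ_per_L     # relative influence (%), decreasing
```

The same chain is laid out as a readable sequence of numbered scripts
under `analysis/` (simulate → resolve censoring → indicators → screening
→ boosted models → maps), each writing its tables under
`results/analysis/`. On the default seed the boosted model recovers the
generator's truth: the three true drivers (WTEMP, PO4_P, PH) carry ~95%
of the relative influence for eco-exergy, the known pure-noise predictor
stays below 1%, and both indicators pass the adequacy gate (eco-exergy
NSE 0.90, RSR 0.32 in-sample).

## Layout

```
R/                  package code: synthetic data, censoring, exergy,
                    screening, boosting (+ src/ C++ split search),
                    evaluation, spatial, pipeline
analysis/           numbered narrative scripts over the package
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette: models, assumptions, design choices
inst/extdata/       published 15-variable correlation matrix (CSV fixture)
```
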