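# seedallometry

Seed composition does not scale proportionally with seed size. In barrel
medic (*Medicago truncatula*), single-seed measurements show a systematic
rise in nitrogen content (≈ +0.17 %N mg⁻¹), a fall in hydrogen content
(≈ −0.14 %H mg⁻¹) and a decline in δ²H with seed weight — the signature
of lipid-rich small seeds giving way to S-poor-protein-rich large seeds.
This package implements the computational machinery needed to establish
such *seed metabolic allometry* from single-seed data, for seed
physiologists and metabolomics analysts:

* **Elemental deconvolution** — water/mineral correction (÷0.85) of CHNS
  elemental analysis and nonnegative least-squares inversion of the mass
  balance `e = Wᵀ·w` into four biochemical components (carbohydrate,
  S-rich albumin, S-poor proteins + other N compounds, lipid), plus the
  lipid hydrogen mole fraction *x*.
* **δ²H isotope mass balance** — δ_source = δ_wl(1+ε_A) + ε_A with
  ε_A = −171 ‰; per-class exchange
  δ = (1−f)·δ_source + f·(δ_wp(1+ε_H) + ε_H) − Δ with ε_H = +158 ‰ and
  (f, Δ) of (0.33, 0 ‰), (0.14, 80 ‰), (0.75, 70 ‰) for starch, protein
  and lipid; seed mixture δ_seed = (1−x)·δ_other + x·δ_lipids, under
  three leaf/pod water scenarios.
* **Allometry statistics** — per-analyte OLS regressions on seed weight,
  Bonferroni control (α/m = 2.05 × 10⁻⁴ at m = 244), volcano tables
  (−log₁₀ p against the OPLS pq1 loading), and exhaustive best-subset
  regression with per-variable best-R² scores.
* **Multivariate models** — PCA with 99 % Hotelling T² outlier
  screening, OPLS with a continuous response (NIPALS, one predictive +
  n orthogonal components), 7-fold cross-validated Q² = 1 − PRESS/TSS,
  CV-ANOVA model significance, and Ward clustering of scores.
* **A synthetic cohort generator** — eight accessions with their natural
  weight ranges, noise calibrated to the reported regression R² values,
  and a 244-analyte metabolome with weight-correlated metabolite classes
  and paired amino-acid / degradation-product columns, so the entire
  pipeline runs and is tested without any measurement data.

## Worked example

The `analysis/` scripts run the full workflow on the default synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # two 160-seed cohorts, 244 analytes
Rscript analysis/02_compose.R     # elemental allometry + deconvolution
Rscript analysis/03_isotope.R     # delta-2H mass balance vs observation
Rscript analysis/04_metabolome.R  # OPLS, volcano, subsets, clusters
```

Output of the composition leg:

```
%N on weight: slope +0.169 %/mg (95% CI +0.133..+0.204), R2 = 0.36
%H on weight: slope -0.139 %/mg (95% CI -0.171..-0.107), R2 = 0.32
median inverted composition: carb 0.57, albumin 0.14, S-poor protein 0.26, lipid 0.10 (total 1.07)
biochemical-mode cohort: latent fractions recovered to 5.1e-14
lipid fraction vs weight (biochemical cohort): slope -0.0167 per mg (p = 2.8e-89)
```

The regressions recover the allometric slopes the generator embeds
(+0.17 and −0.14 are inside both confidence intervals) at the calibrated
R², and on the cohort whose elemental data come from the exact mixing
model, inversion recovers the latent component fractions to machine
precision, with the lipid fraction falling with seed weight.

The isotope leg:

```
delta-2H on lipid H mole fraction: slope +124.9 permil per unit x, R2 = 0.33 (p = 1.1e-15)
scenario (a): RMSE observed vs predicted = 5.0 permil
scenario (b): RMSE observed vs predicted = 6.1 permil
scenario (c): RMSE observed vs predicted = 14.3 permil
delta-2H vs seed weight: slope -3.07 permil/mg, R2 = 0.31 (declines with weight)
delta-13C shows no weight relation: R2 = 0.000
```

Observed δ²H rises with the lipid H mole fraction (the lipid H pool is
²H-enriched) and declines with seed weight, and scenario (a) — moderate
leaf–pod water enrichment — tracks the observations most closely.

The metabolome leg:

```
PCA screen: 3 of 160 seeds outside the 99% Hotelling region
OPLS: R2Y = 0.99, Q2 = 0.94 (7-fold), P_CV-ANOVA = 3e-96
volcano: 40 of 244 analytes below the Bonferroni threshold (0.000205)
```

The OPLS model is highly explicative and predictive of seed weight; the
volcano recovers essentially all 40 truly weight-linked analytes with
family-wise error control.

See `vignettes/seed-allometry-methods.Rmd` for the models, their
assumptions, parameter choices, and what the synthetic cohorts do and do
not emulate.

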