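---
title: "Methods: seed metabolic allometry from elemental, isotopic and metabolomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed metabolic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedallometry)
```

This vignette explains the models and procedures the package implements,
the choices made where the design was genuinely open, and what the
synthetic cohorts can and cannot tell you about real seed data.

## The scientific problem

Seed size is widely used as a proxy for seed quality, on the assumption
that a larger seed simply holds proportionally more reserve material. In
barrel medic (*Medicago truncatula*), single-seed measurements show
instead that composition scales *allometrically*: nitrogen content rises
with seed weight (about +0.17 %N per mg), hydrogen content falls (about
−0.14 %H per mg), and the hydrogen isotope composition (δ²H) declines,
all reflecting a shift from lipid-rich small seeds towards S-poor-protein
rich large seeds. The package provides the three computational layers
used to establish this: (1) deconvolution of CHNS elemental analysis into
biochemical components, (2) an isotope mass balance predicting bulk seed
δ²H from lipid content, and (3) uni- and multivariate statistics linking
a 244-analyte single-seed metabolome to seed weight.

## Elemental deconvolution

Measured %C, %N, %S and %H refer to whole-seed weight. Residual
non-extractible water (11 %) and minerals (4 %) carry no measured C/N/S
and dilute the organic matter, so observed fractions are divided by
0.85 (`correction_policy()`) before the mass balance.

The corrected composition is modelled as a nonnegative mixture of four
components of known elemental composition (`component_reference()`):

| component | C | N | S | H |
|---|---|---|---|---|
| carbohydrate (starch-like) | 0.400 | 0 | 0 | 0.066 |
| albumin (S-rich protein) | 0.505 | 0.187 | 0.027 | 0.069 |
| S-poor proteins + other N compounds | 0.519 | 0.194 | 0.001 | 0.068 |
| lipid (fatty-acid-like) | 0.760 | 0 | 0 | 0.120 |

`invert_composition()` minimises the sum of squared differences between
modelled and corrected observed composition subject to nonnegativity,
using the Lawson–Hanson active-set nonnegative least-squares solver —
an exact, deterministic convex solve with no random initialisation, so
results are bit-stable. Two deliberate choices:

* **No sum-to-one constraint.** The system is square (4 equations, 4
  unknowns); forcing the total would over-constrain it. The total is
  reported, and a warning is raised when it leaves [0.90, 1.10], which in
  practice flags inconsistent elemental data.
* **Residuals are reported, not hidden.** `compose_seeds()` carries the
  per-element absolute misfit for every seed.

The *lipid hydrogen mole fraction* `x` is the share of seed H atoms
contributed by lipids, computed from the component fractions and the
reference H column; because all H atoms weigh the same, weight shares
equal mole shares.

### A caution on identifiability

The 4×4 system is poorly conditioned in one direction: if %C is truly
constant while %N rises and %H falls with weight, the least-squares
solution trades carbohydrate against lipid strongly (the lipid estimate
*rises* with weight even as %H falls). Real seeds resolve this because
%C co-varies consistently with composition; elemental tables with an
artificially constant %C will not. This is why the composition and
isotope legs of the bundled analysis run on the biochemical-mode cohort
(below), whose elemental data are exactly consistent with a known
composition, and it is a genuine limitation to keep in mind when
interpreting component trends from sparse elemental data.

## The δ²H mass balance

Delta values are ratios relative to an international standard
(`ratio_to_delta()`), reported in ‰ but manipulated internally as
dimensionless fractions: the model equations multiply δ by ε terms,
which is only dimensionally consistent in fractional form.

The prediction composes three steps (`predict_seed_delta2h()`):

1. **Source metabolites** inherit leaf water corrected for fractionation
   in NADPH reduction: δ_source = δ_wl(1 + ε_A) + ε_A with ε_A = −171 ‰.
2. **Each metabolite class** exchanges a fraction *f* of its H with pod
   water (ε_H = +158 ‰) and pays a synthesis fractionation Δ:
   δ = (1 − f)·δ_source + f·(δ_wp(1 + ε_H) + ε_H) − Δ, with
   (f, Δ) = (0.33, 0 ‰) for starch, (0.14, 80 ‰) for proteins and
   (0.75, 70 ‰) for lipids.
3. **The seed** mixes a lipid pool and a non-lipid pool along the lipid
   H mole fraction: δ_seed = (1 − x)·δ_other + x·δ_lipids, exactly
   affine in x. δ_other is the *unweighted* mean of the protein and
   starch values, as the model defines it; a weighted variant is
   available through `other_weights` but is off by default.

Leaf and pod water were not measured, so three scenarios bracket them
from source water at −33 ‰: (a) leaf +60 ‰ / pod +30 ‰, (b) leaf
+75 ‰ / pod at source, (c) both waters at 0 ‰ absolute. Scenario (a) is
the default for generation and reporting, being the one that tracks
observations most closely; on the bundled synthetic cohort it is also
the scenario with the smallest observed-vs-predicted RMSE, by
construction. Useful anchors (scenario c): δ_source = −171 ‰ at
δ_wl = 0; the x = 0 endpoint is −133.685 ‰ and the x = 1 endpoint
+5.75 ‰. A noted model tension, left as stated: about two sevenths of
amino-acid H atoms are exchangeable, yet the model's f for proteins is
0.14 (≈ one seventh); the package follows the stated f values.

## The synthetic cohorts

No per-seed measurements are distributed, so `simulate_cohort()`
generates cohorts with the statistical structure the analyses assume.
Defaults are the study conditions: eight accessions with their natural
weight ranges (1.0–8.6 mg overall), 20 seeds per accession (160 seeds),
244 metabolome analytes. Weights follow a Beta(2, 2) rescaled to each
accession's range — mild central tendency without edge pile-up.

Two generation modes:

* **Elemental mode** (default): %N and %H are linear in weight with the
  allometric slopes; %C and %S have constant means. Noise SDs are
  calibrated as σ² = Var(signal)·(1 − R²)/R² so the weight regressions
  achieve the reported R² (0.36 for %N) on average; the same calibration
  sets the δ²H noise against a target R² of 0.38 on x.
* **Biochemical mode**: carbohydrate (0.37) and albumin (0.13) fractions
  are constant, the lipid fraction decays with weight
  (`0.08 + 0.14·exp(−0.4(w − 1))`, chosen to give lipid-rich ~22 % small
  seeds decaying towards 8 %), S-poor proteins take the remainder, and
  elemental data come from the exact forward mixing model — so
  correct-then-invert recovers the latent truth to solver precision.

The elemental intercepts (5.83 %N, 7.14 %H at the 1 mg boundary minus
one slope unit) put %N near 6 and %H near 7 in the smallest seeds; they
are calibration choices, not reported constants. δ¹³C, δ¹⁵N and δ³⁴S are
weight-independent Gaussian draws — the study found no weight relation
for them, and the generator emulates exactly that.

The metabolome draws log-intensities as
`baseline + sign·effect·(w − w̄) + accession offset + noise`, with
hexoses, amino acids and nucleosides rising with weight; disaccharides,
fatty acids, organic acids and amino-acid degradation products falling;
and 204 of 244 analytes null. Five amino acids are paired with a
degradation product of opposite sign, emulating the up-regulation of
amino-acid catabolism in small seeds. The 40/244 signal share (~16 %) is
set so that near-perfect biomarker ranking yields the >5-fold top-decile
enrichment the statistics should achieve; accession offsets default to
near zero (the study saw no accession discrimination) and can be raised
to study restricted-weight-window behaviour. Effect size 0.25 per mg and
noise SD 0.30 on the log scale give per-analyte signal R² around 0.5,
comfortably above the detection floor at n = 160.

What the generator does *not* emulate: instrument drift, heteroscedastic
or correlated analyte noise, missing values, retention-index ambiguity,
non-linear (saturating) metabolite–weight trends, and real
accession-level composition differences. Passing tests demonstrate that
the statistical machinery behaves as designed under the assumed
structure — not that real seed metabolomes satisfy that structure.

## Statistics

* `fit_linear()` is ordinary least squares with the slope F-test p-value
  and 95 % CI; `univariate_screen()` applies it per analyte, flagging
  constant columns instead of failing.
* `bonferroni_threshold(0.05, 244)` = 2.05 × 10⁻⁴, the family-wise line
  on the volcano; the boundary is strict (`p < α/m`), a conservative and
  reproducible convention. (With the printed threshold rounded to
  2.04 × 10⁻⁴ the two agree within 1 %; the package always uses the
  actual analyte count.)
* `volcano_table()` merges −log₁₀(p) with the predictive OPLS loading;
  the best biomarkers maximise both.
* `best_subset()` enumerates all predictor subsets up to `nvmax = 5`,
  keeping the `nbest = 100` highest-R² models per size and scoring each
  variable by the best model containing it. Exhaustive enumeration over
  a full metabolome is infeasible, so `top_candidates()` first restricts
  to the top k = 20 analytes by univariate R² — a documented choice, as
  is declining to force any variable into every model. Ties from
  duplicate columns break deterministically by column order.

## Multivariate models

X is unit-variance scaled and y centred (the standard convention for
this model family; configurable). `pca_fit()` uses the singular value
decomposition and reports per-sample Hotelling T² with an F-based
critical region — 99 % for outlier screening, 95 % conventional for
display ellipses.

`opls_fit()` implements OPLS for a single continuous response: NIPALS
orthogonal-component removal (default `n_ortho = 1`, matching one
predictive plus one orthogonal display axis) followed by one predictive
PLS component. The predictive X-loading per analyte (`pq1`) feeds the
volcano. By construction the orthogonal scores have exactly zero
covariance with y; with `n_ortho = 0` the model coincides with
single-component PLS-1, which an independent oracle verifies in the
tests. A subtlety worth knowing: with a *single* predictive component,
an exactly linear y is recovered with R²Y = 1 only after the
y-orthogonal X-variation has been stripped; chance correlations
otherwise leak into the weight vector.

Q² uses 7-fold cross-validation (the conventional default fold count),
total-PRESS definition Q² = 1 − PRESS/TSS, with scaling and model
re-estimated inside every training fold. Folds are interleaved and
deterministic; an explicit `cv_seed` switches to a reproducible random
permutation.

`cv_anova()` compares the cross-validated residuals against a
cross-validated mean-only model:
F = ((PRESS₀ − PRESS)/df₁)/(PRESS/df₂), df₁ = number of latent
components, df₂ = n − df₁ − 1. Because cross-validation already
penalises complexity, a noise-fitted component almost always *worsens*
PRESS relative to the mean model, so under the null the p-value
concentrates at 1 rather than being uniform: the test is conservative,
never anti-conservative. Treat its p as a significance screen, not as a
calibrated tail probability near the threshold.

`cluster_scores()` applies Ward-linkage hierarchical clustering to the
model scores; on the default cohort three clusters organise seeds by
weight tertile.

## Numerical and degenerate-input policy

Inversion is an exact convex solve (no iterations to tune); round-trip
recovery is enforced to 10⁻⁶ over random compositions, and achieves
~10⁻¹⁴ in practice. All-zero elemental input returns all-zero fractions;
an all-zero composition makes the lipid H mole fraction undefined and is
an error. Constant analyte columns are dropped from scaling and flagged
in the screen. Empty tables flow through `compose_seeds()` and
`scenario_line()` as empty outputs. Problem sizes in the tests and the
bundled analysis (160-seed cohorts, 50-replicate calibrations,
100-permutation nulls) were chosen to estimate each quantity to well
within its assertion tolerance.

## Known limitations

* The four-component deconvolution ignores oxygen and ash and cannot
  resolve tissue-level (coat/cotyledon/embryo) composition.
* Identifiability of component *trends* depends on consistent co-variation
  of all four elements (see the caution above).
* The isotope model treats leaf/pod water as scenario constants, not
  meteorology-driven quantities, and δ_other as an unweighted average.
* CV-ANOVA p-values are conservative under the null (by construction of
  cross-validation), and the exhaustive best-subset search sees only the
  pre-filtered candidate set.
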