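Package: seedallometry
Title: Seed Metabolic Allometry: Elemental Deconvolution, Hydrogen
    Isotope Mass Balance and Metabolome Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for seed metabolic allometry in barrel
    medic (Medicago truncatula). Converts CHNS elemental analysis of
    single seeds into biochemical composition (carbohydrates, S-rich
    albumins, S-poor proteins and other nitrogenous compounds, lipids)
    by water/mineral correction and nonnegative least-squares mass
    balance; predicts seed bulk hydrogen isotope composition (delta-2H)
    from the lipid hydrogen mole fraction with a fractionation and
    exchange mass-balance model under configurable leaf/pod water
    scenarios; and provides the allometry statistics used on single-seed
    GC-MS metabolomes: per-analyte linear regression on seed weight,
    Bonferroni control, volcano tables, exhaustive best-subset
    regression, PCA with Hotelling outlier screening, and OPLS
    regression with cross-validated Q2 and CV-ANOVA significance. A
    synthetic seed-cohort generator reproduces the statistical structure
    the analyses assume, so the full pipeline is testable without any
    measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
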