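#!/usr/bin/env Rscript
# Metabolome statistics: PCA outlier screen, OPLS of the 244-analyte
# matrix on seed weight (R2Y, Q2, CV-ANOVA), volcano table with the
# Bonferroni line, exhaustive best-subset regression on the top
# univariate candidates, and clustering of the model scores. Writes
# results/metabolome/.

library(seedallometry)

seeds <- read_seed_table("results/cohort/seeds.csv")
met <- read_metabolome("results/cohort/metabolome.tsv")
stopifnot(identical(rownames(met), seeds$seed_id))

pca <- pca_fit(met, k = 2)
out99 <- hotelling_outliers(pca, level = 0.99)
cat(sprintf("PCA screen: %d of %d seeds outside the 99%% Hotelling region\n",
            sum(out99), length(out99)))

st <- metabolome_stats(met, seeds$weight_mg, cv_seed = 8484)
paths <- write_stats(st, "results/metabolome")

cat(sprintf("OPLS: R2Y = %.2f, Q2 = %.2f (7-fold), P_CV-ANOVA = %.2g\n",
            st$summary$r2y, st$summary$q2, st$summary$p_cv_anova))
cat(sprintf("volcano: %d of %d analytes below the Bonferroni threshold (%.3g)\n",
            st$summary$n_pass_bonferroni, st$summary$n_analytes,
            st$summary$bonferroni_threshold))
cat("top 5 biomarkers by -log10(p):\n")
print(utils::head(st$volcano[, c("analyte", "loading_pq1", "neg_log10_p")], 5),
      row.names = FALSE)

vs <- st$subsets$variable_scores
vs <- vs[order(-vs$best_r_squared), ]
cat("best-subset search: top correlates by best-model R2:\n")
print(utils::head(vs, 4), row.names = FALSE)

tab <- table(st$clusters,
             cut(seeds$weight_mg, 3, labels = c("small", "medium", "large")))
cat("score clusters vs weight tertiles:\n")
print(tab)
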