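#!/usr/bin/env Rscript
# Build the genetic risk scores for the simulated cohort and residualize
# both the phenotype and the scores on sex, age, age^2, study and smoking.
#
# Three scores: the published-weights GRS (here, the simulator's true
# per-allele effects, playing the role of meta-analysis weights), the
# sample-fitted-weights GRS (multiple regression of the adjusted phenotype
# on all dosages), and the two-component refit that gives the largest-effect
# SNP its own coefficient.
#
# Reads results/cohort/; writes results/grs/subjects.csv + fitted_weights.tsv.

suppressPackageStartupMessages(library(quantpen))

dos <- read_dosages("results/cohort/dosages.tsv")
ph <- read_phenotypes("results/cohort/phenotypes.csv")
wt <- read_weights("results/cohort/published_weights.tsv")
stopifnot(identical(rownames(dos), ph$subject_id))

grs_pub <- compute_grs(dos, wt)
y_adj <- adjust_covariates(ph$triglycerides, ph)
g_adj <- adjust_covariates(as.numeric(grs_pub), ph)

wt_fit <- fit_weights(dos, y_adj, trait = "triglycerides")
grs_fit <- compute_grs(dos, wt_fit)
gf_adj <- adjust_covariates(as.numeric(grs_fit), ph)

# two-component refit: the largest published effect vs the rest
top <- wt$snp_id[which.max(abs(wt$weight))]
rest <- wt[wt$snp_id != top, ]
two <- two_component_refit(dos[, top], compute_grs(dos, rest), y_adj)

r2 <- function(x) summary(lm(y_adj ~ x))$r.squared
message(sprintf("adjusted R2: published %.4f, fitted %.4f, two-component %.4f",
                r2(g_adj), r2(gf_adj), r2(two$combined)))
message(sprintf("two-component coefficients: %.4f * %s + %.4f * rest-GRS",
                two$coef_primary, top, two$coef_rest))

dir.create("results/grs", showWarnings = FALSE, recursive = TRUE)
write_weights(wt_fit, "results/grs/fitted_weights.tsv")
out <- data.frame(ph[c("subject_id", "sex", "age", "study", "smoking")],
                  triglycerides = ph$triglycerides,
                  grs_published = as.numeric(grs_pub),
                  grs_fitted = as.numeric(grs_fit),
                  trait_adj = y_adj, grs_published_adj = g_adj,
                  grs_fitted_adj = gf_adj)
write.csv(out, "results/grs/subjects.csv", row.names = FALSE)
message("written to results/grs/")
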