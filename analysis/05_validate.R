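#!/usr/bin/env Rscript
# Stage 5: validate the regional index.
#
# Correlates the normalized regional PDI with the regional epidemic
# caseload (Pearson and Spearman), checks leave-one-indicator-out
# robustness, and measures recovery of the generator's latent regional
# deprivation. Writes validation.csv.

library(pdindex)

study <- "results/study"
agg <- utils::read.csv(file.path(study, "aggregates_admin1.csv"))
caseloads <- read_caseloads(file.path(study, "caseloads.csv"))
truth <- utils::read.csv(file.path(study, "truth.csv"))
households <- read_households(file.path(study, "households.csv"))
im <- indicator_matrix(households)

report <- validation_report(agg, caseloads, x = im$matrix, truth = truth)

cat(sprintf("PDI vs caseload over %d regions: Pearson %.2f, Spearman %.2f\n",
            report$pearson$n_regions, report$pearson$correlation,
            report$spearman$correlation))
cat(sprintf("recovery of latent regional deprivation: Spearman %.2f\n",
            report$truth$spearman))
cat("leave-one-indicator-out correlations with the full index:\n")
print(round(report$loo, 3))

write_table(
  data.frame(metric = c("pearson_caseload", "spearman_caseload",
                        "spearman_truth", paste0("loo_", names(report$loo))),
             value = c(report$pearson$correlation, report$spearman$correlation,
                       report$truth$spearman, unname(report$loo))),
  file.path(study, "validation.csv"))
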