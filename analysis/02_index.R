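#!/usr/bin/env Rscript
# Stage 2: derive indicators and fit the household index.
#
# Builds the five deprivation indicators from the raw survey records, fits
# the pooled first-principal-component model on the z-scored indicator
# matrix, and scores every household. Writes model.json and scores.csv.

library(pdindex)

study <- "results/study"
households <- read_households(file.path(study, "households.csv"))
im <- indicator_matrix(households)
cat(sprintf("indicator matrix: %d x %d (%d records excluded for missingness)\n",
            nrow(im$matrix), ncol(im$matrix), sum(im$excluded)))

model <- fit_pdi_model(im$matrix)
write_pdi_model(model, file.path(study, "model.json"))
scores <- data.frame(household_id = im$household_id,
                     score = score_households(model, im$matrix))
write_table(scores, file.path(study, "scores.csv"))

cat(sprintf("first component explains %.1f%% of the indicator variance\n",
            100 * model$explained_variance_share))
cat("loadings (all positive => higher score = more deprived):\n")
print(round(model$loadings, 3))
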