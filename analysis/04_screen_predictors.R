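#!/usr/bin/env Rscript
# Stage 4: collinearity screening.
#
# Pearson correlations over the resolved predictors; pairs with |R| > 0.7
# and p < 0.05 are thinned by an ordered preference (dissolved nutrient
# fractions over totals, water temperature over dissolved oxygen). As a
# cross-check, the published 15-variable correlation matrix shipped with
# the package is screened with the same rule, reproducing the published
# 5 strong pairs and 11-predictor set.

suppressPackageStartupMessages(library(lakexergy))
out <- "results/analysis"

resolved <- read_monitoring_csv(file.path(out, "monitoring_resolved.csv"))
candidates <- setdiff(names(resolved),
                      c("site_id", "sub_region", "month", "Chla"))
cm <- pearson_matrix(resolved, candidates)
preds <- select_predictors(cm)
write_correlation_csv(cm, file.path(out, "correlation_matrix.csv"))
jsonlite::write_json(list(predictors = preds, strong_pairs = strong_pairs(cm)),
                     file.path(out, "predictors.json"),
                     auto_unbox = TRUE, digits = NA)

cat("Strong pairs in the synthetic survey:\n")
print(strong_pairs(cm))
cat("Retained predictors:", paste(preds, collapse = ", "), "\n\n")

pub <- taihu_correlations()
cat("Published matrix:", nrow(strong_pairs(pub)), "strong pairs;",
    length(select_predictors(pub)), "predictors retained:\n")
cat(paste(select_predictors(pub), collapse = ", "), "\n")
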