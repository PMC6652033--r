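#!/usr/bin/env Rscript
# Step 4: leave-one-out cross-validated classification into NINDS grades.
# Evaluates the six published feature-set x PCA combinations against the four
# classifiers and reports the headline configuration (naive Bayes on the
# excursion and peak-velocity features) in detail.

library(reflexquant)

seed <- 20260926L
out_dir <- "results"
config <- pipeline_config(seed = seed)
features <- read_feature_table(file.path(out_dir, "features.csv"))

grid <- accuracy_grid(features, config = config, seed = seed)
write.csv(grid, file.path(out_dir, "table_accuracy.csv"), row.names = FALSE)
message("LOO CV accuracy grid (fractions):")
print(cbind(grid[, 1:2], round(grid[, 3:6], 4)))

spec <- classifier_spec("naive_bayes", feature_subset = c("delta_a", "vmax"))
best <- loo_cv(features, spec, seed = seed)
message(sprintf(
  "Headline: naive Bayes on (delta_a, vmax): %.2f%% (%d/%d misclassified)",
  100 * best$accuracy, length(best$misclassified_ids), nrow(features)))
print(best$confusion)

jsonlite::write_json(
  list(classifier = "naive_bayes", features = c("delta_a", "vmax"),
       accuracy = best$accuracy,
       confusion = as.data.frame(best$confusion),
       misclassified_ids = best$misclassified_ids),
  file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("Wrote results/table_accuracy.csv and results/report.json")
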