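#!/usr/bin/env Rscript
# Prepare the classifier dataset: keep only parameter sets whose runs
# completed under all four divergence models (equal class sizes), then
# prune highly collinear summary statistics (|Pearson r| > 0.90), mirroring
# the validation step that reduced the statistic catalogue before model
# discrimination.

suppressMessages(library(evospeed))

tab <- read.csv("results/ensemble.csv", check.names = FALSE)
filt <- completeness_filter(tab)
cat(sprintf("filtered table: %d rows (%d parameter sets x 4 models)\n",
            nrow(filt), nrow(filt) / 4))

meta_cols <- c("param_id", "model", "completed", "reason", "n_species")
stats <- setdiff(names(filt), meta_cols)
mat <- as.matrix(filt[, stats])
keep <- collinearity_filter(mat, threshold = 0.90)
cat(sprintf("collinearity pruning at r > 0.90: %d of %d statistics retained\n",
            length(keep), length(stats)))
cat(paste(" -", keep), sep = "\n")

write.csv(filt, "results/ensemble_filtered.csv", row.names = FALSE)
writeLines(keep, "results/retained_features.txt")
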