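#!/usr/bin/env Rscript
# The traditional correlative test, run on the pseudo-empirical clades: per
# clade, Spearman correlations of species richness with |latitude| and
# temperature (across occupied cells) and of the DR speciation-rate proxy
# with body size and temperature niche (across species); each coefficient
# Fisher-transformed and pooled across clades with a random-effects model
# (REML tau^2).

suppressMessages(library(evospeed))

dirs <- list.dirs("results/pseudo_empirical", recursive = FALSE)
if (!length(dirs)) stop("run analysis/04_model_selection.R first")
bundles <- lapply(dirs, function(d) suppressMessages(read_bundle(d)))
cat(sprintf("loaded %d pseudo-empirical clades\n", length(bundles)))

out <- key_correlation_battery(bundles, min_species = 20)
print(out$pooled, digits = 3)
write.csv(out$pooled, "results/meta_pooled.csv", row.names = FALSE)
write.csv(out$records, "results/meta_records.csv", row.names = FALSE)

pos <- out$pooled[out$pooled$statistic == "richness_temperature", ]
cat(sprintf("pooled richness~temperature effect: beta_z = %.3f (p = %.3g)\n",
            pos$beta_z, pos$p))
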