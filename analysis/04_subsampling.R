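#!/usr/bin/env Rscript
# Stage 4 — marker-density and training-population-size experiments.
#
# Random subsets along each axis, one five-fold CV per subset, GBLUP
# throughout. The expectation from the study design: the marker-density
# curve plateaus quickly while predictability keeps improving with
# training-population size — so sample collection, not genotyping density,
# is the binding constraint.

suppressPackageStartupMessages(library(hybridgs))
seed <- 1

bundle <- make_study_bundle(sim_config(seed = seed))
y <- bundle$pheno_means[, "GY"]          # hardest trait: lowest H

mk <- subsample_experiment("markers", c(100, 250, 500, 1000, 2000),
                           selections_per_size = 20, "gblup",
                           bundle$hybrids, y, seed = seed)
cat("marker-density curve (GY):\n"); print(mk, digits = 3)

ind <- subsample_experiment("individuals", c(115, 230, 345, 460, 575),
                            selections_per_size = 20, "gblup",
                            bundle$hybrids, y, seed = seed)
cat("\ntraining-size curve (GY):\n"); print(ind, digits = 3)

cat(sprintf("\nrelative drop, 2000 -> 100 markers: %.1f%%\n",
            100 * (mk$mean[5] - mk$mean[1]) / mk$mean[5]))
cat(sprintf("relative drop, 575 -> 115 hybrids:  %.1f%%\n",
            100 * (ind$mean[5] - ind$mean[1]) / ind$mean[5]))

dir.create("results", showWarnings = FALSE)
write.table(mk, "results/04_subsample_markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ind, "results/04_subsample_individuals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
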