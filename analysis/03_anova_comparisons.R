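#!/usr/bin/env Rscript
# Stage 3 — trait x method ANOVA of predictabilities + Tukey letter groups.
#
# Consumes the CV records written by 02_cross_validate.R (falls back to a
# quick GBLUP/PLS run if they are absent), fits the two-way fixed-effects
# factorial with interaction, and assigns Tukey HSD letter groups to the
# trait and method main effects.

suppressPackageStartupMessages(library(hybridgs))

rec_path <- "results/02_cv_records.tsv"
cv <- NULL
if (file.exists(rec_path)) {
  cv <- cv_result(read.table(rec_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  if (max(cv$records$replicate) < 2) {
    message("stored CV records have a single replicate (no residual df); ",
            "rerunning a replicated pass")
    cv <- NULL
  }
}
if (is.null(cv)) {
  message("running a quick replicated GBLUP/PLS pass")
  bundle <- make_study_bundle(sim_config(seed = 1))
  parts <- list()
  for (tr in colnames(bundle$pheno_means)) for (me in c("gblup", "pls"))
    parts[[paste(tr, me)]] <- cross_validate(
      me, bundle$hybrids, bundle$pheno_means[, tr], replicates = 5,
      seed = 1, trait = tr)
  cv <- combine_cv_results(parts)
}

an <- predictability_anova(cv)
cat("Analysis of variance of predictabilities:\n")
print(an, digits = 4)

tg_m <- tukey_groups(cv, "method")
tg_t <- tukey_groups(cv, "trait")
cat("\nTukey letter groups (methods):\n"); print(tg_m, digits = 3)
cat("\nTukey letter groups (traits):\n"); print(tg_t, digits = 3)

dir.create("results", showWarnings = FALSE)
write.table(an, "results/03_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tg_m, "results/03_tukey_method.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tg_t, "results/03_tukey_trait.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
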