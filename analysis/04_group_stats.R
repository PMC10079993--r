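#!/usr/bin/env Rscript
# Group comparison of channel-mean theta connectivity: one-way ANOVA with
# Tukey post-hoc pairwise tests, on both observation units (the pooled
# subject-by-channel unit used for the per-channel tables, and the
# calibrated per-subject-mean unit). Subject matrices are rebuilt from the
# cohort seeds through the continuous-record path (zero-phase filtering and
# Hilbert phase on the full record), the same chain step 02 used.

library(plinet)

cfg <- pipeline_config(
  cohort = default_cohort_spec(n_subjects_per_group = 5, seed = 20260921),
  bands = "theta", variants = character(0), seed = 20260921)
res <- run_pipeline(cfg)

mats <- res$bands$theta$subject_matrices
groups <- unname(res$groups[names(mats)])

pooled <- compare_groups(mats, groups, names(mats), band = "theta")
cat("subject x channel unit (per-channel dependent variable):\n")
print(pooled$anova)
print(pooled$tukey)

subj <- compare_groups(mats, groups, names(mats), band = "theta",
                       per_subject_mean = TRUE)
cat("\nper-subject-mean unit (calibrated):\n")
print(subj$anova)
print(subj$tukey)

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)
write.table(pooled$tukey, "results/stats/tukey_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(subj$tukey, "results/stats/tukey_subject_mean.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Tukey tables written under results/stats\n")
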