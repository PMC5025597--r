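#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic breast-cancer cohort: 755 tumours with a
# typical PAM50 mix, ~60 SNVs per tumour, APOBEC-high prevalence skewed
# toward the HER2-enriched subtype, a 10-entry driver panel with planted
# odds ratios, and per-sample copy-number segment profiles (Poisson mean
# 40 breakpoints in high vs 20 in low). Everything is written under
# results/cohort/ in the same dialects the readers accept, so the later
# stages run off plain files, exactly as they would on real data.

library(apobecsig)

config <- pipeline_config(seed = 1L, out_dir = "results")
config <- run_simulate_stage(config)

cohort_dir <- file.path(config$out_dir, "cohort")
truth <- read.delim(file.path(cohort_dir, "truth_classes.tsv"))
cat("\nSubtype composition:\n")
print(table(truth$subtype))
cat("\nPlanted APOBEC-high fraction by subtype:\n")
print(round(tapply(truth$apobec_class == "high", truth$subtype, mean), 3))
cat("\nCohort files in", cohort_dir, "\n")
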