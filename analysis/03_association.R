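#!/usr/bin/env Rscript
# Stage 3 — gene alterations vs APOBEC class.
#
# Builds binary SNV / amplification / loss statuses from the gene tables
# (amplification: CN >= 2x ploidy; loss: CN <= ploidy - 1), then tests
# each panel gene for enrichment among APOBEC-high samples with the
# 100,000-permutation label-shuffling test — whole cohort first, then
# within each subtype — BH-corrected per (stratum, class), significant at
# q < 0.1. Also tests APOBEC class against subtype by Pearson chi-square
# with pairwise post hoc tests. Runs off the outputs of stages 1-2; a few
# minutes at the default permutation count.

library(apobecsig)

config <- pipeline_config(seed = 1L, out_dir = "results")
cohort <- file.path(config$out_dir, "cohort")
config$paths$annotations <- file.path(cohort, "annotations.tsv")
config$paths$gene_cn <- file.path(cohort, "gene_copy_number.tsv")
config$paths$gene_mutations <- file.path(cohort, "gene_mutations.tsv")

run_association_stage(config)

assoc <- read.delim(file.path(config$out_dir, "association.tsv"))
sig <- assoc[assoc$significant, c("gene", "alteration_class", "stratum",
                                  "observed_stat", "q")]
cat("\nAssociations significant at q < 0.1:\n")
print(sig[order(sig$stratum, sig$q), ], row.names = FALSE)

chisq <- read.delim(file.path(config$out_dir, "subtype_chisq.tsv"))
cat(sprintf("\nAPOBEC class vs subtype: chi-square = %.2f (df = %d), p = %.3g\n",
            chisq$statistic, chisq$df, chisq$p))
posthoc <- read.delim(file.path(config$out_dir, "subtype_posthoc.tsv"))
cat("Pairwise post hoc tests (BH-corrected):\n")
print(posthoc, row.names = FALSE)
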