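#!/usr/bin/env Rscript
# Stage 4 — segmental SCNA breakpoint burden by APOBEC class.
#
# Counts breakpoints per sample (adjacent same-chromosome segments whose
# copy numbers differ by >= 0.5; chromosome boundaries never count) and
# compares the APOBEC-high vs -low distributions with a two-sided
# Mann-Whitney U test, reading the direction off the class medians.
# Runs off the outputs of stages 1-2.

library(apobecsig)

config <- pipeline_config(seed = 1L, out_dir = "results")
config$paths$segments <- file.path(config$out_dir, "cohort",
                                   "segments.seg.tsv")

run_breakpoint_stage(config)

bt <- read.delim(file.path(config$out_dir, "breakpoint_test.tsv"))
cat(sprintf(
  "\nBreakpoints per sample: median %g (APOBEC high, n = %d) vs %g (low, n = %d)\n",
  bt$median_high, bt$n_high, bt$median_low, bt$n_low))
cat(sprintf("Mann-Whitney U = %g, two-sided p = %.3g (%s)\n",
            bt$U, bt$p, bt$method))
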