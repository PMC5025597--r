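# APOBEC3 fold-enrichment scoring. For each sample the four motif counts
# are accumulated over +/-w windows centred on every qualifying mutated
# cytosine (or guanine on the opposite strand):
#
#   E = (mutations_tcw * context_c) / (mutations_c * context_tcw)
#
# where mutations_tcw counts mutated Cs in a TCW motif (or Gs in WGA,
# W in {A, T}), mutations_c counts all qualifying mutated Cs (or Gs),
# context_tcw counts TCW (or WGA) motifs inside the windows and context_c
# counts Cs (or Gs) inside the windows. Significance is a one-sided exact
# hypergeometric (Fisher) test for over-representation of TCW mutations,
# BH-corrected across samples; 'APOBEC high' means q < alpha and E > fold.

#' Enrichment configuration
#'
#' @param w context-window half-width in nucleotides (window length
#'   `2w + 1`); default 20.
#' @param substitution_filter `"ct_cg_only"` counts only the APOBEC
#'   substitution classes C>T/C>G (and strand mirrors G>A/G>C);
#'   `"all_c_mutations"` counts every mutated C or G.
#' @param alpha BH-adjusted significance cut-off for the high call.
#' @param fold_threshold fold-enrichment cut-off for the high call.
#' @return a list of class `enrichment_config`.
#' @export
enrichment_config <- function(w = 20L,
                              substitution_filter = c("ct_cg_only",
                                                      "all_c_mutations"),
                              alpha = 0.05, fold_threshold = 2) {
  substitution_filter <- match.arg(substitution_filter)
  if (w < 1) stop_format("w must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_format("alpha must be in (0, 1)")
  structure(list(w = as.integer(w), substitution_filter = substitution_filter,
                 alpha = alpha, fold_threshold = fold_threshold),
            class = "enrichment_config")
}

# which mutations qualify for counting, by ref/alt and filter
qualifying_mutations <- function(mutations, substitution_filter) {
  on_c <- mutations$ref == "C"
  on_g <- mutations$ref == "G"
  if (substitution_filter == "ct_cg_only") {
    keep <- (on_c & mutations$alt %in% c("T", "G")) |
      (on_g & mutations$alt %in% c("A", "C"))
  } else {
    keep <- on_c | on_g
  }
  keep
}

# rowSums of motif hits over a character matrix of windows
count_in_windows <- function(mat, strand) {
  w1 <- ncol(mat)
  if (strand == "C") {
    base_hits <- mat == "C"
    tri <- mat[, 1:(w1 - 2), drop = FALSE] == "T" &
      mat[, 2:(w1 - 1), drop = FALSE] == "C" &
      (mat[, 3:w1, drop = FALSE] == "A" | mat[, 3:w1, drop = FALSE] == "T")
  } else {
    base_hits <- mat == "G"
    tri <- (mat[, 1:(w1 - 2), drop = FALSE] == "A" |
              mat[, 1:(w1 - 2), drop = FALSE] == "T") &
      mat[, 2:(w1 - 1), drop = FALSE] == "G" &
      mat[, 3:w1, drop = FALSE] == "A"
  }
  list(base = rowSums(base_hits), motif = rowSums(tri))
}

#' Count TCW/WGA motif mutations and context occurrences for one sample
#'
#' For every qualifying mutation (see [enrichment_config()]), the reference
#' trinucleotide immediately around the position decides motif membership
#' (TCW for a mutated C, WGA for a mutated G, W in A/T), and the
#' `(2w + 1)`-window centred on the position contributes its C (or G) count
#' and its TCW (or WGA) motif count to the context totals. Windows of
#' distinct mutations are counted independently even when they overlap.
#' Motifs are evaluated on the reference sequence, never the mutant allele;
#' `N` positions never match.
#'
#' @param mutations mutation table for a single sample.
#' @param reference named character vector of chromosome sequences.
#' @param config an [enrichment_config()].
#' @return one-row `data.frame` with `sample_id`, `mutations_tcw`,
#'   `mutations_c`, `context_tcw`, `context_c`.
#' @export
count_motifs <- function(mutations, reference, config = enrichment_config()) {
  validate_mutations(mutations)
  sample_id <- if (nrow(mutations) > 0) unique(mutations$sample_id) else NA_character_
  if (length(sample_id) > 1) {
    stop_format("count_motifs expects records of a single sample, got %d",
                length(sample_id))
  }
  zero <- data.frame(sample_id = sample_id, mutations_tcw = 0L,
                     mutations_c = 0L, context_tcw = 0L, context_c = 0L,
                     stringsAsFactors = FALSE)
  if (nrow(mutations) == 0) return(zero)
  keep <- qualifying_mutations(mutations, config$substitution_filter)
  mut <- mutations[keep, , drop = FALSE]
  if (nrow(mut) == 0) return(zero)

  w <- config$w
  ctx <- character(nrow(mut))
  for (chrom in unique(mut$chrom)) {
    idx <- mut$chrom == chrom
    ctx[idx] <- fetch_context(reference, chrom, mut$pos[idx], w)
  }
  mat <- matrix(unlist(strsplit(ctx, "", fixed = TRUE), use.names = FALSE),
                nrow = nrow(mut), byrow = TRUE)
  centre <- mat[, w + 1]
  if (any(centre != mut$ref)) {
    i <- which(centre != mut$ref)[1]
    stop_format("reference base %s at %s:%d does not match record ref %s",
                centre[i], mut$chrom[i], mut$pos[i], mut$ref[i])
  }

  m_tcw <- 0L; m_c <- 0L; c_tcw <- 0L; c_c <- 0L
  for (strand in c("C", "G")) {
    idx <- mut$ref == strand
    if (!any(idx)) next
    sub <- mat[idx, , drop = FALSE]
    counts <- count_in_windows(sub, strand)
    c_c <- c_c + sum(counts$base)
    c_tcw <- c_tcw + sum(counts$motif)
    m_c <- m_c + sum(idx)
    # motif membership of the mutated base itself: trinucleotide centred at pos
    if (strand == "C") {
      in_motif <- sub[, w] == "T" & (sub[, w + 2] == "A" | sub[, w + 2] == "T")
    } else {
      in_motif <- (sub[, w] == "A" | sub[, w] == "T") & sub[, w + 2] == "A"
    }
    m_tcw <- m_tcw + sum(in_motif)
  }
  data.frame(sample_id = sample_id, mutations_tcw = as.integer(m_tcw),
             mutations_c = as.integer(m_c), context_tcw = as.integer(c_tcw),
             context_c = as.integer(c_c), stringsAsFactors = FALSE)
}

#' APOBEC3 fold enrichment from motif counts
#'
#' `E = (mutations_tcw * context_c) / (mutations_c * context_tcw)`.
#' Returns `NA` when a denominator term is zero (undefined enrichment,
#' reported distinctly from any numeric value).
#'
#' @param counts one-row counts `data.frame` or list with the four count
#'   fields.
#' @return a single numeric value, or `NA_real_` when undefined.
#' @export
compute_enrichment <- function(counts) {
  if (counts$mutations_c == 0 || counts$context_tcw == 0) return(NA_real_)
  (counts$mutations_tcw * counts$context_c) /
    (counts$mutations_c * counts$context_tcw)
}

#' One-sided exact enrichment p-value
#'
#' Exact hypergeometric (Fisher) tail probability for over-representation
#' of TCW mutations, from the 2x2 table
#' `[[mutations_tcw, mutations_c - mutations_tcw],
#'   [context_tcw, context_c - context_tcw]]`.
#' A sample with no qualifying mutations carries no evidence and gets
#' `p = 1` by convention.
#'
#' @param counts motif counts as in [compute_enrichment()].
#' @return p-value in `[0, 1]`.
#' @export
enrichment_pvalue <- function(counts) {
  a <- counts$mutations_tcw; mc <- counts$mutations_c
  ct <- counts$context_tcw; cc <- counts$context_c
  if (any(c(a, mc, ct, cc) < 0)) stop_format("counts must be non-negative")
  if (a > mc) stop_format("mutations_tcw cannot exceed mutations_c")
  if (mc == 0) return(1)
  # P(X >= a), X hypergeometric with row margins (mc, cc), column margin a+ct
  stats::phyper(a - 1, m = mc, n = cc, k = a + ct, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); output order matches
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_format("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify samples as APOBEC high or low
#'
#' A sample is 'high' iff its BH-adjusted p-value is below `alpha` and its
#' fold enrichment exceeds `fold_threshold`; everything else — including
#' samples with undefined enrichment — is 'low'.
#'
#' @param results `data.frame` with columns `E` and `q`.
#' @param config an [enrichment_config()].
#' @return `results` with an `apobec_class` column (`"high"`/`"low"`).
#' @export
classify_samples <- function(results, config = enrichment_config()) {
  high <- !is.na(results$E) & results$E > config$fold_threshold &
    results$q < config$alpha
  results$apobec_class <- ifelse(high, "high", "low")
  results
}

#' Per-sample APOBEC3 enrichment over a cohort
#'
#' Runs motif counting, fold enrichment, the exact per-sample test, BH
#' correction across samples and the high/low classification.
#'
#' @param mutations cohort mutation table (multiple samples).
#' @param reference named character vector of chromosome sequences.
#' @param config an [enrichment_config()].
#' @param samples optional character vector fixing the sample set (samples
#'   without mutations get all-zero counts and class 'low').
#' @return `data.frame` with one row per sample: the four counts, `E`, `p`,
#'   `q`, `undefined_e` flag and `apobec_class`.
#' @export
apobec_enrichment <- function(mutations, reference,
                              config = enrichment_config(), samples = NULL) {
  validate_mutations(mutations)
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  if (length(samples) == 0) {
    return(data.frame(sample_id = character(0), mutations_tcw = integer(0),
                      mutations_c = integer(0), context_tcw = integer(0),
                      context_c = integer(0), E = numeric(0), p = numeric(0),
                      q = numeric(0), undefined_e = logical(0),
                      apobec_class = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(samples, function(s) {
    m <- mutations[mutations$sample_id == s, , drop = FALSE]
    counts <- count_motifs(m, reference, config)
    counts$sample_id <- s
    counts$E <- compute_enrichment(counts)
    counts$p <- enrichment_pvalue(counts)
    counts
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$undefined_e <- is.na(res$E)
  classify_samples(res, config)
}
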