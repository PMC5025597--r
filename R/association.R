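# Gene-alteration association with APOBEC-high status. Alteration statuses
# are binary per (gene, sample, class): snv = at least one non-silent SNV
# in the gene (gene assignment is an input); amplification = gene copy
# number >= 2x ploidy; loss = copy number at least one copy below ploidy.
# The association test permutes the APOBEC high/low labels; BH correction
# is applied over the genes tested within each (stratum, class); the
# significance rule is q < 0.1. The cohort is tested first, then each gene
# within each subtype.

ALTERATION_CLASSES <- c("snv", "amplification", "loss")

#' Build binary gene-alteration statuses
#'
#' @param gene_cn gene copy-number `data.frame` (`gene`, `sample_id`,
#'   `copy_number`). Samples missing a value for a gene get `NA` for both
#'   copy-number classes and are excluded from that gene's CN tests.
#' @param annotations sample annotations (`sample_id`, `subtype`,
#'   `ploidy`); every sample must have a ploidy.
#' @param gene_mutations `data.frame` with columns `sample_id`, `gene`:
#'   one row per non-silent SNV already assigned to a gene.
#' @param genes character vector of genes to score (the driver panel).
#' @param loss_rule `"below_ploidy"` calls a loss when
#'   `copy_number <= ploidy - 1`; the alternative reading `"ratio"`
#'   (`copy_number <= ploidy`) is provided as a switch.
#' @return an `alteration_matrix`: list with `genes`, `samples` and
#'   `status`, a list of three gene x sample 0/1 matrices (`snv`,
#'   `amplification`, `loss`).
#' @export
build_alterations <- function(gene_cn, annotations, gene_mutations, genes,
                              loss_rule = c("below_ploidy", "ratio")) {
  loss_rule <- match.arg(loss_rule)
  if (length(genes) == 0) stop_format("gene list must be non-empty")
  samples <- annotations$sample_id
  if (any(!is.finite(annotations$ploidy) | annotations$ploidy <= 0)) {
    stop_format("every sample needs a known positive ploidy")
  }
  ploidy <- stats::setNames(annotations$ploidy, samples)

  mk <- function() matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                          dimnames = list(genes, samples))
  snv <- mk(); amp <- mk(); loss <- mk()
  snv[] <- 0
  if (nrow(gene_mutations) > 0) {
    hit <- gene_mutations[gene_mutations$gene %in% genes &
                            gene_mutations$sample_id %in% samples, ]
    if (nrow(hit) > 0) snv[cbind(hit$gene, hit$sample_id)] <- 1
  }
  cn <- gene_cn[gene_cn$gene %in% genes & gene_cn$sample_id %in% samples, ]
  if (nrow(cn) > 0) {
    pl <- ploidy[cn$sample_id]
    amp[cbind(cn$gene, cn$sample_id)] <- as.numeric(cn$copy_number >= 2 * pl)
    loss_call <- if (loss_rule == "below_ploidy") {
      cn$copy_number <= pl - 1
    } else {
      cn$copy_number <= pl
    }
    loss[cbind(cn$gene, cn$sample_id)] <- as.numeric(loss_call)
  }
  structure(list(genes = genes, samples = samples,
                 status = list(snv = snv, amplification = amp, loss = loss)),
            class = "alteration_matrix")
}

#' Label-permutation association test
#'
#' Tests whether an alteration is enriched among APOBEC-high samples. The
#' statistic is the difference in alteration proportion, high minus low;
#' the null is built by shuffling the high/low labels. The test is
#' one-sided for enrichment in the high class. When the number of distinct
#' label assignments `choose(n, n_high)` is at most `exhaustive_limit`, all
#' assignments are enumerated and the p-value is exact; otherwise `n_perm`
#' uniform random permutations are drawn and
#' `p = (1 + #[permuted stat >= observed]) / (1 + n_perm)`.
#'
#' @param labels binary vector (1 = APOBEC high, 0 = low).
#' @param alteration binary vector, same length; `NA` entries (sample not
#'   scorable) are dropped pairwise.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed for the permutation stream.
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"`, or
#'   `"always"`.
#' @param exhaustive_limit enumeration cut-off on `choose(n, n_high)`.
#' @return list with `observed_stat`, `p`, `n_perm` (`NA` for exhaustive
#'   mode), `method` and `n` (samples used).
#' @export
permutation_test <- function(labels, alteration, n_perm = 100000L, seed = 1L,
                             exhaustive = c("auto", "never", "always"),
                             exhaustive_limit = 1e5) {
  exhaustive <- match.arg(exhaustive)
  if (length(labels) != length(alteration)) {
    stop_format("labels and alteration must have the same length")
  }
  ok <- !is.na(alteration) & !is.na(labels)
  lab <- as.integer(labels[ok]); alt <- as.numeric(alteration[ok])
  n <- length(lab)
  if (n < 2) stop_format("need at least 2 scorable samples")
  n_high <- sum(lab == 1); n_low <- n - n_high
  if (n_high == 0 || n_low == 0) {
    stop_format("both APOBEC classes must be present among scorable samples")
  }
  if (n_perm < 1) stop_format("n_perm must be >= 1")
  observed <- mean(alt[lab == 1]) - mean(alt[lab == 0])
  total <- sum(alt)
  eps <- 1e-12

  do_exhaustive <- switch(exhaustive,
    always = TRUE,
    never = FALSE,
    auto = choose(n, n_high) <= exhaustive_limit
  )
  if (do_exhaustive) {
    sets <- utils::combn(n, n_high)
    k <- colSums(matrix(alt[sets], nrow = n_high))
    stat <- k / n_high - (total - k) / n_low
    p <- mean(stat >= observed - eps)
    return(list(observed_stat = observed, p = p, n_perm = NA_integer_,
                method = "exhaustive", n = n))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      k <- sum(alt[sample.int(n, n_high)])
      stat <- k / n_high - (total - k) / n_low
      stat >= observed - eps
    }, logical(1)))
  })
  p <- (1 + hits) / (1 + n_perm)
  list(observed_stat = observed, p = p, n_perm = as.integer(n_perm),
       method = "montecarlo", n = n)
}

#' Cohort-then-subtype permutation association
#'
#' Runs the label-permutation test for every (gene, alteration class) on
#' the whole cohort, then repeats it within each subtype (HER2, Basal,
#' LumA, LumB). q-values are BH-adjusted over the genes tested within each
#' (stratum, class); a gene is flagged significant at q < `q_threshold`.
#' A stratum where only one APOBEC class is present is skipped with a
#' message.
#'
#' @param classes `data.frame` with `sample_id` and `apobec_class` (the
#'   output of [apobec_enrichment()] works).
#' @param alterations an [build_alterations()] result.
#' @param annotations sample annotations with `subtype`.
#' @param n_perm permutations per test (default 100000).
#' @param seed master seed; each (stratum, class, gene) gets a derived
#'   substream so results do not depend on evaluation order.
#' @param q_threshold significance cut-off on the q-value (default 0.1).
#' @param exhaustive passed to [permutation_test()].
#' @return `data.frame`: `gene`, `alteration_class`, `stratum`,
#'   `observed_stat`, `n`, `p`, `q`, `significant`.
#' @export
run_association <- function(classes, alterations, annotations,
                            n_perm = 100000L, seed = 1L, q_threshold = 0.1,
                            exhaustive = "auto") {
  class_map <- stats::setNames(classes$apobec_class, classes$sample_id)
  subtype_map <- stats::setNames(annotations$subtype, annotations$sample_id)
  samples <- intersect(alterations$samples, classes$sample_id)
  strata <- c("cohort", intersect(c("HER2", "Basal", "LumA", "LumB"),
                                  unique(subtype_map[samples])))
  out <- list()
  for (si in seq_along(strata)) {
    stratum <- strata[si]
    s_samples <- if (stratum == "cohort") samples else {
      samples[subtype_map[samples] == stratum]
    }
    lab <- as.integer(class_map[s_samples] == "high")
    if (length(s_samples) < 2 || length(unique(lab)) < 2) {
      message(sprintf("run_association: stratum %s skipped (single class)",
                      stratum))
      next
    }
    for (ci in seq_along(ALTERATION_CLASSES)) {
      cls <- ALTERATION_CLASSES[ci]
      status <- alterations$status[[cls]][, s_samples, drop = FALSE]
      rows <- lapply(seq_along(alterations$genes), function(gi) {
        gene <- alterations$genes[gi]
        vec <- status[gene, ]
        ok <- !is.na(vec)
        if (sum(ok) < 2 || length(unique(lab[ok])) < 2) {
          message(sprintf(
            "run_association: %s/%s in %s skipped (insufficient scorable samples)",
            gene, cls, stratum))
          return(NULL)
        }
        pt <- permutation_test(lab[ok], vec[ok], n_perm = n_perm,
                               seed = substream_seed(seed, 5L,
                                                     si * 1000L + ci * 100L + gi),
                               exhaustive = exhaustive)
        data.frame(gene = gene, alteration_class = cls, stratum = stratum,
                   observed_stat = pt$observed_stat, n = pt$n, p = pt$p,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      if (is.null(rows)) next
      rows$q <- bh_adjust(rows$p)
      rows$significant <- rows$q < q_threshold
      out[[length(out) + 1]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chi-square association of APOBEC class with subtype
#'
#' Pearson chi-square on the high/low x subtype contingency table, with
#' pairwise two-proportion chi-square post hoc tests (BH-corrected over
#' the pairs).
#'
#' @param classes per-sample `"high"`/`"low"` vector.
#' @param subtypes per-sample subtype labels, same length.
#' @return list with `table`, `statistic`, `df`, `p` and `pairwise`
#'   (`data.frame` of subtype pairs with `p` and `q`).
#' @export
subtype_association <- function(classes, subtypes) {
  if (length(classes) != length(subtypes)) {
    stop_format("classes and subtypes must have the same length")
  }
  subtypes <- as.character(subtypes)
  levels_present <- intersect(SUBTYPE_LEVELS, unique(subtypes))
  if (length(levels_present) < 2) stop_format("need at least 2 subtypes")
  tab <- table(factor(classes, levels = c("high", "low")),
               factor(subtypes, levels = levels_present))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop_format(
      "contingency table has an expected count of 0; merge sparse categories")
  }
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  pairs <- utils::combn(levels_present, 2)
  pw <- apply(pairs, 2, function(pr) {
    sub <- tab[, pr, drop = FALSE]
    suppressWarnings(stats::chisq.test(sub, correct = FALSE))$p.value
  })
  pairwise <- data.frame(subtype_a = pairs[1, ], subtype_b = pairs[2, ],
                         p = pw, q = bh_adjust(pw), stringsAsFactors = FALSE)
  list(table = tab, statistic = unname(test$statistic),
       df = unname(test$parameter), p = test$p.value, pairwise = pairwise)
}
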