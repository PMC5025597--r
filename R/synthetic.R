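# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes: a random reference with a controllable GC fraction,
# per-sample mutation catalogs in which APOBEC-high samples draw a tunable
# fraction of their C>T/C>G mutations from TCW (or strand-mirrored WGA)
# sites, planted gene alterations at chosen odds ratios versus the high
# class, subtype labels, and per-sample segment profiles with class-
# specific breakpoint rates. Everything is reproducible end to end from a
# single seed via per-component, per-sample substreams.

#' Synthetic cohort specification
#'
#' Defaults describe a breast-cancer-like study cohort: 755 tumours with a
#' typical PAM50 mix, ~60 exonic SNVs per tumour (negative binomial), an
#' APOBEC-high prevalence skewed toward the HER2-enriched subtype, a
#' driver panel with moderate planted odds ratios, and a higher segmental
#' breakpoint rate in APOBEC-high tumours.
#'
#' @param n_samples number of tumours.
#' @param subtype_proportions named proportions over HER2, Basal, LumA,
#'   LumB, Normal; must sum to 1.
#' @param reference_length synthetic chromosome length (bases).
#' @param gc_fraction GC content of the reference.
#' @param mutations_per_sample single integer, or `list(mean=, dispersion=)`
#'   for a negative-binomial load.
#' @param apobec_fraction_high,apobec_fraction_low fraction of a sample's
#'   mutations drawn from TCW/WGA sites in each class (the rest are uniform
#'   background substitutions).
#' @param prop_high probability a sample is APOBEC high: one number, or a
#'   named per-subtype vector (the default skews prevalence toward HER2).
#' @param genes `data.frame` with columns `gene`, `alteration_class`
#'   (snv/amplification/loss), `base_rate` (alteration probability in the
#'   low class) and `odds_ratio` (high vs low).
#' @param breakpoint_means named vector `c(high=, low=)` of Poisson means
#'   for per-sample breakpoint counts.
#' @param ploidy sample ploidy (constant across the cohort).
#' @param n_chrom,chrom_length segment-map geometry for the SEG output.
#' @param seed master seed; all randomness derives from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 755L,
                        subtype_proportions = c(HER2 = 0.10, Basal = 0.18,
                                                LumA = 0.45, LumB = 0.20,
                                                Normal = 0.07),
                        reference_length = 1e6, gc_fraction = 0.41,
                        mutations_per_sample = list(mean = 60, dispersion = 2),
                        apobec_fraction_high = 0.5,
                        apobec_fraction_low = 0,
                        prop_high = c(HER2 = 0.55, Basal = 0.30, LumB = 0.25,
                                      LumA = 0.10, Normal = 0.08),
                        genes = default_gene_panel(),
                        breakpoint_means = c(high = 40, low = 20),
                        ploidy = 2, n_chrom = 5L, chrom_length = 2e7,
                        seed = 1L) {
  stopifnot(n_samples >= 1, reference_length >= 1000,
            gc_fraction >= 0, gc_fraction <= 1,
            apobec_fraction_high >= 0, apobec_fraction_high <= 1,
            apobec_fraction_low >= 0, apobec_fraction_low <= 1,
            ploidy > 0)
  if (abs(sum(subtype_proportions) - 1) > 1e-8) {
    stop_format("subtype_proportions must sum to 1")
  }
  if (is.null(names(subtype_proportions)) ||
      !all(names(subtype_proportions) %in% SUBTYPE_LEVELS)) {
    stop_format("subtype_proportions must be named with PAM50 subtypes")
  }
  if (length(prop_high) > 1) {
    missing <- setdiff(names(subtype_proportions), names(prop_high))
    if (length(missing) > 0) {
      stop_format("prop_high missing subtype(s): %s",
                  paste(missing, collapse = ", "))
    }
  }
  if (any(prop_high < 0 | prop_high > 1)) {
    stop_format("prop_high must lie in [0, 1]")
  }
  req <- c("gene", "alteration_class", "base_rate", "odds_ratio")
  if (!all(req %in% names(genes))) {
    stop_format("genes needs columns %s", paste(req, collapse = ", "))
  }
  if (any(genes$base_rate <= 0 | genes$base_rate >= 1)) {
    stop_format("gene base rates must lie in (0, 1)")
  }
  if (any(genes$odds_ratio < 0)) stop_format("odds ratios must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 subtype_proportions = subtype_proportions,
                 reference_length = reference_length,
                 gc_fraction = gc_fraction,
                 mutations_per_sample = mutations_per_sample,
                 apobec_fraction_high = apobec_fraction_high,
                 apobec_fraction_low = apobec_fraction_low,
                 prop_high = prop_high, genes = genes,
                 breakpoint_means = breakpoint_means, ploidy = ploidy,
                 n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default driver-gene panel
#'
#' The breast-cancer driver panel scored in the association stage: SNVs in
#' TP53, CDH1, NCOR1, PTEN, NF1 and PIK3CA; ERBB2 and CCND1 amplification;
#' TP53 and KMT2C loss. Base rates are of the order seen in breast-tumour
#' cohorts; odds ratios are the planted high-vs-low effects.
#'
#' @return `data.frame` usable as the `genes` field of [cohort_spec()].
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("TP53", "CDH1", "NCOR1", "PTEN", "NF1", "PIK3CA",
             "ERBB2", "CCND1", "TP53", "KMT2C"),
    alteration_class = c(rep("snv", 6), "amplification", "amplification",
                         "loss", "loss"),
    base_rate = c(0.30, 0.12, 0.05, 0.05, 0.04, 0.35,
                  0.12, 0.15, 0.10, 0.08),
    odds_ratio = c(2.5, 2, 2, 2.5, 2.5, 1.5, 3, 2, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a random reference sequence
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc_fraction / 2`. The TCW and WGA
#' motif centre positions are scanned once and returned alongside the
#' sequence so the catalog generator can place signature mutations.
#'
#' @param length sequence length (>= 1000).
#' @param gc_fraction GC content.
#' @param seed integer seed.
#' @param chrom_name chromosome name (default `"chr1"`).
#' @return list with `sequence` (named character vector), `tcw_centers`
#'   and `wga_centers` (integer positions of the mutable C / G).
#' @export
generate_reference <- function(length, gc_fraction, seed,
                               chrom_name = "chr1") {
  if (length < 1000) stop_format("reference length must be >= 1000")
  bases <- with_seed(seed, {
    sample(BASES, length, replace = TRUE,
           prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                    gc_fraction / 2, (1 - gc_fraction) / 2))
  })
  seq <- paste(bases, collapse = "")
  n <- length
  is_t <- bases == "T"; is_a <- bases == "A"
  is_c <- bases == "C"; is_g <- bases == "G"
  w_at <- is_a | is_t
  # TCW: T at i-1, C at i, A/T at i+1; WGA: A/T at i-1, G at i, A at i+1
  mid <- 2:(n - 1)
  tcw <- mid[is_t[mid - 1] & is_c[mid] & w_at[mid + 1]]
  wga <- mid[w_at[mid - 1] & is_g[mid] & is_a[mid + 1]]
  list(sequence = stats::setNames(seq, chrom_name),
       tcw_centers = tcw, wga_centers = wga)
}

# negative-binomial or fixed per-sample mutation count
draw_mutation_count <- function(mps) {
  if (is.list(mps)) {
    max(1L, stats::rnbinom(1, mu = mps$mean, size = mps$dispersion))
  } else {
    as.integer(mps)
  }
}

#' Generate a synthetic mutation catalog
#'
#' For each sample, with probability `apobec_fraction(class)` a mutation is
#' a C>T or C>G (equal odds) at a uniformly chosen TCW site — or its
#' strand mirror, a G>A/G>C at a WGA site — and otherwise a uniform
#' substitution at a uniformly chosen unconstrained position. Positions are
#' sampled without replacement within a sample. Each sample draws from its
#' own seed substream, so adding samples leaves earlier catalogs unchanged.
#'
#' @param spec a [cohort_spec()].
#' @param reference a [generate_reference()] result.
#' @param class_assignments named character vector, sample -> "high"/"low".
#' @return cohort mutation `data.frame` (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @export
generate_catalog <- function(spec, reference, class_assignments) {
  motif_pool <- c(reference$tcw_centers, reference$wga_centers)
  if (length(reference$tcw_centers) == 0) {
    stop_format("reference has no TCW site; increase length or GC fraction")
  }
  n_tcw <- length(reference$tcw_centers)
  chrom <- names(reference$sequence)
  bases <- strsplit(reference$sequence[[1]], "", fixed = TRUE)[[1]]
  len <- length(bases)
  samples <- names(class_assignments)
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    f <- if (class_assignments[[s]] == "high") spec$apobec_fraction_high
         else spec$apobec_fraction_low
    out[[i]] <- with_seed(substream_seed(spec$seed, 2L, i), {
      n_mut <- draw_mutation_count(spec$mutations_per_sample)
      n_apo <- stats::rbinom(1, n_mut, f)
      if (n_apo > length(motif_pool) || n_mut > len) {
        stop_format("sample %s requests more mutations than available sites", s)
      }
      apo_pos <- if (n_apo > 0) {
        motif_pool[sample.int(length(motif_pool), n_apo)]
      } else integer(0)
      # background positions: uniform, rejecting collisions
      bg_pos <- integer(0)
      need <- n_mut - n_apo
      used <- apo_pos
      while (need > 0) {
        cand <- sample.int(len, need)
        cand <- setdiff(cand, used)
        bg_pos <- c(bg_pos, cand)
        used <- c(used, cand)
        need <- n_mut - n_apo - length(bg_pos)
      }
      pos <- c(apo_pos, bg_pos)
      ref <- bases[pos]
      alt <- character(length(pos))
      if (n_apo > 0) {
        is_c <- ref[seq_len(n_apo)] == "C"
        alt[seq_len(n_apo)] <- ifelse(
          is_c,
          sample(c("T", "G"), n_apo, replace = TRUE),
          sample(c("A", "C"), n_apo, replace = TRUE)
        )
      }
      if (length(bg_pos) > 0) {
        idx <- n_apo + seq_along(bg_pos)
        alt[idx] <- vapply(ref[idx], function(b) sample(setdiff(BASES, b), 1),
                           character(1))
      }
      data.frame(sample_id = s, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# probability in the high class implied by an odds ratio against base_rate
implied_high_rate <- function(base_rate, odds_ratio) {
  odds <- odds_ratio * base_rate / (1 - base_rate)
  p <- odds / (1 + odds)
  if (any(p >= 1)) stop_format("implied high-class probability >= 1")
  p
}

#' Plant gene alterations with chosen odds ratios
#'
#' Each panel gene is altered with probability `base_rate` in APOBEC-low
#' samples and with the probability implied by its odds ratio in high
#' samples. SNV genes are realised as gene-annotated mutation rows;
#' copy-number genes are realised as gene copy numbers respecting the
#' calling thresholds (amplified draws >= 2x ploidy, lost draws <=
#' ploidy - 1, neutral draws = ploidy).
#'
#' @param spec a [cohort_spec()].
#' @param class_assignments named sample -> class vector.
#' @param seed integer seed.
#' @return list with `truth` (long `data.frame` of planted 0/1 statuses),
#'   `gene_cn` and `gene_mutations` tables in the formats the readers
#'   accept.
#' @export
generate_alterations <- function(spec, class_assignments,
                                 seed = substream_seed(spec$seed, 3L)) {
  samples <- names(class_assignments)
  is_high <- unname(class_assignments == "high")
  genes <- spec$genes
  with_seed(seed, {
    truth <- list(); cn_rows <- list(); mut_rows <- list()
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      p_high <- implied_high_rate(g$base_rate, g$odds_ratio)
      prob <- ifelse(is_high, p_high, g$base_rate)
      status <- stats::rbinom(length(samples), 1, prob)
      truth[[gi]] <- data.frame(gene = g$gene,
                                alteration_class = g$alteration_class,
                                sample_id = samples, status = status,
                                stringsAsFactors = FALSE)
      if (g$alteration_class == "snv") {
        hit <- samples[status == 1]
        if (length(hit) > 0) {
          mut_rows[[length(mut_rows) + 1]] <-
            data.frame(sample_id = hit, gene = g$gene,
                       stringsAsFactors = FALSE)
        }
      } else {
        pl <- spec$ploidy
        cn <- rep(pl, length(samples))
        alt_idx <- which(status == 1)
        if (g$alteration_class == "amplification") {
          cn[alt_idx] <- 2 * pl + stats::runif(length(alt_idx), 0, 2)
        } else {
          cn[alt_idx] <- stats::runif(length(alt_idx),
                                      max(0, pl - 2), pl - 1)
        }
        cn_rows[[length(cn_rows) + 1]] <-
          data.frame(gene = g$gene, sample_id = samples, copy_number = cn,
                     stringsAsFactors = FALSE)
      }
    }
    gene_cn <- if (length(cn_rows) > 0) do.call(rbind, cn_rows) else
      data.frame(gene = character(0), sample_id = character(0),
                 copy_number = numeric(0))
    # copy-number genes sharing a name across classes (e.g. TP53 loss vs
    # snv) are fine; but one gene must not appear twice within cn table
    if (anyDuplicated(gene_cn[, c("gene", "sample_id")])) {
      gene_cn <- gene_cn[!duplicated(gene_cn[, c("gene", "sample_id")]), ]
    }
    gene_mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else
      data.frame(sample_id = character(0), gene = character(0))
    list(truth = do.call(rbind, truth), gene_cn = gene_cn,
         gene_mutations = gene_mutations)
  })
}

#' Generate per-sample copy-number segment profiles
#'
#' Each sample draws a Poisson breakpoint count with its class mean,
#' places the breakpoints uniformly on a multi-chromosome map and assigns
#' alternating copy-number levels around the sample ploidy so every
#' adjacent pair differs by 1 (>= the default analysis `min_delta`).
#'
#' @param spec a [cohort_spec()].
#' @param class_assignments named sample -> class vector.
#' @return segment `data.frame` (`sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`).
#' @export
generate_segments <- function(spec, class_assignments) {
  samples <- names(class_assignments)
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    mean_b <- spec$breakpoint_means[[class_assignments[[s]]]]
    out[[i]] <- with_seed(substream_seed(spec$seed, 4L, i), {
      b <- stats::rpois(1, mean_b)
      chr_of <- if (b > 0) sample(chroms, b, replace = TRUE) else character(0)
      pos_of <- if (b > 0) sample.int(spec$chrom_length - 1, b, replace = TRUE)
                else integer(0)
      rows <- lapply(chroms, function(ch) {
        bp <- sort(unique(pos_of[chr_of == ch]))
        starts <- c(1L, bp + 1L)
        ends <- c(bp, as.integer(spec$chrom_length))
        # alternate around ploidy: pl, pl+1, pl, pl+1, ...
        cn <- spec$ploidy + (seq_along(starts) - 1) %% 2
        data.frame(sample_id = s, chrom = ch, start = starts, end = ends,
                   copy_number = cn, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic cohort
#'
#' Draws subtype labels, APOBEC classes (per-subtype prevalence), the
#' reference, the mutation catalog, the planted gene alterations and the
#' segment profiles, all from the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `spec`, `reference`, `mutations`, `annotations`,
#'   `gene_cn`, `gene_mutations`, `segments` and `truth` (per-sample class
#'   + per-gene planted status).
#' @export
generate_cohort <- function(spec) {
  samples <- sprintf("S%04d", seq_len(spec$n_samples))
  subtypes <- with_seed(substream_seed(spec$seed, 1L, 1L), {
    sample(names(spec$subtype_proportions), spec$n_samples, replace = TRUE,
           prob = spec$subtype_proportions)
  })
  ph <- spec$prop_high
  p_high <- if (length(ph) == 1) rep(ph, spec$n_samples) else unname(ph[subtypes])
  classes <- with_seed(substream_seed(spec$seed, 1L, 2L), {
    ifelse(stats::runif(spec$n_samples) < p_high, "high", "low")
  })
  names(classes) <- samples
  reference <- generate_reference(spec$reference_length, spec$gc_fraction,
                                  seed = substream_seed(spec$seed, 1L, 3L))
  mutations <- generate_catalog(spec, reference, classes)
  alt <- generate_alterations(spec, classes)
  segments <- generate_segments(spec, classes)
  annotations <- data.frame(sample_id = samples, subtype = subtypes,
                            ploidy = spec$ploidy, stringsAsFactors = FALSE)
  truth_class <- data.frame(sample_id = samples, subtype = subtypes,
                            apobec_class = unname(classes),
                            stringsAsFactors = FALSE)
  list(spec = spec, reference = reference, mutations = mutations,
       annotations = annotations, gene_cn = alt$gene_cn,
       gene_mutations = alt$gene_mutations, segments = segments,
       truth = list(classes = truth_class, alterations = alt$truth))
}

#' Write a synthetic cohort in the dialects the readers accept
#'
#' Emits MAF, FASTA, SEG, annotation TSV, gene copy-number TSV, gene-
#' mutation TSV and the truth tables into `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    maf = file.path(dir, "mutations.maf.tsv"),
    fasta = file.path(dir, "reference.fa"),
    seg = file.path(dir, "segments.seg.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    gene_cn = file.path(dir, "gene_copy_number.tsv"),
    gene_mutations = file.path(dir, "gene_mutations.tsv"),
    truth_classes = file.path(dir, "truth_classes.tsv"),
    truth_alterations = file.path(dir, "truth_alterations.tsv")
  )
  write_maf(cohort$mutations, paths[["maf"]])
  dna <- Biostrings::DNAStringSet(cohort$reference$sequence)
  Biostrings::writeXStringSet(dna, paths[["fasta"]])
  seg <- data.frame(sample = cohort$segments$sample_id,
                    chrom = cohort$segments$chrom,
                    start = cohort$segments$start,
                    end = cohort$segments$end,
                    value = cohort$segments$copy_number)
  utils::write.table(seg, paths[["seg"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(cohort$annotations, paths[["annotations"]])
  wt(cohort$gene_cn, paths[["gene_cn"]])
  wt(cohort$gene_mutations, paths[["gene_mutations"]])
  wt(cohort$truth$classes, paths[["truth_classes"]])
  wt(cohort$truth$alterations, paths[["truth_alterations"]])
  invisible(paths)
}
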