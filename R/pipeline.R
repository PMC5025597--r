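# Pipeline orchestration: the stages (simulate, enrich, associate,
# breakpoints) as functions over a single declarative config, with
# deterministic outputs and a run manifest. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced here, none hard-coded in the
#' stages: window half-width 20, high-call rule q < 0.05 and E > 2,
#' 100,000 permutations, association significance q < 0.1, breakpoint
#' `min_delta` 0.5.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "results") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    paths = list(
      mutations = NULL, reference = NULL, segments = NULL,
      annotations = NULL, gene_cn = NULL, gene_mutations = NULL
    ),
    enrichment = list(w = 20L, substitution_filter = "ct_cg_only",
                      alpha = 0.05, fold_threshold = 2),
    association = list(genes = unique(default_gene_panel()$gene),
                       n_perm = 100000L, q_threshold = 0.1,
                       loss_rule = "below_ploidy"),
    scna = list(min_delta = 0.5),
    simulate = list()
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected so typos cannot silently fall back to a
#' default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  config <- pipeline_config()
  merge_checked <- function(base, override, prefix = "") {
    for (key in names(override)) {
      full <- paste0(prefix, key)
      if (!key %in% names(base)) stop_format("unknown config key: %s", full)
      if (is.list(base[[key]]) && is.list(override[[key]]) &&
          length(base[[key]]) > 0 && key != "simulate") {
        base[[key]] <- merge_checked(base[[key]], override[[key]],
                                     paste0(full, "."))
      } else {
        base[[key]] <- override[[key]]
      }
    }
    base
  }
  config <- merge_checked(unclass(config), user)
  validate_pipeline_config(structure(config, class = "pipeline_config"))
}

validate_pipeline_config <- function(config) {
  if (config$association$n_perm < 1) {
    stop_format("association n_perm must be >= 1")
  }
  if (config$enrichment$w < 1) stop_format("enrichment w must be >= 1")
  if (config$association$q_threshold <= 0 || config$association$q_threshold >= 1) {
    stop_format("association q_threshold must be in (0, 1)")
  }
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# manifest records inputs, parameters and seed; no timestamps and no
# absolute paths, so reruns with the same seed are byte-identical
write_manifest <- function(out_dir, config, stage, inputs) {
  inputs <- lapply(inputs, function(p) if (is.null(p)) NULL else basename(p))
  manifest <- list(
    package = "apobecsig",
    version = as.character(utils::packageVersion("apobecsig")),
    stage = stage,
    seed = config$seed,
    inputs = inputs,
    parameters = config[c("enrichment", "association", "scna")]
  )
  yaml::write_yaml(manifest, file.path(out_dir, paste0("manifest_", stage,
                                                       ".yaml")))
}

#' Simulate stage: write a synthetic cohort to disk
#'
#' @param config a `pipeline_config`; `config$simulate` holds
#'   [cohort_spec()] overrides (the spec's own seed is tied to the
#'   pipeline seed).
#' @return updated config whose input paths point at the written cohort.
#' @export
run_simulate_stage <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  args <- config$simulate
  args$seed <- config$seed
  spec <- do.call(cohort_spec, args)
  cohort <- generate_cohort(spec)
  paths <- write_cohort(cohort, file.path(config$out_dir, "cohort"))
  message(sprintf("simulate: wrote %d samples, %d mutations, %d segments",
                  spec$n_samples, nrow(cohort$mutations),
                  nrow(cohort$segments)))
  config$paths$mutations <- unname(paths[["maf"]])
  config$paths$reference <- unname(paths[["fasta"]])
  config$paths$segments <- unname(paths[["seg"]])
  config$paths$annotations <- unname(paths[["annotations"]])
  config$paths$gene_cn <- unname(paths[["gene_cn"]])
  config$paths$gene_mutations <- unname(paths[["gene_mutations"]])
  write_manifest(config$out_dir, config, "simulate", list())
  config
}

#' Enrichment stage: per-sample APOBEC3 scoring and classification
#'
#' @param config a `pipeline_config` with `paths$mutations`,
#'   `paths$reference` and `paths$annotations` set.
#' @return path of the written enrichment TSV.
#' @export
run_enrichment_stage <- function(config) {
  for (p in c("mutations", "reference")) {
    if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
      stop_format("enrichment stage: missing input %s (%s)", p,
                  if (is.null(config$paths[[p]])) "unset" else config$paths[[p]])
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  mutations <- read_mutations(config$paths$mutations, dialect = "maf")
  reference <- read_reference(config$paths$reference)
  ecfg <- enrichment_config(
    w = config$enrichment$w,
    substitution_filter = config$enrichment$substitution_filter,
    alpha = config$enrichment$alpha,
    fold_threshold = config$enrichment$fold_threshold
  )
  samples <- NULL
  if (!is.null(config$paths$annotations) &&
      file.exists(config$paths$annotations)) {
    samples <- read_annotations(config$paths$annotations)$sample_id
  }
  res <- apobec_enrichment(mutations, reference, ecfg, samples = samples)
  out <- file.path(config$out_dir, "enrichment.tsv")
  write_tsv(res, out)
  message(sprintf("enrich: %d samples scored, %d APOBEC high",
                  nrow(res), sum(res$apobec_class == "high")))
  write_manifest(config$out_dir, config, "enrich",
                 config$paths[c("mutations", "reference")])
  out
}

#' Association stage: gene alterations vs APOBEC class, plus subtype test
#'
#' @param config a `pipeline_config` with annotation, gene copy-number and
#'   gene-mutation paths set and the enrichment TSV already written.
#' @return named vector with the association and subtype report paths.
#' @export
run_association_stage <- function(config) {
  enr_path <- file.path(config$out_dir, "enrichment.tsv")
  if (!file.exists(enr_path)) {
    stop_format("association stage: enrichment output not found at %s",
                enr_path)
  }
  classes <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
  annotations <- read_annotations(config$paths$annotations)
  gene_cn <- read_gene_cn(config$paths$gene_cn)
  gene_mutations <- utils::read.delim(config$paths$gene_mutations,
                                      stringsAsFactors = FALSE)
  alterations <- build_alterations(gene_cn, annotations, gene_mutations,
                                   genes = config$association$genes,
                                   loss_rule = config$association$loss_rule)
  assoc <- run_association(classes, alterations, annotations,
                           n_perm = config$association$n_perm,
                           seed = config$seed,
                           q_threshold = config$association$q_threshold)
  assoc_path <- write_tsv(assoc, file.path(config$out_dir, "association.tsv"))
  ann_map <- stats::setNames(annotations$subtype, annotations$sample_id)
  st <- subtype_association(classes$apobec_class,
                            ann_map[classes$sample_id])
  st_tab <- data.frame(statistic = st$statistic, df = st$df, p = st$p)
  st_path <- write_tsv(st_tab, file.path(config$out_dir,
                                         "subtype_chisq.tsv"))
  pw_path <- write_tsv(st$pairwise, file.path(config$out_dir,
                                              "subtype_posthoc.tsv"))
  message(sprintf(
    "associate: %d tests, %d significant at q < %g; subtype chi-square p = %.3g",
    nrow(assoc), sum(assoc$significant), config$association$q_threshold, st$p))
  write_manifest(config$out_dir, config, "associate",
                 config$paths[c("annotations", "gene_cn", "gene_mutations")])
  c(association = assoc_path, subtype = st_path, posthoc = pw_path)
}

#' Breakpoint stage: SCNA breakpoint burden by APOBEC class
#'
#' @param config a `pipeline_config` with `paths$segments` set and the
#'   enrichment TSV already written.
#' @return named vector with the per-sample summary and report paths.
#' @export
run_breakpoint_stage <- function(config) {
  enr_path <- file.path(config$out_dir, "enrichment.tsv")
  if (!file.exists(enr_path)) {
    stop_format("breakpoint stage: enrichment output not found at %s",
                enr_path)
  }
  classes <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
  segments <- read_segments(config$paths$segments)
  summary <- breakpoint_summary(segments, classes,
                                min_delta = config$scna$min_delta)
  bt <- breakpoint_test(summary)
  sum_path <- write_tsv(summary, file.path(config$out_dir,
                                           "breakpoints.tsv"))
  report <- data.frame(U = bt$U, p = bt$p, method = bt$method,
                       median_high = bt$median_high,
                       median_low = bt$median_low,
                       n_high = bt$n_high, n_low = bt$n_low)
  rep_path <- write_tsv(report, file.path(config$out_dir,
                                          "breakpoint_test.tsv"))
  message(sprintf(
    "breakpoints: median high = %g, low = %g, Mann-Whitney p = %.3g",
    bt$median_high, bt$median_low, bt$p))
  write_manifest(config$out_dir, config, "breakpoints",
                 config$paths["segments"])
  c(summary = sum_path, report = rep_path)
}

#' Run the full pipeline on a simulated cohort
#'
#' simulate -> enrich -> associate -> breakpoints. Every output file is
#' reproducible byte-for-byte from (config, seed). A stage failure aborts
#' the chain with the failing stage named.
#'
#' @param config a `pipeline_config`.
#' @return the final config (with resolved paths), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  stages <- list(
    simulate = function() run_simulate_stage(config),
    enrich = function() run_enrichment_stage(config),
    associate = function() run_association_stage(config),
    breakpoints = function() run_breakpoint_stage(config)
  )
  for (stage in names(stages)) {
    result <- tryCatch(stages[[stage]](), error = function(e) {
      stop_format("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e))
    })
    if (stage == "simulate") config <- result
  }
  invisible(config)
}
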