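test_that("reference generation honours GC content and the seed", {
  # gc = 0: A/T only, no mutable C sites
  ref0 <- generate_reference(2000, gc_fraction = 0, seed = 1)
  expect_false(grepl("[CG]", ref0$sequence[[1]]))
  expect_length(ref0$tcw_centers, 0)

  ref <- generate_reference(1e5, gc_fraction = 0.4, seed = 2)
  gc <- sum(strsplit(ref$sequence[[1]], "")[[1]] %in% c("C", "G")) / 1e5
  se <- sqrt(0.4 * 0.6 / 1e5)
  expect_lt(abs(gc - 0.4), 3 * se)

  again <- generate_reference(1e5, gc_fraction = 0.4, seed = 2)
  expect_identical(ref, again)
  expect_error(generate_reference(100, 0.4, 1), ">= 1000")
})

test_that("motif site index marks exactly the TCW / WGA centres", {
  ref <- generate_reference(5000, gc_fraction = 0.5, seed = 3)
  bases <- strsplit(ref$sequence[[1]], "")[[1]]
  for (p in ref$tcw_centers[1:20]) {
    expect_equal(bases[p], "C")
    expect_equal(bases[p - 1], "T")
    expect_true(bases[p + 1] %in% c("A", "T"))
  }
  for (p in ref$wga_centers[1:20]) {
    expect_equal(bases[p], "G")
    expect_true(bases[p - 1] %in% c("A", "T"))
    expect_equal(bases[p + 1], "A")
  }
})

test_that("apobec_fraction = 1 puts every signature mutation in a motif", {
  spec <- cohort_spec(n_samples = 4, reference_length = 2e4,
                      mutations_per_sample = 60,
                      apobec_fraction_high = 1, seed = 5)
  ref <- generate_reference(spec$reference_length, spec$gc_fraction,
                           seed = 9)
  cls <- setNames(rep("high", 4), paste0("H", 1:4))
  cat <- generate_catalog(spec, ref, cls)
  for (s in names(cls)) {
    m <- cat[cat$sample_id == s, ]
    counts <- count_motifs(m, ref$sequence, enrichment_config())
    expect_equal(counts$mutations_tcw, counts$mutations_c)
  }
})

test_that("apobec_fraction = 0 gives background enrichment near 1", {
  spec <- cohort_spec(n_samples = 50, reference_length = 5e4,
                      mutations_per_sample = 150,
                      apobec_fraction_low = 0, seed = 6)
  ref <- generate_reference(spec$reference_length, spec$gc_fraction,
                           seed = 10)
  cls <- setNames(rep("low", 50), sprintf("L%02d", 1:50))
  cat <- generate_catalog(spec, ref, cls)
  es <- vapply(names(cls), function(s) {
    counts <- count_motifs(cat[cat$sample_id == s, ], ref$sequence,
                           enrichment_config())
    compute_enrichment(counts)
  }, numeric(1))
  es <- es[!is.na(es)]
  se <- sd(es) / sqrt(length(es))
  expect_lt(abs(mean(es) - 1), 3 * se + 0.05)
})

test_that("catalogs are deterministic and stable under cohort growth", {
  spec <- cohort_spec(n_samples = 6, reference_length = 1e4,
                      mutations_per_sample = 30, seed = 77)
  ref <- generate_reference(1e4, 0.41, seed = 4)
  cls6 <- setNames(rep(c("high", "low"), 3), paste0("S", 1:6))
  a <- generate_catalog(spec, ref, cls6)
  b <- generate_catalog(spec, ref, cls6)
  expect_identical(a, b)
  # adding samples leaves earlier substreams untouched
  cls8 <- setNames(rep(c("high", "low"), 4), paste0("S", 1:8))
  c8 <- generate_catalog(spec, ref, cls8)
  expect_identical(a, c8[c8$sample_id %in% names(cls6), ])
})

test_that("planted odds ratios reproduce the implied high-class rates", {
  genes <- data.frame(gene = c("NULLG", "ORG8"),
                      alteration_class = "snv",
                      base_rate = 0.15, odds_ratio = c(1, 8),
                      stringsAsFactors = FALSE)
  spec <- cohort_spec(n_samples = 4000, genes = genes, seed = 19)
  cls <- setNames(rep(c("high", "low"), 2000), sprintf("S%04d", 1:4000))
  alt <- generate_alterations(spec, cls, seed = 99)
  tr <- alt$truth
  rate <- function(g, k) {
    v <- tr[tr$gene == g & cls[tr$sample_id] == k, "status"]
    mean(v)
  }
  se <- sqrt(0.15 * 0.85 / 2000)
  expect_lt(abs(rate("NULLG", "high") - rate("NULLG", "low")), 4 * se)
  p_high <- (8 * 0.15 / 0.85) / (1 + 8 * 0.15 / 0.85)
  expect_equal(p_high, 0.585, tolerance = 0.001)
  expect_lt(abs(rate("ORG8", "high") - p_high),
            4 * sqrt(p_high * (1 - p_high) / 2000))
})

test_that("copy-number realisations respect the calling thresholds", {
  genes <- data.frame(gene = c("AMPG", "LOSSG", "NEUTG"),
                      alteration_class = c("amplification", "loss",
                                           "amplification"),
                      base_rate = c(0.5, 0.5, 1e-9 + 0.001),
                      odds_ratio = c(1, 1, 0),
                      stringsAsFactors = FALSE)
  genes$base_rate[3] <- 0.001 # effectively neutral
  spec <- cohort_spec(n_samples = 300, genes = genes, seed = 23)
  cls <- setNames(rep(c("high", "low"), 150), sprintf("S%03d", 1:300))
  alt <- generate_alterations(spec, cls, seed = 7)
  ann <- data.frame(sample_id = names(cls), subtype = "LumA",
                    ploidy = spec$ploidy, stringsAsFactors = FALSE)
  built <- build_alterations(alt$gene_cn, ann, alt$gene_mutations,
                             genes = unique(genes$gene))
  tr <- alt$truth
  for (g in c("AMPG", "LOSSG")) {
    cls_name <- genes$alteration_class[genes$gene == g]
    planted <- tr[tr$gene == g, ]
    called <- built$status[[cls_name]][g, planted$sample_id]
    expect_equal(unname(called), planted$status)
  }
  # neutral draws are never flagged in either CN class
  neut <- tr[tr$gene == "NEUTG" & tr$status == 0, "sample_id"]
  expect_true(all(built$status$amplification["NEUTG", neut] == 0))
  expect_true(all(built$status$loss["NEUTG", neut] == 0))
})

test_that("segment profiles carry the class-specific breakpoint rates", {
  spec <- cohort_spec(n_samples = 80, seed = 31,
                      breakpoint_means = c(high = 40, low = 20))
  cls <- setNames(rep(c("high", "low"), 40), sprintf("S%02d", 1:80))
  seg <- generate_segments(spec, cls)
  counts <- vapply(names(cls), function(s) {
    count_breakpoints(seg[seg$sample_id == s, ], min_delta = 0.5)
  }, integer(1))
  m_high <- mean(counts[cls == "high"]); m_low <- mean(counts[cls == "low"])
  expect_lt(abs(m_high - 40), 3 * sqrt(40 / 40))
  expect_lt(abs(m_low - 20), 3 * sqrt(20 / 40))

  # mean 0: one segment per chromosome, zero breakpoints
  spec0 <- cohort_spec(n_samples = 2, seed = 32,
                       breakpoint_means = c(high = 1e-9, low = 1e-9))
  seg0 <- generate_segments(spec0, setNames(c("high", "low"), c("A", "B")))
  expect_equal(nrow(seg0), 2 * spec0$n_chrom)
  expect_equal(count_breakpoints(seg0[seg0$sample_id == "A", ]), 0L)
})

test_that("whole cohorts are byte-identical across runs with one seed", {
  spec <- cohort_spec(n_samples = 10, reference_length = 1e4,
                      mutations_per_sample = 20, seed = 41)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(spec), d1)
  write_cohort(generate_cohort(spec), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
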