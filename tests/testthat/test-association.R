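make_annotations <- function(samples, subtype = "LumA", ploidy = 2) {
  data.frame(sample_id = samples, subtype = subtype, ploidy = ploidy,
             stringsAsFactors = FALSE)
}

test_that("alteration calls follow the ploidy thresholds", {
  ann <- make_annotations(c("S1", "S2", "S3"), ploidy = c(2, 2, 3.1))
  cn <- data.frame(gene = "ERBB2", sample_id = c("S1", "S2", "S3"),
                   copy_number = c(4, 1, 5), stringsAsFactors = FALSE)
  muts <- data.frame(sample_id = "S1", gene = "TP53",
                     stringsAsFactors = FALSE)
  alt <- build_alterations(cn, ann, muts, genes = c("ERBB2", "TP53"))
  expect_equal(alt$status$amplification["ERBB2", ], c(S1 = 1, S2 = 0, S3 = 0))
  expect_equal(alt$status$loss["ERBB2", ], c(S1 = 0, S2 = 1, S3 = 0))
  expect_equal(alt$status$snv["TP53", ], c(S1 = 1, S2 = 0, S3 = 0))
  # samples without a CN value are excluded from CN classes, not zeroed
  expect_true(all(is.na(alt$status$amplification["TP53", ])))

  # the alternate loss reading flags CN <= ploidy
  alt2 <- build_alterations(cn, ann, muts, genes = "ERBB2",
                            loss_rule = "ratio")
  expect_equal(unname(alt2$status$loss["ERBB2", ]), c(0, 1, 0))

  ann_bad <- make_annotations("S1", ploidy = NA)
  expect_error(build_alterations(cn, ann_bad, muts, genes = "ERBB2"),
               "ploidy")
  expect_error(build_alterations(cn, ann, muts, genes = character(0)),
               "non-empty")
})

test_that("permutation test handles degenerate and exhaustive cases exactly", {
  lab <- c(1, 1, 1, 0, 0, 0)
  expect_error(permutation_test(rep(1, 4), rbinom(4, 1, 0.5)), "both APOBEC")

  # constant alteration: statistic 0, p = 1
  res0 <- permutation_test(lab, rep(0, 6), n_perm = 200, seed = 1)
  expect_equal(res0$observed_stat, 0)
  expect_equal(res0$p, 1)

  # alteration exactly the high samples: exhaustive p = 1 / C(6,3)
  res <- permutation_test(lab, c(1, 1, 1, 0, 0, 0), exhaustive = "always")
  expect_equal(res$method, "exhaustive")
  expect_equal(res$observed_stat, 1)
  expect_equal(res$p, 1 / 20)

  # Monte-Carlo agrees with the exhaustive value within binomial error
  mc <- permutation_test(lab, c(1, 1, 1, 0, 0, 0), n_perm = 4000, seed = 3,
                         exhaustive = "never")
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(mc$p - 0.05), 4 * se + 1 / 4000)

  # fixed seed is reproducible bit for bit
  a <- permutation_test(lab, c(1, 0, 1, 0, 0, 1), n_perm = 500, seed = 11,
                        exhaustive = "never")
  b <- permutation_test(lab, c(1, 0, 1, 0, 0, 1), n_perm = 500, seed = 11,
                        exhaustive = "never")
  expect_identical(a, b)
})

test_that("exhaustive mode matches full enumeration on small cohorts", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    lab <- sample(c(rep(1, 3), rep(0, n - 3)))
    alt <- rbinom(n, 1, 0.4)
    if (length(unique(alt)) == 1) next
    res <- permutation_test(lab, alt, exhaustive = "always")
    # direct enumeration, written out independently
    sets <- combn(n, 3)
    obs <- mean(alt[lab == 1]) - mean(alt[lab == 0])
    stats <- apply(sets, 2, function(ix) {
      mean(alt[ix]) - mean(alt[-ix])
    })
    expect_equal(res$p, mean(stats >= obs - 1e-12))
  }
})

test_that("null permutation p-values are uniform for a continuous score", {
  set.seed(31)
  ps <- replicate(300, {
    lab <- sample(c(rep(1, 30), rep(0, 70)))
    score <- rnorm(100)
    permutation_test(lab, score, n_perm = 500,
                     seed = sample.int(1e6, 1), exhaustive = "never")$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cohort-then-subtype association recovers a planted gene", {
  set.seed(8)
  n <- 200
  samples <- sprintf("P%03d", 1:n)
  subtype <- sample(c("HER2", "LumA"), n, replace = TRUE)
  classes <- data.frame(sample_id = samples,
                        apobec_class = ifelse(runif(n) < 0.3, "high", "low"),
                        stringsAsFactors = FALSE)
  ann <- data.frame(sample_id = samples, subtype = subtype, ploidy = 2,
                    stringsAsFactors = FALSE)
  is_high <- classes$apobec_class == "high"
  p_high <- (8 * 0.15 / 0.85) / (1 + 8 * 0.15 / 0.85)
  planted <- rbinom(n, 1, ifelse(is_high, p_high, 0.15))
  null1 <- rbinom(n, 1, 0.15)
  muts <- data.frame(
    sample_id = c(samples[planted == 1], samples[null1 == 1]),
    gene = c(rep("GENE_A", sum(planted)), rep("GENE_B", sum(null1))),
    stringsAsFactors = FALSE
  )
  cn <- data.frame(gene = character(0), sample_id = character(0),
                   copy_number = numeric(0))
  alt <- build_alterations(cn, ann, muts, genes = c("GENE_A", "GENE_B"))
  res <- suppressMessages(
    run_association(classes, alt, ann, n_perm = 2000, seed = 5)
  )
  cohort_snv <- res[res$stratum == "cohort" & res$alteration_class == "snv", ]
  expect_true(cohort_snv$significant[cohort_snv$gene == "GENE_A"])
  expect_setequal(unique(res$stratum), c("cohort", "HER2", "LumA"))
  # q-values within a stratum/class depend only on that p-value set
  expect_equal(cohort_snv$q, bh_adjust(cohort_snv$p))
})

test_that("chi-square subtype association and post hoc tests are Pearson", {
  # identical high fractions: statistic 0, p 1
  classes <- rep(c("high", "low", "low", "low"), times = 4)
  subtypes <- rep(c("HER2", "Basal", "LumA", "LumB"), each = 4)
  st <- subtype_association(classes, subtypes)
  expect_equal(st$statistic, 0)
  expect_equal(st$p, 1)

  # toy 2x4 table against the hand-computed sum((O - E)^2 / E)
  counts_high <- c(HER2 = 30, Basal = 10, LumA = 12, LumB = 8)
  counts_low <- c(HER2 = 70, Basal = 90, LumA = 88, LumB = 92)
  classes2 <- c(rep("high", sum(counts_high)), rep("low", sum(counts_low)))
  subtypes2 <- c(rep(names(counts_high), counts_high),
                 rep(names(counts_low), counts_low))
  st2 <- subtype_association(classes2, subtypes2)
  obs <- rbind(counts_high, counts_low)
  exp_tab <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(st2$statistic, sum((obs - exp_tab)^2 / exp_tab),
               tolerance = 1e-12)
  expect_lt(st2$p, 0.01)

  # a pairwise post hoc p equals the global test restricted to that pair
  pair <- st2$pairwise[st2$pairwise$subtype_a == "HER2" &
                         st2$pairwise$subtype_b == "Basal", ]
  keep <- subtypes2 %in% c("HER2", "Basal")
  st_pair <- subtype_association(classes2[keep], subtypes2[keep])
  expect_equal(pair$p, st_pair$p, tolerance = 1e-12)

  expect_error(subtype_association(rep("low", 8),
                                   rep(c("HER2", "LumA"), 4)),
               "expected count of 0")
})
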