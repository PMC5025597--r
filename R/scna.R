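# Segmental SCNA breakpoints. A breakpoint is a boundary between adjacent
# segments of one chromosome whose copy numbers differ by at least
# min_delta; chromosome boundaries never count. Per-sample counts are
# compared between APOBEC classes with a Mann-Whitney U test.

#' Count segmental copy-number breakpoints for one sample
#'
#' Adjacent same-chromosome segment pairs with `|delta copy_number| >=
#' min_delta` each contribute one breakpoint. Adjacency is by segment
#' order, not genomic proximity, so gaps between consecutive segments are
#' tolerated. The count is invariant under a constant shift of all copy
#' numbers.
#'
#' @param segments segment `data.frame` for a single sample (`chrom`,
#'   `start`, `end`, `copy_number`); validated and sorted internally.
#' @param min_delta minimum absolute copy-number change (default 0.5 on
#'   absolute copy number).
#' @return non-negative integer breakpoint count.
#' @export
count_breakpoints <- function(segments, min_delta = 0.5) {
  if (nrow(segments) == 0) return(0L)
  if (length(unique(segments$sample_id)) > 1) {
    stop_format("count_breakpoints expects segments of a single sample")
  }
  seg <- validate_segments(segments)
  n <- 0L
  for (chrom in unique(seg$chrom)) {
    cn <- seg$copy_number[seg$chrom == chrom]
    if (length(cn) > 1) {
      n <- n + sum(abs(diff(cn)) >= min_delta - 1e-9)
    }
  }
  as.integer(n)
}

#' Per-sample breakpoint summary joined with APOBEC class
#'
#' @param segments cohort segment `data.frame` (multiple samples).
#' @param classes `data.frame` with `sample_id` and `apobec_class`.
#' @param min_delta passed to [count_breakpoints()].
#' @return `data.frame` with `sample_id`, `n_breakpoints`, `apobec_class`
#'   for every classified sample (samples without segments get 0).
#' @export
breakpoint_summary <- function(segments, classes, min_delta = 0.5) {
  counts <- vapply(classes$sample_id, function(s) {
    count_breakpoints(segments[segments$sample_id == s, , drop = FALSE],
                      min_delta = min_delta)
  }, integer(1))
  data.frame(sample_id = classes$sample_id,
             n_breakpoints = unname(counts),
             apobec_class = classes$apobec_class,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midrank tie handling. The two-sided
#' p-value is exact (full enumeration of the rank distribution) when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` (for `x` vs `y`), `p`, and `method`
#'   (`"exact"`/`"normal"`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_format("both samples must be non-empty")
  }
  if (any(!is.finite(c(x, y)))) stop_format("inputs must be finite numbers")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny) <= 20 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  list(U = unname(U), p = min(1, p), method = if (exact) "exact" else "normal")
}

#' Compare breakpoint burden between APOBEC classes
#'
#' Mann-Whitney U test of per-sample breakpoint counts, APOBEC high vs
#' low; the direction of the effect is read off the class medians.
#'
#' @param summary a [breakpoint_summary()] result.
#' @return list with `U`, `p`, `median_high`, `median_low`, `n_high`,
#'   `n_low`.
#' @export
breakpoint_test <- function(summary) {
  hi <- summary$n_breakpoints[summary$apobec_class == "high"]
  lo <- summary$n_breakpoints[summary$apobec_class == "low"]
  if (length(hi) == 0 || length(lo) == 0) {
    stop_format("both APOBEC classes must be present")
  }
  mw <- mann_whitney(hi, lo)
  list(U = mw$U, p = mw$p, method = mw$method,
       median_high = stats::median(hi), median_low = stats::median(lo),
       n_high = length(hi), n_low = length(lo))
}
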