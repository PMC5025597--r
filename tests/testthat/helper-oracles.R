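# Independent oracles and small fixture builders. Every oracle here is a
# deliberately naive implementation (full rescans, exhaustive enumeration,
# closed forms) kept separate from the code paths it checks.

make_ref <- function(...) {
  seqs <- toupper(unlist(list(...)))
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  seqs
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# reverse-complement an entire catalog + reference (strand mirror)
revcomp_catalog <- function(mutations, reference) {
  lens <- nchar(reference)
  ref_rc <- vapply(reference, revcomp, character(1))
  names(ref_rc) <- names(reference)
  mut_rc <- mutations
  mut_rc$pos <- lens[mutations$chrom] - mutations$pos + 1L
  mut_rc$ref <- unname(COMP[mutations$ref])
  mut_rc$alt <- unname(COMP[mutations$alt])
  list(mutations = mut_rc, reference = ref_rc)
}

# full-window rescan motif counter: walks every offset of every window
# with substr, character by character
naive_count_motifs <- function(mutations, reference, w = 20,
                               filter = "ct_cg_only") {
  m_tcw <- 0; m_c <- 0; c_tcw <- 0; c_c <- 0
  for (i in seq_len(nrow(mutations))) {
    ref <- mutations$ref[i]; alt <- mutations$alt[i]
    qual <- if (filter == "ct_cg_only") {
      (ref == "C" && alt %in% c("T", "G")) ||
        (ref == "G" && alt %in% c("A", "C"))
    } else ref %in% c("C", "G")
    if (!qual) next
    seq <- reference[[mutations$chrom[i]]]
    len <- nchar(seq)
    pos <- mutations$pos[i]
    win <- character(2 * w + 1)
    for (k in seq_len(2 * w + 1)) {
      p <- pos - w + k - 1
      win[k] <- if (p < 1 || p > len) "N" else substr(seq, p, p)
    }
    m_c <- m_c + 1
    tri <- paste(win[w:(w + 2)], collapse = "")
    if (ref == "C") {
      if (substr(tri, 1, 2) == "TC" && substr(tri, 3, 3) %in% c("A", "T")) {
        m_tcw <- m_tcw + 1
      }
      for (k in 1:(2 * w - 1)) {
        t3 <- paste(win[k:(k + 2)], collapse = "")
        if (substr(t3, 1, 2) == "TC" && substr(t3, 3, 3) %in% c("A", "T")) {
          c_tcw <- c_tcw + 1
        }
      }
      c_c <- c_c + sum(win == "C")
    } else {
      if (substr(tri, 1, 1) %in% c("A", "T") && substr(tri, 2, 3) == "GA") {
        m_tcw <- m_tcw + 1
      }
      for (k in 1:(2 * w - 1)) {
        t3 <- paste(win[k:(k + 2)], collapse = "")
        if (substr(t3, 1, 1) %in% c("A", "T") && substr(t3, 2, 3) == "GA") {
          c_tcw <- c_tcw + 1
        }
      }
      c_c <- c_c + sum(win == "G")
    }
  }
  list(mutations_tcw = m_tcw, mutations_c = m_c,
       context_tcw = c_tcw, context_c = c_c)
}

# exhaustive one-sided hypergeometric tail by direct enumeration over all
# tables with the observed margins, probabilities from choose()
hyper_tail_enum <- function(a, mc, ct, cc) {
  if (mc == 0) return(1)
  k <- a + ct # first-column margin
  total <- mc + cc
  xs <- max(0, k - cc):min(mc, k)
  probs <- choose(mc, xs) * choose(cc, k - xs) / choose(total, k)
  sum(probs[xs >= a])
}

# textbook BH step-up: q_i = min over j >= rank(i) of p_(j) * m / j
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive two-sided Mann-Whitney p by enumerating every assignment of
# ranks to the first group (no ties assumed)
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  ranks <- seq_len(nx + ny)
  u_all <- colSums(matrix(ranks[sets], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# uniform random catalog on a random reference; mutations at C/G sites
# (plus a few at A/T to exercise the qualifying filter)
random_catalog <- function(n_mut, ref_len = 2000, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
               collapse = "")
  reference <- c(chr1 = seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(ref_len, n_mut)
  ref <- bases[pos]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  list(mutations = data.frame(sample_id = "S1", chrom = "chr1", pos = pos,
                              ref = ref, alt = alt,
                              stringsAsFactors = FALSE),
       reference = reference)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
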