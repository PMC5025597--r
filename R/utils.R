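#' @keywords internal
"_PACKAGE"

# Subtype vocabulary used throughout; labels are consumed as given (PAM50
# assignment itself is upstream of this package).
SUBTYPE_LEVELS <- c("HER2", "Basal", "LumA", "LumB", "Normal")

BASES <- c("A", "C", "G", "T")

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed. Each component
#' (reference, catalog, alterations, segments, permutation batches) and each
#' sample gets its own substream so that, e.g., adding samples to a cohort
#' does not perturb the draws of earlier samples. The derived seed is kept
#' inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed master integer seed.
#' @param stream integer component offset (1 = reference, 2 = catalog, ...).
#' @param index integer within-stream index (e.g. sample number), default 0.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(seed) %% m) * 48271 %% m
  s <- (s + stream * 9973 + index * 7919) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Evaluate an expression with a local RNG state
#'
#' Seeds the RNG for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library functions do not silently consume the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
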