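`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a global seed
#'
#' Counter-based seed splitting: every (stage, unit) pair maps to its own
#' 31-bit sub-seed through a fixed LCG-style mix of the global seed and the
#' counter, so adding a unit to a run never perturbs the random draws of the
#' others.
#'
#' @param seed global integer seed.
#' @param counter nonnegative integer identifying the consumer (unit index,
#'   stage offset, ...).
#' @return A positive integer below `2^31`.
#' @export
deriveSeed <- function(seed, counter = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  # two rounds of multiplicative mixing keep nearby counters uncorrelated
  s <- (s * 48271) %% m
  s <- (s + as.numeric(counter) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

## short stable content hash (FNV-1a, 32-bit) for provenance records
.contentHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
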