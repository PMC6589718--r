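#' Derive a reproducible substream seed
#'
#' Folds one or more integer stream identifiers into a base seed with a
#' Lehmer-style recurrence modulo the Mersenne prime 2^31 - 1. The rule is
#' deterministic and position-sensitive, so `substream_seed(s, i, j)` for one
#' participant/block never depends on how many other participants or blocks a
#' run contains: adding a participant to a cohort leaves everyone else's
#' simulated data untouched.
#'
#' @param seed base integer seed (non-negative).
#' @param ... integer stream identifiers (e.g. participant index, block index).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, 3, 2)
substream_seed <- function(seed, ...) {
  ids <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m) + 1
  for (k in as.double(ids)) {
    x <- (x * 48271 + (k %% m) + 1) %% m
  }
  as.integer(x %% (m - 1)) + 1L
}

# clamp scalar/vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "noxithresh_error")))
}
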