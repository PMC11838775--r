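#' Nearest-rank percentile
#'
#' The nearest-rank convention: the p-th percentile of `x` is the value at
#' sorted position `ceiling(p/100 * n)`. Used for all bootstrap and
#' permutation cuts in the package (95th/5th percentile verdicts).
#'
#' @param x numeric vector (nonempty).
#' @param p percentile in (0, 100].
#' @return A single value of `x`.
#' @export
percentile_nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Circularly shift a vector
#'
#' Rotates `x` to the right by `k` positions: element `i` of the result is
#' `x[(i - k - 1) %% n + 1]`. A circular shift is a permutation, so the
#' multiset of values (e.g. per-cell event counts) is conserved exactly.
#'
#' @param x a vector.
#' @param k integer shift offset.
#' @return The rotated vector.
#' @export
circular_shift <- function(x, k) {
  n <- length(x)
  if (n == 0) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# run-length encode a logical vector into half-open frame-index runs of TRUE
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths   # 0-based start of each run
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])  # half-open frame indices
}

# derive a stage seed from a base seed, kept within 32-bit integer range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
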