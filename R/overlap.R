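#' Overlap between two cell groups
#'
#' The proportion of cells classified as part of both groups. The default
#' denominator is the union (Jaccard index); alternatives are the smaller
#' group size or the full session cell count. Verdicts from
#' [overlap_test()] are robust to this choice because the bootstrap null
#' uses the same metric.
#'
#' @param A,B vectors of member cell ids (sets).
#' @param denominator `"union"` (Jaccard, default), `"min"`, or
#'   `"n_cells"`.
#' @param n_cells session cell count; required for
#'   `denominator = "n_cells"`.
#' @return Overlap proportion in `[0, 1]`.
#' @examples
#' overlap(1:10, 9:18)  # 2/18
#' @export
overlap <- function(A, B, denominator = c("union", "min", "n_cells"),
                    n_cells = NULL) {
  denominator <- match.arg(denominator)
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0)
    stop("overlap undefined: both groups are empty")
  inter <- length(intersect(A, B))
  den <- switch(denominator,
    union = length(union(A, B)),
    min = min(length(A), length(B)),
    n_cells = { stopifnot(!is.null(n_cells)); n_cells })
  if (den == 0) stop("overlap denominator is zero")
  inter / den
}

#' Bootstrapped chance-level overlap distribution
#'
#' Each resample draws two uniform random subsets of the stated sizes,
#' without replacement, from the session's cell population and records
#' their overlap. This is the chance-level distribution against which a
#' real overlap is judged.
#'
#' @param n_cells session cell count.
#' @param size_A,size_B group sizes (each `<= n_cells`).
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @inheritParams overlap
#' @return Numeric vector of `n_resamples` overlap proportions.
#' @export
overlap_null <- function(n_cells, size_A, size_B, n_resamples = 1000,
                         seed = 1, denominator = c("union", "min", "n_cells")) {
  denominator <- match.arg(denominator)
  stopifnot(size_A <= n_cells, size_B <= n_cells, size_A + size_B > 0)
  set.seed(seed)
  flag <- logical(n_cells)
  vapply(seq_len(n_resamples), function(r) {
    a <- sample.int(n_cells, size_A)
    b <- sample.int(n_cells, size_B)
    flag[a] <- TRUE
    inter <- sum(flag[b])
    flag[a] <- FALSE
    den <- switch(denominator,
                  union = size_A + size_B - inter,
                  min = min(size_A, size_B),
                  n_cells = n_cells)
    inter / den
  }, numeric(1))
}

#' Percentile verdict on an observed overlap
#'
#' Groups are significantly overlapped when the real overlap falls
#' strictly above the nearest-rank 95th percentile of the bootstrapped
#' chance distribution, and significantly non-overlapped when it falls
#' strictly below the 5th percentile; otherwise not significant (`"ns"`).
#'
#' @param observed observed overlap proportion.
#' @param null_values numeric vector of bootstrap overlaps (nonempty).
#' @param upper,lower percentile cuts (defaults 95 and 5).
#' @return `"overlapped"`, `"non-overlapped"`, or `"ns"`.
#' @export
overlap_verdict <- function(observed, null_values, upper = 95, lower = 5) {
  stopifnot(length(null_values) > 0)
  if (observed > percentile_nearest_rank(null_values, upper)) return("overlapped")
  if (observed < percentile_nearest_rank(null_values, lower)) return("non-overlapped")
  "ns"
}

#' Overlap test between two cell groups
#'
#' Convenience wrapper: computes the observed overlap, its bootstrap null
#' and the percentile verdict in one call.
#'
#' @inheritParams overlap
#' @inheritParams overlap_null
#' @param labels length-2 character vector naming the groups.
#' @return An object of class `"overlap_test"`: list with `group_pair`,
#'   `observed`, `null_values`, `n_resamples`, `verdict`, `p95`, `p5`,
#'   `seed`, `denominator`.
#' @export
overlap_test <- function(A, B, n_cells, n_resamples = 1000, seed = 1,
                         denominator = c("union", "min", "n_cells"),
                         labels = c("A", "B")) {
  denominator <- match.arg(denominator)
  obs <- overlap(A, B, denominator = denominator, n_cells = n_cells)
  null <- overlap_null(n_cells, length(unique(A)), length(unique(B)),
                       n_resamples = n_resamples, seed = seed,
                       denominator = denominator)
  structure(list(group_pair = labels, observed = obs, null_values = null,
                 n_resamples = n_resamples,
                 verdict = overlap_verdict(obs, null),
                 p95 = percentile_nearest_rank(null, 95),
                 p5 = percentile_nearest_rank(null, 5),
                 seed = seed, denominator = denominator),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> %s vs %s: observed %.4f, null [P5 %.4f, P95 %.4f] -> %s\n",
              x$group_pair[1], x$group_pair[2], x$observed, x$p5, x$p95,
              x$verdict))
  invisible(x)
}

#' Pairwise overlap tests for an ensemble assignment
#'
#' Runs [overlap_test()] for every unordered pair of groups in an
#' assignment.
#'
#' @param assignment an [ensemble_assignment()].
#' @param n_resamples,seed,denominator passed to [overlap_test()]; each
#'   pair gets a distinct seed derived from `seed`.
#' @return Data frame with columns `group_A`, `group_B`, `observed`,
#'   `p5`, `p95`, `verdict`, `seed`.
#' @export
overlap_pairs <- function(assignment, n_resamples = 1000, seed = 1,
                          denominator = "union") {
  stopifnot(inherits(assignment, "ensemble_assignment"))
  gs <- names(assignment$membership)
  out <- NULL
  k <- 0
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    k <- k + 1
    A <- assignment$membership[[gs[i]]]; B <- assignment$membership[[gs[j]]]
    if (length(A) == 0 && length(B) == 0) next
    tst <- overlap_test(A, B, n_cells = length(assignment$cell_ids),
                        n_resamples = n_resamples, seed = stage_seed(seed, k),
                        denominator = denominator, labels = c(gs[i], gs[j]))
    out <- rbind(out, data.frame(group_A = gs[i], group_B = gs[j],
                                 observed = tst$observed, p5 = tst$p5,
                                 p95 = tst$p95, verdict = tst$verdict,
                                 seed = tst$seed))
  }
  out
}
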