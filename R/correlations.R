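#' Pairwise Pearson correlations of binned event arrays
#'
#' Pearson r for every unordered pair of cells in the event raster.
#' Zero-variance cells (no events, or events in every bin) have no defined
#' correlation; they are excluded and listed with a reason rather than
#' silently dropped. Group slices (intra-group "freezing-freezing" pairs,
#' inter-group "freezing-shock" pairs, ...) are extracted downstream by
#' [compare_group_to_null()].
#'
#' @param raster an `"event_raster"` (by default correlations operate on
#'   the binary event arrays so that observed and circular-shift null use
#'   the same object; pass a binned z-matrix as a plain raster-like object
#'   to correlate z values instead).
#' @return An object of class `"correlation_table"`: list with `pairs`
#'   (data frame `cell_i`, `cell_j`, `r`; `cell_i < cell_j`), `excluded`
#'   (data frame `cell`, `reason`), `included` (cell ids), `n_bins`.
#' @export
pairwise_correlations <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  ev <- raster$events
  v <- apply(ev, 1, stats::var)
  excl <- raster$cell_ids[v == 0]
  reason <- ifelse(rowSums(ev[v == 0, , drop = FALSE]) == 0,
                   "no events", "constant (event in every bin)")
  keep <- which(v > 0)
  if (length(keep) < 2)
    stop("fewer than 2 cells with nonzero variance: no pairs to correlate")
  ids <- raster$cell_ids[keep]
  cm <- stats::cor(t(ev[keep, , drop = FALSE]))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(cell_i = ids[ut[, 1]], cell_j = ids[ut[, 2]],
                      r = cm[ut])
  structure(list(pairs = pairs,
                 excluded = data.frame(cell = excl, reason = reason),
                 included = ids, n_bins = ncol(ev)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table> %d pair(s) over %d cells (%d excluded), mean r %.4f\n",
              nrow(x$pairs), length(x$included), nrow(x$excluded),
              mean(x$pairs$r)))
  invisible(x)
}

#' Circular-shift null correlations
#'
#' Builds the permutation null of the pairwise correlations: in each
#' replicate, every cell's event array is circularly shifted by an
#' independent uniform offset in `[1, n_bins - 1]` and the pair
#' correlations are recomputed. Shifting is a permutation, so every
#' replicate conserves each cell's event count exactly; independent
#' per-cell offsets preserve single-cell statistics while destroying
#' pairwise timing.
#'
#' @param raster the `"event_raster"` used for the observed table.
#' @param table the [pairwise_correlations()] result (fixes the pair set
#'   and exclusions).
#' @param n_replicates number of replicates (default 1000).
#' @param seed integer seed.
#' @param keep_marginals when `TRUE`, also return `marginals`, the
#'   `n_replicates x n_cells` matrix of per-replicate per-cell event
#'   counts (each row must equal the observed counts — the conservation
#'   invariant of the permutation null).
#' @return An object of class `"null_correlations"`: list with `r`
#'   (matrix `n_replicates x n_pairs`, columns in the order of
#'   `table$pairs`), `pairs`, `n_replicates`, `seed`, and optionally
#'   `marginals`.
#' @export
null_correlations <- function(raster, table, n_replicates = 1000, seed = 1,
                              keep_marginals = FALSE) {
  stopifnot(inherits(raster, "event_raster"),
            inherits(table, "correlation_table"), n_replicates >= 1)
  idx <- match(table$included, raster$cell_ids)
  ev <- raster$events[idx, , drop = FALSE]
  n_bins <- ncol(ev)
  n_cells <- nrow(ev)
  ui <- match(table$pairs$cell_i, table$included)
  uj <- match(table$pairs$cell_j, table$included)
  sel <- cbind(ui, uj)
  set.seed(seed)
  out <- matrix(NA_real_, n_replicates, nrow(table$pairs))
  marg <- if (keep_marginals) matrix(NA_real_, n_replicates, n_cells)
  shifted <- ev
  for (rep_i in seq_len(n_replicates)) {
    offs <- sample.int(n_bins - 1L, n_cells, replace = TRUE)
    for (c_i in seq_len(n_cells))
      shifted[c_i, ] <- circular_shift(ev[c_i, ], offs[c_i])
    cm <- stats::cor(t(shifted))
    out[rep_i, ] <- cm[sel]
    if (keep_marginals) marg[rep_i, ] <- rowSums(shifted)
  }
  structure(list(r = out, pairs = table$pairs[, c("cell_i", "cell_j")],
                 n_replicates = n_replicates, seed = seed,
                 marginals = marg),
            class = "null_correlations")
}

# row indices of the pairs connecting member sets A and B
pair_slice <- function(pairs, A, B) {
  which((pairs$cell_i %in% A & pairs$cell_j %in% B) |
        (pairs$cell_i %in% B & pairs$cell_j %in% A))
}

#' Compare a group slice of correlations to its circular-shift null
#'
#' The observed statistic is the mean Pearson r over the slice of pairs
#' connecting the two member sets (intra-group when `A` and `B` coincide);
#' the null distribution is the per-replicate mean over the same slice.
#' The slice is significant (one-sided) when the observed mean strictly
#' exceeds the nearest-rank `100*(1-alpha)` percentile of the null means.
#' Cumulative distributions of observed and pooled null r values are
#' returned for plotting. Comparing to a same-size null controls for
#' sample-size effects. Nulls with fewer than `1/alpha` replicates cannot
#' resolve the percentile and are flagged underpowered.
#'
#' @param table a [pairwise_correlations()] result.
#' @param null the matching [null_correlations()] result.
#' @param members_A,members_B cell id sets defining the slice.
#' @param alpha one-sided level (default 0.05).
#' @param group_pair length-2 labels for reporting.
#' @return An object of class `"correlation_comparison"`: list with
#'   `group_pair`, `n_pairs`, `observed_mean`, `null_means`, `null_cut`,
#'   `significant`, `underpowered`, `observed_r`, `null_r_pooled`.
#' @export
compare_group_to_null <- function(table, null, members_A, members_B = members_A,
                                  alpha = 0.05, group_pair = c("A", "B")) {
  stopifnot(inherits(table, "correlation_table"),
            inherits(null, "null_correlations"))
  sl <- pair_slice(table$pairs, members_A, members_B)
  if (length(sl) == 0) stop("no correlation pairs in the requested slice")
  obs_r <- table$pairs$r[sl]
  obs <- mean(obs_r)
  null_means <- rowMeans(null$r[, sl, drop = FALSE])
  underpowered <- null$n_replicates < ceiling(1 / alpha)
  cut <- percentile_nearest_rank(null_means, 100 * (1 - alpha))
  structure(list(group_pair = group_pair, n_pairs = length(sl),
                 observed_mean = obs, null_means = null_means,
                 null_cut = cut,
                 significant = !underpowered && obs > cut,
                 underpowered = underpowered,
                 observed_r = obs_r,
                 null_r_pooled = as.vector(null$r[, sl, drop = FALSE])),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> %s-%s: %d pair(s), mean r %.4f vs null cut %.4f -> %s%s\n",
              x$group_pair[1], x$group_pair[2], x$n_pairs, x$observed_mean,
              x$null_cut, if (x$significant) "significant" else "ns",
              if (x$underpowered) " [UNDERPOWERED]" else ""))
  invisible(x)
}
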