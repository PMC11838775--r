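#' Ensemble assignment container
#'
#' Holds per-cell group membership produced by one of the two detection
#' methods. Groups may overlap (a cell can belong to several groups).
#'
#' @param membership named list: group label -> integer vector of member
#'   cell ids.
#' @param method `"rank"` or `"statistical"`.
#' @param cell_ids the full cell id set of the source session.
#' @param thresholds named list of thresholds used (documentation only).
#' @param flagged cell ids excluded or degenerate (e.g. all-zero cells).
#' @return An object of class `"ensemble_assignment"`.
#' @export
ensemble_assignment <- function(membership, method, cell_ids,
                                thresholds = list(), flagged = integer()) {
  stopifnot(is.list(membership), method %in% c("rank", "statistical"))
  for (g in names(membership))
    if (!all(membership[[g]] %in% cell_ids))
      stop("member cells of group '", g, "' missing from the cell set")
  structure(list(membership = membership, method = method,
                 cell_ids = as.integer(cell_ids), thresholds = thresholds,
                 flagged = as.integer(flagged)),
            class = "ensemble_assignment")
}

#' @export
print.ensemble_assignment <- function(x, ...) {
  cat(sprintf("<ensemble_assignment> method=%s, %d cells\n",
              x$method, length(x$cell_ids)))
  for (g in names(x$membership))
    cat(sprintf("  %-14s %d member(s)\n", g, length(x$membership[[g]])))
  invisible(x)
}

# per-cell mean of raw trace samples whose midpoints fall inside the epochs
in_epoch_means <- function(trace, epochs) {
  epochs <- as_epoch_set(epochs)
  if (nrow(epochs) == 0) stop("epoch set is empty")
  mid <- (seq_len(ncol(trace$values)) - 0.5) / trace$sample_rate
  sel <- in_epochs(mid, epochs)
  if (!any(sel)) stop("no trace samples fall inside the epochs")
  rowMeans(trace$values[, sel, drop = FALSE])
}

#' Ensemble detection by activity ranking
#'
#' The activity-ranking rule used to emulate activity-dependent tagging:
#' each cell's raw trace is averaged over the condition epochs (the period
#' light would have been delivered), and cells whose in-epoch mean exceeds
#' the across-cell mean plus `sd_mult` population standard deviations of
#' those in-epoch means are designated group members (strict inequality).
#'
#' @param trace a [trace_matrix()].
#' @param epochs an [epoch_set()] of condition (tagging) epochs.
#' @param sd_mult SD multiplier (default 1, "mean plus one standard
#'   deviation").
#' @return Integer vector of member cell ids, with attributes `means`
#'   (the in-epoch means) and `threshold`.
#' @examples
#' tr <- trace_matrix(rbind(rep(0, 60), rep(0, 60), rep(0, 60), rep(10, 60)), 1)
#' detect_rank(tr, epoch_set("w", 0, 60))  # only the high cell
#' @export
detect_rank <- function(trace, epochs, sd_mult = 1) {
  stopifnot(inherits(trace, "trace_matrix"))
  means <- in_epoch_means(trace, epochs)
  mu <- mean(means)
  sdp <- sqrt(mean((means - mu)^2))   # population SD
  thr <- mu + sd_mult * sdp
  members <- trace$cell_ids[means > thr]
  structure(members, means = stats::setNames(means, trace$cell_ids),
            threshold = thr)
}

# in-sums of x under all circular right-shifts k = 0..n-1 (FFT cross-corr):
# S[k+1] = sum_b mask[b] * x[((b-1-k) mod n) + 1]
circ_in_sums <- function(x, mask) {
  n <- length(x)
  Re(stats::fft(stats::fft(as.numeric(mask)) * Conj(stats::fft(x)),
                inverse = TRUE)) / n
}

#' Ensemble detection by circular-shift permutation test
#'
#' The statistical criterion: for every cell, activity is the 1-s binned
#' trace (pre-threshold), and the statistic is the ratio of mean binned
#' activity inside the condition epochs to the mean outside. A null
#' distribution is built from `n_shifts` random circular shifts of that
#' cell's binned series (uniform offsets in `[1, n_bins - 1]`), and the
#' cell is a member when its real ratio strictly exceeds the nearest-rank
#' 95th percentile of its null. Replicates with zero out-of-epoch activity
#' have an undefined ratio and are redrawn; all-zero cells are non-members
#' and flagged.
#'
#' @param trace a [trace_matrix()].
#' @param epochs an [epoch_set()] of condition epochs; both the in-epoch
#'   and out-of-epoch bin sets must be nonempty.
#' @param n_shifts number of circular shifts (default 1000).
#' @param seed integer seed for the shift offsets.
#' @param percentile percentile cut (default 95).
#' @return Integer vector of member cell ids with attributes `statistic`
#'   (per-cell real in/out ratio; `Inf` when all activity is in-epoch),
#'   `null_p95` (per-cell percentile cut) and `flagged` (all-zero cells).
#' @export
detect_statistical <- function(trace, epochs, n_shifts = 1000, seed = 1,
                               percentile = 95) {
  stopifnot(inherits(trace, "trace_matrix"), n_shifts >= 1)
  epochs <- as_epoch_set(epochs)
  binned <- bin_trace(trace$values, trace$sample_rate)
  n_bins <- ncol(binned)
  mask <- in_epochs(seq_len(n_bins) - 0.5, epochs)
  n_in <- sum(mask); n_out <- n_bins - n_in
  if (n_in == 0 || n_out == 0)
    stop("both in-epoch and out-of-epoch time must be nonzero")

  set.seed(seed)
  n_cells <- nrow(binned)
  stat <- numeric(n_cells); cut <- numeric(n_cells)
  member <- logical(n_cells); flagged <- logical(n_cells)
  ratio_of <- function(in_sum, total) {
    out_mean <- (total - in_sum) / n_out
    (in_sum / n_in) / out_mean
  }
  for (i in seq_len(n_cells)) {
    x <- binned[i, ]
    total <- sum(x)
    if (all(x == 0)) { flagged[i] <- TRUE; stat[i] <- NA_real_; cut[i] <- NA_real_; next }
    in_sums <- circ_in_sums(x, mask)          # offsets 0 .. n_bins-1
    real_in <- sum(x[mask])
    tol <- 1e-9 * (sum(abs(x)) + 1)           # "zero out-of-epoch activity"
    stat[i] <- if (abs(total - real_in) <= tol) Inf
               else ratio_of(real_in, total)
    # null: uniform offsets in [1, n_bins-1]; undefined ratios redrawn
    valid <- which(abs(total - in_sums[-1]) > tol)
    if (length(valid) == 0)
      stop("cell ", trace$cell_ids[i],
           ": every circular shift leaves zero out-of-epoch activity")
    offs <- sample.int(n_bins - 1L, n_shifts, replace = TRUE)
    bad <- !(offs %in% valid)
    while (any(bad)) {
      offs[bad] <- sample.int(n_bins - 1L, sum(bad), replace = TRUE)
      bad <- !(offs %in% valid)
    }
    null <- ratio_of(in_sums[offs + 1L], total)
    cut[i] <- percentile_nearest_rank(null, percentile)
    member[i] <- !is.na(stat[i]) && stat[i] > cut[i]
  }
  structure(trace$cell_ids[member],
            statistic = stats::setNames(stat, trace$cell_ids),
            null_p95 = stats::setNames(cut, trace$cell_ids),
            flagged = trace$cell_ids[flagged])
}

#' Detect all condition ensembles of a session
#'
#' Applies one detection method to each condition's epoch set and returns
#' the combined assignment.
#'
#' @param trace a [trace_matrix()].
#' @param epochs_by_group named list: group label -> [epoch_set()].
#' @param method `"rank"` or `"statistical"`.
#' @param sd_mult,n_shifts,seed method parameters; for the statistical
#'   method each group's null uses a distinct seed derived from `seed`.
#' @return An [ensemble_assignment()].
#' @export
detect_ensembles <- function(trace, epochs_by_group, method = c("rank", "statistical"),
                             sd_mult = 1, n_shifts = 1000, seed = 1) {
  method <- match.arg(method)
  membership <- list()
  flagged <- integer()
  for (k in seq_along(epochs_by_group)) {
    g <- names(epochs_by_group)[k]
    if (method == "rank") {
      m <- detect_rank(trace, epochs_by_group[[k]], sd_mult = sd_mult)
    } else {
      m <- detect_statistical(trace, epochs_by_group[[k]], n_shifts = n_shifts,
                              seed = stage_seed(seed, k))
      flagged <- union(flagged, attr(m, "flagged"))
    }
    membership[[g]] <- as.integer(m)
  }
  ensemble_assignment(membership, method, trace$cell_ids,
                      thresholds = list(sd_mult = sd_mult, n_shifts = n_shifts),
                      flagged = flagged)
}

#' Recall-session ensembles (freezing / no-freezing cells)
#'
#' Applies the chosen detection method to the recall session with epochs
#' equal to the freezing bouts (`frz-recall` group) and to their
#' complement (`no-frz-recall` group).
#'
#' @param trace_recall the recall-session [trace_matrix()].
#' @param labels recall-session [freezing_labels()].
#' @param method `"rank"` or `"statistical"`.
#' @param ... passed to [detect_ensembles()].
#' @return An [ensemble_assignment()] with groups `frz-recall` and
#'   `no-frz-recall`.
#' @export
recall_groups <- function(trace_recall, labels, method = c("rank", "statistical"),
                          ...) {
  method <- match.arg(method)
  stopifnot(inherits(labels, "freezing_labels"))
  dur <- floor(ncol(trace_recall$values) / trace_recall$sample_rate)
  if (nrow(labels$bouts) == 0)
    stop("no freezing bouts in recall: frz-recall group undefined")
  frz <- epoch_intersect(labels$bouts, epoch_set("w", 0, dur))
  if (nrow(frz) == 0)
    stop("no freezing bouts in recall: frz-recall group undefined")
  no_frz <- epoch_complement(labels$bouts, dur)
  if (nrow(no_frz) == 0)
    stop("recall is entirely frozen: no-frz-recall group undefined")
  detect_ensembles(trace_recall,
                   list(`frz-recall` = frz, `no-frz-recall` = no_frz),
                   method = method, ...)
}

#' Mean closest-neighbor distance between cell groups
#'
#' For every cell of group X, the distance to its nearest cell of group Y
#' in the imaging field of view; only the smallest distance per X cell is
#' kept, and the mean over X is returned. The measure is asymmetric:
#' X to Y can differ from Y to X. When the groups share cells (or X = Y),
#' self-distances are excluded.
#'
#' @param positions data frame with columns `cell`, `x`, `y` (microns).
#' @param members_X,members_Y integer vectors of member cell ids
#'   (nonempty).
#' @return Mean nearest-neighbor distance in microns.
#' @examples
#' pos <- data.frame(cell = 1:2, x = c(0, 3), y = c(0, 4))
#' nearest_group_distance(pos, 1, 2)  # 5
#' @export
nearest_group_distance <- function(positions, members_X, members_Y) {
  stopifnot(all(c("cell", "x", "y") %in% names(positions)),
            !anyDuplicated(positions$cell))
  if (length(members_X) == 0 || length(members_Y) == 0)
    stop("both groups must be nonempty")
  if (!all(c(members_X, members_Y) %in% positions$cell))
    stop("group members missing from the position table")
  px <- positions[match(members_X, positions$cell), ]
  py <- positions[match(members_Y, positions$cell), ]
  d <- vapply(seq_len(nrow(px)), function(i) {
    dx <- py$x - px$x[i]; dy <- py$y - px$y[i]
    dd <- sqrt(dx^2 + dy^2)
    dd[py$cell == px$cell[i]] <- Inf   # exclude self
    min(dd)
  }, numeric(1))
  if (any(!is.finite(d)))
    stop("a cell of X has no distinct neighbor in Y")
  mean(d)
}

#' Read and write membership and position tables
#'
#' Membership TSV columns: `cell`, `group`, `method`. Position TSV
#' columns: `cell`, `x_um`, `y_um`.
#'
#' @param assignment an [ensemble_assignment()].
#' @param positions data frame with `cell`, `x`, `y`.
#' @param path file path.
#' @param header provenance lines written prefixed by `"# "`.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_membership <- function(assignment, path, header = character()) {
  stopifnot(inherits(assignment, "ensemble_assignment"))
  rows <- do.call(rbind, lapply(names(assignment$membership), function(g) {
    m <- assignment$membership[[g]]
    if (length(m) == 0) return(NULL)
    data.frame(cell = m, group = g, method = assignment$method)
  }))
  if (is.null(rows))
    rows <- data.frame(cell = integer(), group = character(), method = character())
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membership
#' @export
read_membership <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  split(as.integer(df$cell), df$group)
}

#' @rdname write_membership
#' @export
write_positions <- function(positions, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(data.frame(cell = positions$cell, x_um = positions$x,
                                y_um = positions$y),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membership
#' @export
read_positions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  data.frame(cell = as.integer(df$cell), x = df$x_um, y = df$y_um)
}
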