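#' Cross-session registration map
#'
#' An injective correspondence between cell ids of two imaging sessions of
#' the same animal, as produced by cross-session footprint registration.
#'
#' @param cell_A,cell_B integer id vectors of equal length; no id may
#'   appear twice on either side.
#' @return A data frame of class `"registration_map"` with columns
#'   `cell_A`, `cell_B`.
#' @export
registration_map <- function(cell_A = integer(), cell_B = integer()) {
  stopifnot(length(cell_A) == length(cell_B))
  if (anyDuplicated(cell_A) || anyDuplicated(cell_B))
    stop("registration map must be injective on both sides")
  out <- data.frame(cell_A = as.integer(cell_A), cell_B = as.integer(cell_B))
  class(out) <- c("registration_map", "data.frame")
  out
}

#' @export
print.registration_map <- function(x, ...) {
  cat(sprintf("<registration_map> %d tracked cell pair(s)\n", nrow(x)))
  invisible(x)
}

#' Relative reactivation of a cell group across sessions
#'
#' The percentage of a group's cells tracked into the second (recall)
#' session, divided by the overall percentage of first-session cells
#' tracked: `R = (tracked_in_group / group_size) /
#' (tracked_overall / n_cells_FC)`. Chance level — a group tracked at the
#' overall rate — corresponds to a relative value of 1. For instance, with
#' 100 cells of which 70 are tracked (70%) and a 10-cell group of which 5
#' are tracked (50%), R = 50%/70% = 0.71.
#'
#' @param map a [registration_map()] from the FC session to the recall
#'   session.
#' @param group integer vector of FC member cell ids (nonempty).
#' @param n_cells_FC number of cells detected in the FC session (> 0).
#' @return The dimensionless relative value (>= 0).
#' @examples
#' m <- registration_map(1:70, 1:70)
#' relative_reactivation(m, c(1:5, 96:100), 100)  # 0.714...
#' @export
relative_reactivation <- function(map, group, n_cells_FC) {
  stopifnot(inherits(map, "registration_map"), n_cells_FC > 0)
  group <- unique(group)
  if (length(group) == 0) stop("group is empty")
  tracked_overall <- nrow(map)
  if (tracked_overall == 0) stop("no cells tracked overall: ratio undefined")
  tracked_in_group <- sum(group %in% map$cell_A)
  (tracked_in_group / length(group)) / (tracked_overall / n_cells_FC)
}

#' Recall-session activity of tracked FC groups
#'
#' For every FC-defined group, follows its tracked members into the recall
#' session's event raster and reports: tracked count, mean event rate over
#' the whole recall session, event rate restricted to freezing-bout bins
#' and to non-freezing bins, and the in/out ratio. Division by a zero
#' out-of-bout rate is flagged (`ratio_defined = FALSE`), never silently
#' dropped; groups with no tracked members yield a row of `NA` markers.
#'
#' @param map a [registration_map()] (FC id -> recall id).
#' @param membership named list: group -> FC member cell ids.
#' @param raster_recall recall-session `"event_raster"` (ids on the recall
#'   side of the map).
#' @param labels_recall recall-session [freezing_labels()].
#' @return Data frame of class `"reactivation_report"`: one row per group
#'   with columns `group`, `group_size`, `tracked`, `rate`, `rate_in_frz`,
#'   `rate_out_frz`, `ratio`, `ratio_defined`.
#' @export
recall_activity <- function(map, membership, raster_recall, labels_recall) {
  stopifnot(inherits(map, "registration_map"),
            inherits(raster_recall, "event_raster"),
            inherits(labels_recall, "freezing_labels"))
  n_bins <- ncol(raster_recall$events)
  frz_bin <- in_epochs(seq_len(n_bins) - 0.5, labels_recall$bouts)
  rows <- lapply(names(membership), function(g) {
    fc_cells <- unique(membership[[g]])
    recall_ids <- map$cell_B[map$cell_A %in% fc_cells]
    idx <- match(recall_ids, raster_recall$cell_ids)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0)
      return(data.frame(group = g, group_size = length(fc_cells), tracked = 0L,
                        rate = NA_real_, rate_in_frz = NA_real_,
                        rate_out_frz = NA_real_, ratio = NA_real_,
                        ratio_defined = FALSE))
    ev <- raster_recall$events[idx, , drop = FALSE]
    rate <- mean(ev)
    rin <- if (any(frz_bin)) mean(ev[, frz_bin, drop = FALSE]) else NA_real_
    rout <- if (any(!frz_bin)) mean(ev[, !frz_bin, drop = FALSE]) else NA_real_
    defined <- !is.na(rin) && !is.na(rout) && rout > 0
    data.frame(group = g, group_size = length(fc_cells),
               tracked = length(idx), rate = rate, rate_in_frz = rin,
               rate_out_frz = rout,
               ratio = if (defined) rin / rout else NA_real_,
               ratio_defined = defined)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reactivation_report", "data.frame")
  out
}

#' Composition of tracked FC groups in the recall freezing ensemble
#'
#' For each FC group, the percentage of its tracked members that belong to
#' the recall session's freezing ensemble (frz-recall members):
#' `100 * |tracked members that are frz-recall| / |tracked members|`.
#'
#' @param map a [registration_map()] (FC id -> recall id).
#' @param membership_FC named list: group -> FC member cell ids.
#' @param frz_recall_members recall-side cell ids of the frz-recall group.
#' @return Named numeric vector of percentages (`NA` for groups with zero
#'   tracked members).
#' @export
recall_group_composition <- function(map, membership_FC, frz_recall_members) {
  stopifnot(inherits(map, "registration_map"))
  out <- vapply(names(membership_FC), function(g) {
    fc_cells <- unique(membership_FC[[g]])
    tracked_B <- map$cell_B[map$cell_A %in% fc_cells]
    if (length(tracked_B) == 0) return(NA_real_)
    100 * sum(tracked_B %in% frz_recall_members) / length(tracked_B)
  }, numeric(1))
  out
}

#' Read and write registration maps
#'
#' TSV with columns `cell_A`, `cell_B` and optional `#`-prefixed header
#' lines.
#'
#' @param map a [registration_map()].
#' @param path file path.
#' @param header provenance lines written prefixed by `"# "`.
#' @return `read_registration` returns a [registration_map()];
#'   `write_registration` returns `path` invisibly.
#' @export
write_registration <- function(map, path, header = character()) {
  stopifnot(inherits(map, "registration_map"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(as.data.frame(unclass(map)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  registration_map(df$cell_A, df$cell_B)
}
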