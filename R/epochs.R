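#' Labeled half-open time intervals
#'
#' An epoch set is the package's representation of labeled time intervals
#' within a session: shock deliveries, light-delivery (tagging) windows,
#' freezing bouts. Every interval is half-open, `[start, end)`, in seconds
#' from session start.
#'
#' @param label character vector of epoch labels.
#' @param start,end numeric vectors of interval bounds in seconds;
#'   `start < end` elementwise.
#' @return A data frame of class `"epoch_set"` with columns `label`,
#'   `start`, `end`, sorted by `start`.
#' @examples
#' epoch_set("shock", c(120, 180, 240, 300), c(122, 182, 242, 302))
#' @export
epoch_set <- function(label = character(), start = numeric(), end = numeric()) {
  label <- as.character(label)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(label), length(start), length(end))
  if (n > 0) {
    label <- rep_len(label, n)
    stopifnot(length(start) == n, length(end) == n)
    if (any(!is.finite(start)) || any(!is.finite(end)))
      stop("epoch bounds must be finite")
    if (any(end <= start))
      stop("every epoch must satisfy start < end (zero-length epochs are not allowed)")
  }
  out <- data.frame(label = label, start = start, end = end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epoch_set", "data.frame")
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s), total %.3f s\n",
              nrow(x), epoch_duration(x)))
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}

as_epoch_set <- function(x) {
  if (inherits(x, "epoch_set")) return(x)
  stopifnot(is.data.frame(x), all(c("label", "start", "end") %in% names(x)))
  epoch_set(x$label, x$start, x$end)
}

#' Total duration covered by an epoch set
#'
#' @param epochs an [epoch_set()]. Intervals are assumed non-overlapping;
#'   the value is the plain sum of interval lengths.
#' @return Total length in seconds.
#' @export
epoch_duration <- function(epochs) {
  epochs <- as_epoch_set(epochs)
  if (nrow(epochs) == 0) return(0)
  sum(epochs$end - epochs$start)
}

#' Complement of an epoch set within a session
#'
#' Returns the gaps of `epochs` within `[t0, duration)`, i.e. the times not
#' covered by any interval. Overlapping input intervals are merged first.
#'
#' @param epochs an [epoch_set()].
#' @param duration session duration in seconds (upper bound of the complement).
#' @param t0 lower bound of the complement window (default 0).
#' @param label label given to the complement intervals.
#' @return An [epoch_set()].
#' @export
epoch_complement <- function(epochs, duration, t0 = 0, label = "complement") {
  epochs <- merge_epochs(as_epoch_set(epochs))
  stopifnot(duration > t0)
  keep <- epochs$end > t0 & epochs$start < duration
  epochs <- epochs[keep, , drop = FALSE]
  starts <- c(t0, pmin(pmax(epochs$end, t0), duration))
  ends <- c(pmin(pmax(epochs$start, t0), duration), duration)
  ok <- ends > starts
  epoch_set(label, starts[ok], ends[ok])
}

#' Intersection of two epoch sets
#'
#' @param a,b [epoch_set()] objects.
#' @param label label for the resulting intervals (default: labels of `a`).
#' @return An [epoch_set()] holding every nonempty pairwise intersection.
#' @export
epoch_intersect <- function(a, b, label = NULL) {
  a <- as_epoch_set(a); b <- as_epoch_set(b)
  out_label <- character(); out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    ok <- e > s
    if (any(ok)) {
      out_label <- c(out_label, rep(if (is.null(label)) a$label[i] else label, sum(ok)))
      out_s <- c(out_s, s[ok]); out_e <- c(out_e, e[ok])
    }
  }
  epoch_set(out_label, out_s, out_e)
}

# merge overlapping/abutting intervals (labels collapsed)
merge_epochs <- function(epochs, label = NULL) {
  epochs <- as_epoch_set(epochs)
  if (nrow(epochs) <= 1) return(epochs)
  s <- epochs$start; e <- epochs$end
  ms <- s[1]; me <- e[1]; out_s <- numeric(); out_e <- numeric()
  for (i in seq.int(2L, length(s))) {
    if (s[i] <= me) me <- max(me, e[i]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  epoch_set(if (is.null(label)) epochs$label[1] else label, out_s, out_e)
}

#' Membership of time points in an epoch set
#'
#' @param t numeric vector of times in seconds.
#' @param epochs an [epoch_set()].
#' @return Logical vector: `TRUE` where `t` falls inside some `[start, end)`.
#' @export
in_epochs <- function(t, epochs) {
  epochs <- as_epoch_set(epochs)
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(epochs)))
    out <- out | (t >= epochs$start[i] & t < epochs$end[i])
  out
}

#' Read and write epoch tables
#'
#' Epoch tables are TSV files with columns `label`, `start_s`, `end_s`
#' (half-open seconds from session start) and optional `#`-prefixed
#' provenance header lines.
#'
#' @param epochs an [epoch_set()].
#' @param path file path.
#' @param header character vector of provenance lines to prepend, each
#'   written prefixed by `"# "`.
#' @return `read_epochs` returns an [epoch_set()]; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path, header = character()) {
  epochs <- as_epoch_set(epochs)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  writeLines("label\tstart_s\tend_s", con)
  if (nrow(epochs) > 0)
    writeLines(sprintf("%s\t%.6f\t%.6f", epochs$label, epochs$start, epochs$end), con)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  epoch_set(df$label, df$start_s, df$end_s)
}
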