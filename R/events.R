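#' Fluorescence trace matrix
#'
#' Container for extracted single-cell fluorescence traces: one row per
#' cell, one column per sample, with the imaging sample rate.
#'
#' @param values numeric matrix, cells x samples, finite, at least 60
#'   samples per cell.
#' @param sample_rate samples per second (>= 1).
#' @param cell_ids integer cell ids (default `1:n_cells`).
#' @return An object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(values, sample_rate, cell_ids = seq_len(nrow(values))) {
  stopifnot(is.matrix(values), sample_rate >= 1,
            length(cell_ids) == nrow(values), !anyDuplicated(cell_ids))
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (ncol(values) < 60) stop("traces must hold at least 60 samples")
  structure(list(values = values, sample_rate = sample_rate,
                 cell_ids = as.integer(cell_ids)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              ncol(x$values) / x$sample_rate))
  invisible(x)
}

# 1-s non-overlapping bin means; trailing partial window dropped.
# Sample s (1-based) covers [(s-1)/rate, s/rate); it belongs to bin
# floor(midpoint) + 1.
bin_trace <- function(values, sample_rate) {
  n_samples <- ncol(values)
  n_bins <- floor(n_samples / sample_rate)
  if (n_bins < 1) stop("trace shorter than one 1-s bin")
  mid <- (seq_len(n_samples) - 0.5) / sample_rate
  bin_of <- floor(mid) + 1L
  keep <- bin_of <= n_bins
  g <- factor(bin_of[keep], levels = seq_len(n_bins))
  t(apply(values[, keep, drop = FALSE], 1, function(r) tapply(r, g, mean)))
}

#' Bin traces into 1-s windows and z-score with a 2-SD floor
#'
#' Each cell's trace is averaged in non-overlapping 1-s windows (trailing
#' partial window dropped), z-scored against its own binned mean and
#' population SD (divisor n), and thresholded: bins below `z_cut` standard
#' deviations are set to 0, surviving bins keep their z value. This removes
#' activity below 2 SD and makes downstream event detection invariant to
#' any positive rescaling of the raw trace. Zero-variance cells yield an
#' all-zero row and are flagged.
#'
#' @param trace a [trace_matrix()].
#' @param z_cut threshold in SD units (default 2).
#' @return A list of class `"binned_zscores"`: `values` (cells x bins,
#'   thresholded z), `bin_width` (1 s), `cell_ids`, and `flagged`
#'   (cell ids with zero binned variance).
#' @export
bin_and_zscore <- function(trace, z_cut = 2) {
  stopifnot(inherits(trace, "trace_matrix"))
  binned <- bin_trace(trace$values, trace$sample_rate)
  mu <- rowMeans(binned)
  sdp <- sqrt(rowMeans((binned - mu)^2))   # population SD (divisor n)
  flagged <- trace$cell_ids[sdp == 0]
  z <- (binned - mu) / ifelse(sdp == 0, 1, sdp)
  z[sdp == 0, ] <- 0
  z[z < z_cut] <- 0
  structure(list(values = z, bin_width = 1, cell_ids = trace$cell_ids,
                 flagged = flagged),
            class = "binned_zscores")
}

#' Detect calcium events from thresholded z-scores
#'
#' A bin is a calcium event when its thresholded z value is a strict local
#' maximum: greater than both neighbors (boundary bins are compared to
#' their single neighbor) and itself surviving the threshold. Plateaus of
#' equal surviving values yield no event under strict inequality. The
#' result is the binary event raster: 1 for a second with at least one
#' event, 0 otherwise.
#'
#' @param z a `"binned_zscores"` object from [bin_and_zscore()].
#' @return An object of class `"event_raster"`: `events` (cells x bins,
#'   0/1 integer), `bin_width`, `cell_ids`.
#' @export
detect_events <- function(z) {
  stopifnot(inherits(z, "binned_zscores"))
  v <- z$values
  n <- ncol(v)
  left <- cbind(-Inf, v[, -n, drop = FALSE])
  right <- cbind(v[, -1, drop = FALSE], -Inf)
  ev <- (v > 0) & (v > left) & (v > right)
  structure(list(events = matrix(as.integer(ev), nrow = nrow(v),
                                 dimnames = dimnames(v)),
                 bin_width = z$bin_width, cell_ids = z$cell_ids),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d cells x %d 1-s bins, %.3f events/s overall\n",
              nrow(x$events), ncol(x$events), mean(x$events)))
  invisible(x)
}

#' Construct an event raster directly
#'
#' @param events binary matrix, cells x 1-s bins.
#' @param cell_ids integer cell ids.
#' @return An `"event_raster"` object.
#' @export
event_raster <- function(events, cell_ids = seq_len(nrow(events))) {
  stopifnot(is.matrix(events), all(events %in% c(0, 1)),
            length(cell_ids) == nrow(events))
  structure(list(events = matrix(as.integer(events), nrow = nrow(events)),
                 bin_width = 1, cell_ids = as.integer(cell_ids)),
            class = "event_raster")
}

#' Per-cell event rates
#'
#' Overall cell activity: the average number of calcium events per second,
#' i.e. the mean of each cell's row of the binary event raster.
#'
#' @param raster an `"event_raster"`.
#' @return Named numeric vector of events/s, one per cell.
#' @export
event_rate <- function(raster) {
  stopifnot(inherits(raster, "event_raster"), ncol(raster$events) > 0)
  stats::setNames(rowMeans(raster$events), raster$cell_ids)
}

#' Read and write trace matrices and event rasters
#'
#' Traces are written as TSV with a `# sample_rate:` header line, a
#' `cell` id column and one column per sample. Rasters use the same layout
#' with 0/1 values.
#'
#' @param trace a [trace_matrix()]; `raster` an `"event_raster"`.
#' @param path file path.
#' @param header extra provenance lines, written prefixed by `"# "`.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_trace_matrix <- function(trace, path, header = character()) {
  stopifnot(inherits(trace, "trace_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c(sprintf("sample_rate: %g", trace$sample_rate), header))
    writeLines(paste("#", h), con)
  utils::write.table(data.frame(cell = trace$cell_ids, trace$values),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_matrix
#' @export
read_trace_matrix <- function(path) {
  first <- readLines(path, n = 10)
  m <- regmatches(first, regexec("^# sample_rate: ([0-9.]+)", first))
  fr <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
  if (length(fr) == 0) stop("sample_rate header not found")
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#")
  trace_matrix(as.matrix(df[, -1, drop = FALSE]), as.numeric(fr[1]),
               cell_ids = df[[1]])
}

#' @rdname write_trace_matrix
#' @export
write_raster <- function(raster, path, header = character()) {
  stopifnot(inherits(raster, "event_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(data.frame(cell = raster$cell_ids, raster$events),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_matrix
#' @export
read_raster <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#")
  event_raster(as.matrix(df[, -1, drop = FALSE]), cell_ids = df[[1]])
}
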