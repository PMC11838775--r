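#' Pose track container
#'
#' A pose track holds frame-by-frame 2-D coordinates (in cm) of a fixed set
#' of tracked body parts, as produced by markerless pose estimation of a
#' top-down video. The default part set is the ten parts used for
#' closed-loop freezing detection: nose, neck, both ears, both sides,
#' middle back, both hindlegs, tail base.
#'
#' @param positions numeric array `frames x parts x 2` (x, y in cm), or a
#'   `frames x (2*parts)` matrix with x/y columns interleaved per part.
#' @param frame_rate frames per second (> 0).
#' @param part_names character vector naming the parts.
#' @return An object of class `"pose_track"`.
#' @export
pose_track <- function(positions, frame_rate,
                       part_names = default_body_parts()) {
  if (is.matrix(positions)) {
    np <- ncol(positions) / 2
    stopifnot(np == as.integer(np))
    positions <- array(positions[, order(rep(seq_len(np), 2))],
                       dim = c(nrow(positions), np, 2))
  }
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 2, frame_rate > 0)
  if (any(!is.finite(positions))) stop("pose coordinates must be finite")
  if (length(part_names) != dim(positions)[2])
    stop("part_names length must match the number of tracked parts")
  dimnames(positions) <- list(NULL, part_names, c("x", "y"))
  structure(list(positions = positions, frame_rate = frame_rate,
                 part_names = part_names),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames x %d parts @ %g Hz (%.1f s)\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_rate,
              dim(x$positions)[1] / x$frame_rate))
  invisible(x)
}

#' @rdname pose_track
#' @export
default_body_parts <- function() {
  c("nose", "neck", "left_ear", "right_ear", "left_side", "right_side",
    "middle_back", "left_hindleg", "right_hindleg", "tail_base")
}

#' Per-part instantaneous speeds
#'
#' Speed of part p at frame f is the Euclidean distance it moved since the
#' previous frame divided by the frame interval (i.e. multiplied by the
#' frame rate). The first frame has no predecessor; its speed is defined
#' as 0, which is conservative for freezing classification.
#'
#' @param track a [pose_track()] with at least 2 frames.
#' @return An object of class `"speed_matrix"`: list with `speeds`
#'   (`frames x parts`, cm/s) and `frame_rate`.
#' @export
compute_speeds <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  pos <- track$positions
  n <- dim(pos)[1]
  if (n < 2) stop("a pose track needs at least 2 frames to define speeds")
  dx <- pos[-1, , 1, drop = FALSE] - pos[-n, , 1, drop = FALSE]
  dy <- pos[-1, , 2, drop = FALSE] - pos[-n, , 2, drop = FALSE]
  sp <- sqrt(dx^2 + dy^2)[, , 1] * track$frame_rate
  if (is.null(dim(sp))) sp <- matrix(sp, nrow = n - 1)
  speeds <- rbind(rep(0, dim(pos)[2]), sp)
  colnames(speeds) <- track$part_names
  structure(list(speeds = speeds, frame_rate = track$frame_rate),
            class = "speed_matrix")
}

#' Freezing labels
#'
#' Couples a per-frame boolean freezing vector with its bout representation:
#' maximal runs of frozen frames converted to half-open second intervals,
#' with frame f covering `[f/rate, (f+1)/rate)` (0-based frames).
#'
#' @param per_frame logical vector, `TRUE` for frozen frames.
#' @param frame_rate frames per second.
#' @return An object of class `"freezing_labels"` with elements `per_frame`,
#'   `frame_rate` and `bouts` (an [epoch_set()] labeled `"freezing"`).
#' @export
freezing_labels <- function(per_frame, frame_rate) {
  stopifnot(is.logical(per_frame), frame_rate > 0, !anyNA(per_frame))
  runs <- true_runs(per_frame)
  bouts <- epoch_set(rep("freezing", nrow(runs)),
                     runs[, "start"] / frame_rate, runs[, "end"] / frame_rate)
  structure(list(per_frame = per_frame, frame_rate = frame_rate, bouts = bouts),
            class = "freezing_labels")
}

#' @export
print.freezing_labels <- function(x, ...) {
  cat(sprintf("<freezing_labels> %d frames @ %g Hz: %d bout(s), %.1f%% frozen\n",
              length(x$per_frame), x$frame_rate, nrow(x$bouts),
              100 * mean(x$per_frame)))
  invisible(x)
}

#' Online (closed-loop) freezing classification
#'
#' Reproduces the closed-loop criterion used for behavior-triggered tagging:
#' a body part is immobile on a frame when its speed is below
#' `immobility_threshold` (0.5 cm/s), and the frame is classified as
#' freezing when at least `min_immobile_parts` of the tracked parts are
#' immobile. The tagging protocol uses two variants of this rule: 7-of-10
#' parts for freezing-tag sessions and 6-of-10 for no-freezing-tag sessions,
#' so that freezing tags contain as much true freezing as possible and
#' no-freezing tags as little as possible.
#'
#' @param speeds a `"speed_matrix"` from [compute_speeds()].
#' @param immobility_threshold speed threshold in cm/s (default 0.5).
#' @param min_immobile_parts minimum number of immobile parts for a frame
#'   to count as freezing; must lie in `[1, n_parts]`.
#' @return A [freezing_labels()] object.
#' @export
classify_freezing_online <- function(speeds, immobility_threshold = 0.5,
                                     min_immobile_parts = 7) {
  stopifnot(inherits(speeds, "speed_matrix"))
  np <- ncol(speeds$speeds)
  if (min_immobile_parts < 1 || min_immobile_parts > np)
    stop("min_immobile_parts must lie in [1, number of parts]")
  immobile <- speeds$speeds < immobility_threshold
  frozen <- rowSums(immobile) >= min_immobile_parts
  freezing_labels(frozen, speeds$frame_rate)
}

#' Parameters of the post-hoc freezing classifier
#'
#' The five parameters of the windowed velocity/head-angle freezing
#' classifier applied to recorded videos: a centroid-speed threshold, a
#' head-direction change threshold, a centered window width, the minimum
#' number of qualifying frames within the window, and a minimum bout
#' duration. Defaults are the values used for 30 fps recordings.
#'
#' @param velocity_threshold centroid speed threshold, cm/s.
#' @param angle_threshold per-frame head-direction change threshold, degrees.
#' @param window_width centered window width, frames.
#' @param count_threshold qualifying frames required within the window.
#' @param min_duration minimum bout duration, seconds.
#' @return A list of class `"posthoc_params"`.
#' @export
posthoc_params <- function(velocity_threshold = 0.3, angle_threshold = 12,
                           window_width = 32, count_threshold = 10,
                           min_duration = 0.5) {
  stopifnot(velocity_threshold > 0, angle_threshold > 0, window_width > 0,
            count_threshold > 0, min_duration > 0,
            count_threshold <= window_width)
  structure(list(velocity_threshold = velocity_threshold,
                 angle_threshold = angle_threshold,
                 window_width = as.integer(window_width),
                 count_threshold = as.integer(count_threshold),
                 min_duration = min_duration),
            class = "posthoc_params")
}

#' Post-hoc freezing classification
#'
#' Windowed velocity + head-movement classifier. A frame qualifies when
#' its centroid speed (speed of the mean position of all parts) is below
#' `velocity_threshold` and its per-frame head-direction change (angle of
#' the nose-to-neck vector relative to the previous frame) is below
#' `angle_threshold` degrees. A frame is a freezing candidate when it
#' qualifies itself and at least `count_threshold` frames qualify inside
#' the centered window of `window_width` frames around it (truncated at
#' the track edges) — the window rescues brief tracking glitches inside a
#' bout without dilating the bout into the surrounding motion. Candidate
#' runs shorter than `min_duration` are discarded.
#'
#' @param track a [pose_track()]; must contain `nose` and `neck` parts and
#'   be at least `window_width` frames long.
#' @param params a [posthoc_params()] object.
#' @return A [freezing_labels()] object.
#' @export
classify_freezing_posthoc <- function(track, params = posthoc_params()) {
  stopifnot(inherits(track, "pose_track"), inherits(params, "posthoc_params"))
  pos <- track$positions
  n <- dim(pos)[1]
  if (n < params$window_width)
    stop("track shorter than the classifier window")
  if (!all(c("nose", "neck") %in% track$part_names))
    stop("post-hoc classifier needs 'nose' and 'neck' parts")

  centroid <- cbind(rowMeans(pos[, , 1]), rowMeans(pos[, , 2]))
  cs <- c(0, sqrt(rowSums(diff(centroid)^2)) * track$frame_rate)

  hv <- pos[, "nose", ] - pos[, "neck", ]          # head vector per frame
  ang <- atan2(hv[, 2], hv[, 1])
  dang <- c(0, abs(diff(ang)))
  dang <- pmin(dang, 2 * pi - dang) * 180 / pi     # wrapped, degrees

  qual <- (cs < params$velocity_threshold) & (dang < params$angle_threshold)
  half <- params$window_width %/% 2
  cq <- cumsum(c(0, qual))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) - half + params$window_width - 1L, n)
  counts <- cq[hi + 1L] - cq[lo]
  candidate <- qual & counts >= params$count_threshold

  min_frames <- ceiling(params$min_duration * track$frame_rate)
  r <- rle(candidate)
  r$values <- r$values & (r$lengths >= min_frames)
  freezing_labels(inverse.rle(r), track$frame_rate)
}

#' Per-epoch freezing percentages and delta-freezing
#'
#' Computes, for each epoch, the percentage of its duration spent frozen
#' (from the bout representation, in continuous time), and the
#' delta-freezing summary used to quantify light-driven freezing: mean
#' percentage over epochs labeled `"ON"` minus mean percentage over epochs
#' labeled `"OFF"`.
#'
#' @param labels a [freezing_labels()] object.
#' @param epochs an [epoch_set()]; epochs labeled `"ON"`/`"OFF"` enter the
#'   delta.
#' @return A list with `per_epoch` (data frame `label`, `start`, `end`,
#'   `pct_freezing`) and `delta_freezing` (`NA` when either label set is
#'   absent).
#' @export
freezing_metrics <- function(labels, epochs) {
  stopifnot(inherits(labels, "freezing_labels"))
  epochs <- as_epoch_set(epochs)
  if (nrow(epochs) == 0) stop("no epochs supplied")
  dur <- length(labels$per_frame) / labels$frame_rate
  if (any(epochs$end > dur + 1e-9))
    stop("epochs extend beyond the labeled track")
  pct <- vapply(seq_len(nrow(epochs)), function(i) {
    e1 <- epochs[i, , drop = FALSE]
    frozen <- epoch_duration(epoch_intersect(labels$bouts, e1))
    100 * frozen / (e1$end - e1$start)
  }, numeric(1))
  per_epoch <- data.frame(label = epochs$label, start = epochs$start,
                          end = epochs$end, pct_freezing = pct,
                          stringsAsFactors = FALSE)
  on <- pct[epochs$label == "ON"]; off <- pct[epochs$label == "OFF"]
  delta <- if (length(on) > 0 && length(off) > 0) mean(on) - mean(off) else NA_real_
  list(per_epoch = per_epoch, delta_freezing = delta)
}

#' Read and write pose tracks
#'
#' Wide tabular layout: a `frame` column followed by `<part>_x`, `<part>_y`
#' coordinate columns per tracked body part (the usual flattened
#' pose-estimation export). Coordinates are multiplied by `cm_per_unit` at
#' load so all downstream thresholds operate in cm/s.
#'
#' @param track a [pose_track()].
#' @param path file path (TSV).
#' @param frame_rate frames per second of the recording.
#' @param cm_per_unit pixel-to-cm calibration scalar applied at load.
#' @param header provenance lines written prefixed by `"# "`.
#' @return `read_pose_track` returns a [pose_track()]; `write_pose_track`
#'   returns `path` invisibly.
#' @export
write_pose_track <- function(track, path, header = character()) {
  stopifnot(inherits(track, "pose_track"))
  pos <- track$positions
  wide <- do.call(cbind, lapply(seq_along(track$part_names), function(p)
    cbind(pos[, p, 1], pos[, p, 2])))
  colnames(wide) <- as.vector(rbind(paste0(track$part_names, "_x"),
                                    paste0(track$part_names, "_y")))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c(sprintf("frame_rate: %g", track$frame_rate), header))
    writeLines(paste("#", h), con)
  utils::write.table(data.frame(frame = seq_len(nrow(wide)) - 1L, wide,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_track
#' @export
read_pose_track <- function(path, frame_rate = NULL, cm_per_unit = 1) {
  first <- readLines(path, n = 20)
  if (is.null(frame_rate)) {
    m <- regmatches(first, regexec("^# frame_rate: ([0-9.]+)", first))
    fr <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    if (length(fr) == 0) stop("frame_rate not given and not found in header")
    frame_rate <- as.numeric(fr[1])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  xcols <- grep("_x$", names(df), value = TRUE)
  parts <- sub("_x$", "", xcols)
  pos <- array(0, dim = c(nrow(df), length(parts), 2))
  for (p in seq_along(parts)) {
    pos[, p, 1] <- df[[paste0(parts[p], "_x")]] * cm_per_unit
    pos[, p, 2] <- df[[paste0(parts[p], "_y")]] * cm_per_unit
  }
  pose_track(pos, frame_rate, parts)
}

#' Write freezing labels
#'
#' Writes the bout table as an epoch TSV and, optionally, the per-frame
#' boolean column.
#'
#' @param labels a [freezing_labels()] object.
#' @param path bout epoch TSV path.
#' @param frames_path optional path for the per-frame 0/1 column.
#' @return `path`, invisibly.
#' @export
write_freezing_labels <- function(labels, path, frames_path = NULL) {
  stopifnot(inherits(labels, "freezing_labels"))
  write_epochs(labels$bouts, path,
               header = sprintf("frame_rate: %g", labels$frame_rate))
  if (!is.null(frames_path))
    writeLines(c("frozen", as.integer(labels$per_frame)), frames_path)
  invisible(path)
}
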