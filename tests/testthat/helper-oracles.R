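# Independent rule-application oracles and fixture builders.
# These deliberately use naive frame-by-frame loops, separate from the
# package's vectorized implementations.

# build a pose_track whose per-part speeds equal `speed_mat` (frames x parts):
# each part moves along x by speed/frame_rate per frame
track_from_speeds <- function(speed_mat, frame_rate = 15) {
  n <- nrow(speed_mat); p <- ncol(speed_mat)
  pos <- array(0, dim = c(n, p, 2))
  for (j in seq_len(p)) {
    pos[, j, 1] <- cumsum(c(0, speed_mat[-1, j] / frame_rate)) + j  # offset per part
    pos[, j, 2] <- j
  }
  pose_track(pos, frame_rate, part_names = default_body_parts()[seq_len(p)])
}

# direct online freezing rule: loop over frames and parts
oracle_freeze_online <- function(speed_mat, threshold, min_parts) {
  n <- nrow(speed_mat)
  out <- logical(n)
  for (f in seq_len(n)) {
    k <- 0
    for (p in seq_len(ncol(speed_mat)))
      if (speed_mat[f, p] < threshold) k <- k + 1
    out[f] <- k >= min_parts
  }
  out
}

# direct post-hoc rule: explicit per-frame window scan + min-duration pass
oracle_freeze_posthoc <- function(track, params) {
  pos <- track$positions
  n <- dim(pos)[1]
  fr <- track$frame_rate
  cx <- apply(pos[, , 1], 1, mean); cy <- apply(pos[, , 2], 1, mean)
  cs <- numeric(n)
  for (f in 2:n) cs[f] <- sqrt((cx[f] - cx[f - 1])^2 + (cy[f] - cy[f - 1])^2) * fr
  nose <- which(track$part_names == "nose"); neck <- which(track$part_names == "neck")
  ang <- atan2(pos[, nose, 2] - pos[, neck, 2], pos[, nose, 1] - pos[, neck, 1])
  dang <- numeric(n)
  for (f in 2:n) {
    d <- abs(ang[f] - ang[f - 1])
    dang[f] <- min(d, 2 * pi - d) * 180 / pi
  }
  qual <- cs < params$velocity_threshold & dang < params$angle_threshold
  half <- params$window_width %/% 2
  cand <- logical(n)
  for (f in seq_len(n)) {
    lo <- max(f - half, 1); hi <- min(f - half + params$window_width - 1, n)
    cand[f] <- qual[f] && sum(qual[lo:hi]) >= params$count_threshold
  }
  # drop runs shorter than min_duration
  min_frames <- ceiling(params$min_duration * fr)
  out <- logical(n)
  f <- 1
  while (f <= n) {
    if (cand[f]) {
      g <- f
      while (g <= n && cand[g]) g <- g + 1
      if (g - f >= min_frames) out[f:(g - 1)] <- TRUE
      f <- g
    } else f <- f + 1
  }
  out
}

# small helper: constant-rows trace (each cell's trace is its constant value)
constant_trace <- function(values, n_samples = 60, sample_rate = 1) {
  trace_matrix(matrix(rep(values, n_samples), nrow = length(values)), sample_rate)
}

# freezing labels from an explicit per-frame logical vector
labels_from_frames <- function(frames, frame_rate = 15) {
  freezing_labels(as.logical(frames), frame_rate)
}
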