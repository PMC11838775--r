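#' Synthetic session specification
#'
#' Parameters of one simulated miniscope/behavior session: duration,
#' behavior-camera frame rate, imaging sample rate, cell count, shock
#' times and seed. Defaults mirror a standard dorsal-CA1 fear-conditioning
#' recording: 15 fps closed-loop tracking, 20 Hz trace sampling, 90 cells
#' (the typical per-session yield).
#'
#' @param duration_s session duration in seconds (> 0).
#' @param frame_rate_behavior behavior frames per second.
#' @param sample_rate_trace imaging samples per second.
#' @param n_cells number of cells (>= 1).
#' @param shock_onsets_s strictly increasing shock onset times.
#' @param shock_duration_s shock duration (default 2 s).
#' @param context_label free-form context token.
#' @param seed integer seed; all randomness of the generators derives
#'   from it.
#' @return A list of class `"session_spec"`.
#' @export
session_spec <- function(duration_s, frame_rate_behavior = 15,
                         sample_rate_trace = 20, n_cells = 90,
                         shock_onsets_s = numeric(), shock_duration_s = 2,
                         context_label = "ctxA", seed = 1) {
  stopifnot(duration_s > 0, n_cells >= 1, frame_rate_behavior > 0,
            sample_rate_trace >= 1)
  if (length(shock_onsets_s) > 0) {
    if (is.unsorted(shock_onsets_s, strictly = TRUE))
      stop("shock onsets must be strictly increasing")
    if (any(shock_onsets_s + shock_duration_s > duration_s))
      stop("shocks must end within the session")
  }
  structure(list(duration_s = duration_s,
                 frame_rate_behavior = frame_rate_behavior,
                 sample_rate_trace = sample_rate_trace,
                 n_cells = as.integer(n_cells),
                 shock_onsets_s = shock_onsets_s,
                 shock_duration_s = shock_duration_s,
                 context_label = context_label, seed = as.integer(seed)),
            class = "session_spec")
}

#' Ground truth of a synthetic session
#'
#' Planted structure underlying a synthetic session: which cells belong to
#' which period-tuned ensemble, how strongly tuning elevates their event
#' rate, the background event rate, cross-session tracking probability and
#' the freezing dwell process. Planted groups are pairwise disjoint by
#' construction; remaining cells are background.
#'
#' Defaults define the package's reference conditions: four 14-cell
#' ensembles among 90 cells (14/90 is the fraction the mean-plus-one-SD
#' ranking rule captures for a normal activity distribution), in-period
#' gain 10 over a 0.02 events/s baseline (a 40-s condition window then
#' holds ~8 expected tuned events against 0.8 background, enough for
#' reliable rank separation), 70% tracking, freezing bouts of mean 4 s
#' separated by mean 16 s (20% stationary freezing), jGCaMP8f-like 0.5-s
#' calcium decay and additive Gaussian noise of SD 0.1 (event
#' amplitude 1).
#'
#' @param n_cells number of cells.
#' @param membership optional named list group -> cell ids; when `NULL`,
#'   the first `n_per_group` cells are assigned to each of `groups` in
#'   order.
#' @param groups group labels to plant.
#' @param n_per_group planted cells per group.
#' @param gain_in_period multiplicative in-period rate gain (>= 1).
#' @param baseline_event_rate background event rate, events/s.
#' @param registration_keep_prob cross-session tracking probability.
#' @param mean_bout_s,mean_inter_s mean freezing bout and inter-bout
#'   durations, seconds (`mean_bout_s = 0` disables freezing).
#' @param kernel_tau_s calcium kernel decay time constant, seconds.
#' @param noise_sd additive Gaussian noise SD on traces.
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(n_cells = 90, membership = NULL,
                         groups = c("pre-shock", "shock", "freezing", "no-freezing"),
                         n_per_group = 14, gain_in_period = 10,
                         baseline_event_rate = 0.02,
                         registration_keep_prob = 0.7,
                         mean_bout_s = 4, mean_inter_s = 16,
                         kernel_tau_s = 0.5, noise_sd = 0.1) {
  stopifnot(gain_in_period >= 1, baseline_event_rate >= 0,
            registration_keep_prob >= 0, registration_keep_prob <= 1,
            kernel_tau_s > 0, noise_sd >= 0)
  if (is.null(membership)) {
    if (length(groups) * n_per_group > n_cells)
      stop("planted groups exceed the cell count")
    membership <- list()
    nxt <- 1L
    for (g in groups) {
      membership[[g]] <- seq.int(nxt, nxt + n_per_group - 1L)
      nxt <- nxt + n_per_group
    }
  }
  ids <- unlist(membership)
  if (anyDuplicated(ids)) stop("planted groups must be pairwise disjoint")
  if (length(ids) > 0 && (max(ids) > n_cells || min(ids) < 1))
    stop("planted cell ids out of range")
  structure(list(n_cells = as.integer(n_cells), membership = membership,
                 gain_in_period = gain_in_period,
                 baseline_event_rate = baseline_event_rate,
                 registration_keep_prob = registration_keep_prob,
                 mean_bout_s = mean_bout_s, mean_inter_s = mean_inter_s,
                 kernel_tau_s = kernel_tau_s, noise_sd = noise_sd),
            class = "ground_truth")
}

# continuous-time alternating renewal freezing process, started at
# stationarity (exponential dwells are memoryless)
sample_freezing_bouts <- function(duration_s, mean_bout_s, mean_inter_s) {
  if (mean_bout_s < 0 || (mean_bout_s > 0 && mean_inter_s <= 0))
    stop("dwell parameters must be positive (mean_bout_s = 0 disables freezing)")
  if (mean_bout_s == 0)
    return(cbind(start = numeric(), end = numeric()))
  p_frz <- mean_bout_s / (mean_bout_s + mean_inter_s)
  frozen <- stats::runif(1) < p_frz
  t <- 0
  starts <- numeric(); ends <- numeric()
  while (t < duration_s) {
    dwell <- stats::rexp(1, 1 / (if (frozen) mean_bout_s else mean_inter_s))
    if (frozen) {
      starts <- c(starts, t)
      ends <- c(ends, min(t + dwell, duration_s))
    }
    t <- t + dwell
    frozen <- !frozen
  }
  cbind(start = starts, end = ends)
}

# canonical body-frame offsets (cm) of the ten tracked parts
body_offsets <- function() {
  rbind(nose = c(2.5, 0), neck = c(1.5, 0),
        left_ear = c(1.8, 0.6), right_ear = c(1.8, -0.6),
        left_side = c(0, 1), right_side = c(0, -1),
        middle_back = c(-0.5, 0),
        left_hindleg = c(-1.5, 0.8), right_hindleg = c(-1.5, -0.8),
        tail_base = c(-2.5, 0))
}

#' Generate synthetic behavior (pose track + freezing labels)
#'
#' Freezing is a two-state Markov dwell process (exponential bout and
#' inter-bout durations, started at stationarity), generated in continuous
#' time, rasterized to frames (bouts shorter than one frame dropped). The
#' pose track is a centroid random walk carrying ten body parts at fixed
#' body-frame offsets: while frozen the centroid and heading are held
#' (sub-threshold jitter only, all part speeds < 0.5 cm/s); while moving
#' the centroid translates at 2–8 cm/s with a slowly wandering heading, so
#' essentially all parts exceed 0.5 cm/s. Only the speed statistics are
#' meaningful, not the anatomy.
#'
#' @param spec a [session_spec()].
#' @param truth a [ground_truth()] (dwell parameters).
#' @return A list with `track` (a [pose_track()]), `labels` (a
#'   [freezing_labels()] equal to the rasterized generating bouts) and
#'   `seed`.
#' @export
generate_behavior <- function(spec, truth) {
  stopifnot(inherits(spec, "session_spec"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(spec$seed, 1))
  fr <- spec$frame_rate_behavior
  n_frames <- round(spec$duration_s * fr)
  bouts <- sample_freezing_bouts(spec$duration_s, truth$mean_bout_s,
                                 truth$mean_inter_s)
  bouts <- bouts[bouts[, "end"] - bouts[, "start"] >= 1 / fr, , drop = FALSE]
  mids <- (seq_len(n_frames) - 0.5) / fr
  frozen <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(bouts)))
    frozen <- frozen | (mids >= bouts[i, "start"] & mids < bouts[i, "end"])

  offs <- body_offsets()
  arena <- c(24, 24)
  cx <- numeric(n_frames); cy <- numeric(n_frames)
  heading <- numeric(n_frames)
  cx[1] <- arena[1] / 2; cy[1] <- arena[2] / 2
  heading[1] <- stats::runif(1, 0, 2 * pi)
  for (f in seq_len(n_frames)[-1]) {
    if (frozen[f]) {
      cx[f] <- cx[f - 1]; cy[f] <- cy[f - 1]; heading[f] <- heading[f - 1]
    } else {
      heading[f] <- heading[f - 1] + stats::rnorm(1, 0, 10 * pi / 180)
      step <- stats::runif(1, 2, 8) / fr
      x <- cx[f - 1] + step * cos(heading[f])
      y <- cy[f - 1] + step * sin(heading[f])
      if (x < 3 || x > arena[1] - 3) {
        heading[f] <- pi - heading[f]
        x <- pmin(pmax(x, 3), arena[1] - 3)
      }
      if (y < 3 || y > arena[2] - 3) {
        heading[f] <- -heading[f]
        y <- pmin(pmax(y, 3), arena[2] - 3)
      }
      cx[f] <- x; cy[f] <- y
    }
  }
  pos <- array(0, dim = c(n_frames, nrow(offs), 2))
  ch <- cos(heading); sh <- sin(heading)
  for (p in seq_len(nrow(offs))) {
    pos[, p, 1] <- cx + offs[p, 1] * ch - offs[p, 2] * sh
    pos[, p, 2] <- cy + offs[p, 1] * sh + offs[p, 2] * ch
  }
  pos <- pos + stats::rnorm(length(pos), 0, 0.002)   # tracking jitter
  track <- pose_track(pos, fr, rownames(offs))
  list(track = track, labels = freezing_labels(frozen, fr),
       seed = spec$seed)
}

#' Generate synthetic fluorescence traces with planted tuning
#'
#' Events are Poisson-like: each imaging sample is an event with
#' probability `rate / sample_rate`, where the rate is the baseline for
#' background cells and `gain_in_period x baseline` inside a planted
#' cell's condition epochs. Events are convolved with a single-exponential
#' calcium kernel (unit amplitude, decay `kernel_tau_s`), then Gaussian
#' noise of SD `noise_sd` is added. Ground-truth event times are returned
#' alongside the traces.
#'
#' @param spec a [session_spec()].
#' @param truth a [ground_truth()].
#' @param epochs_by_group named list group -> [epoch_set()]: the condition
#'   epochs of every planted group. A planted group without epochs is an
#'   error (it would be untestable).
#' @return A list with `trace` (a [trace_matrix()]), `event_times` (list
#'   of event-time vectors in seconds, one per cell) and `seed`.
#' @export
generate_traces <- function(spec, truth, epochs_by_group = list()) {
  stopifnot(inherits(spec, "session_spec"), inherits(truth, "ground_truth"))
  for (g in names(truth$membership)) {
    if (length(truth$membership[[g]]) == 0) next
    e <- epochs_by_group[[g]]
    if (is.null(e) || nrow(as_epoch_set(e)) == 0)
      stop("planted group '", g, "' has no condition epochs")
    if (any(as_epoch_set(e)$end > spec$duration_s + 1e-9))
      stop("condition epochs of group '", g, "' extend beyond the session")
  }
  set.seed(stage_seed(spec$seed, 2))
  fs <- spec$sample_rate_trace
  n_samples <- round(spec$duration_s * fs)
  n_cells <- spec$n_cells
  mids <- (seq_len(n_samples) - 0.5) / fs
  base_p <- truth$baseline_event_rate / fs
  group_of <- rep(NA_character_, n_cells)
  for (g in names(truth$membership)) group_of[truth$membership[[g]]] <- g

  a <- exp(-1 / (fs * truth$kernel_tau_s))
  values <- matrix(0, n_cells, n_samples)
  event_times <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    p <- rep(base_p, n_samples)
    if (!is.na(group_of[i])) {
      sel <- in_epochs(mids, epochs_by_group[[group_of[i]]])
      p[sel] <- pmin(base_p * truth$gain_in_period, 1)
    }
    ev <- as.numeric(stats::runif(n_samples) < p)
    event_times[[i]] <- mids[ev > 0]
    values[i, ] <- stats::filter(ev, a, method = "recursive")
  }
  if (truth$noise_sd > 0)
    values <- values + matrix(stats::rnorm(length(values), 0, truth$noise_sd),
                              n_cells, n_samples)
  list(trace = trace_matrix(values, fs), event_times = event_times,
       seed = spec$seed)
}

#' Generate a synthetic cross-session registration map
#'
#' Emulates cross-session cell tracking with independent per-cell
#' drop-out: each first-session cell is kept with probability `keep_prob`
#' (optionally group-specific), and kept cells receive consecutive
#' second-session ids. With `keep_prob = 1` the map is the identity on all
#' cells.
#'
#' @param n_cells_A number of first-session cells.
#' @param keep_prob tracking probability in `[0, 1]`.
#' @param seed integer seed.
#' @param keep_prob_by_group optional named list group -> probability,
#'   overriding `keep_prob` for planted members (requires `membership`).
#' @param membership named list group -> cell ids (only with
#'   `keep_prob_by_group`).
#' @return A [registration_map()].
#' @export
generate_registration <- function(n_cells_A, keep_prob, seed = 1,
                                  keep_prob_by_group = NULL,
                                  membership = NULL) {
  stopifnot(keep_prob >= 0, keep_prob <= 1, n_cells_A >= 0)
  set.seed(stage_seed(seed, 3))
  p <- rep(keep_prob, n_cells_A)
  if (!is.null(keep_prob_by_group)) {
    stopifnot(!is.null(membership))
    for (g in names(keep_prob_by_group))
      p[membership[[g]]] <- keep_prob_by_group[[g]]
  }
  kept <- stats::runif(n_cells_A) < p
  registration_map(which(kept), seq_len(sum(kept)))
}

#' Generate cell field-of-view positions
#'
#' Uniform positions within a rectangular miniscope field of view.
#'
#' @param n_cells number of cells.
#' @param fov_um field-of-view width and height in microns.
#' @param seed integer seed.
#' @return Data frame with columns `cell`, `x`, `y` (microns).
#' @export
generate_positions <- function(n_cells, fov_um = c(600, 600), seed = 1) {
  set.seed(stage_seed(seed, 4))
  data.frame(cell = seq_len(n_cells),
             x = stats::runif(n_cells, 0, fov_um[1]),
             y = stats::runif(n_cells, 0, fov_um[2]))
}

#' Generate a complete synthetic session for a protocol preset
#'
#' One-call generator: builds the protocol timeline, simulates behavior,
#' derives the condition (would-be tagging) epochs from the simulated
#' freezing labels via [schedule_tagging()], plants cell tuning on those
#' epochs and simulates traces and positions. Planted cells are thus tuned
#' to exactly the period in which activity-dependent tagging would have
#' labeled them.
#'
#' Presets: `"fc"` (fear conditioning; plants pre-shock, shock, freezing
#' and no-freezing ensembles), `"recall"` (plants recall-frz and
#' recall-no-frz ensembles), `"ctxB"` and `"ctxC"` (neutral contexts,
#' background cells only).
#'
#' @param preset `"fc"`, `"recall"`, `"ctxB"` or `"ctxC"`.
#' @param seed integer seed.
#' @param n_cells number of cells (default 90).
#' @param truth optional [ground_truth()]; defaults to the preset's
#'   planted structure.
#' @return A list of class `"synthetic_session"` with elements `spec`,
#'   `truth`, `timeline`, `track`, `labels`, `condition_epochs`, `plans`,
#'   `trace`, `event_times`, `positions`.
#' @export
synth_session <- function(preset = c("fc", "recall", "ctxB", "ctxC"),
                          seed = 1, n_cells = 90, truth = NULL) {
  preset <- match.arg(preset)
  protocol <- switch(preset, fc = "FC", recall = "RECALL",
                     ctxB = "ctxB", ctxC = "ctxC")
  timeline <- build_timeline(protocol)
  if (is.null(truth)) {
    truth <- switch(preset,
      fc = ground_truth(n_cells),
      recall = ground_truth(n_cells,
                            groups = c("recall-frz", "recall-no-frz")),
      ground_truth(n_cells, membership = list()))
  }
  spec <- session_spec(timeline$duration_s, n_cells = n_cells,
                       shock_onsets_s = timeline$shocks$start,
                       context_label = preset, seed = seed)
  beh <- generate_behavior(spec, truth)
  plans <- list()
  epochs <- list()
  if (preset == "fc") {
    plans[["pre-shock"]] <- schedule_tagging("pre-shock", timeline)
    plans[["shock"]] <- schedule_tagging("shock", timeline)
    plans[["freezing"]] <- schedule_tagging("freezing", timeline, beh$labels)
    plans[["no-freezing"]] <- schedule_tagging("no-freezing", timeline, beh$labels)
  } else if (preset == "recall") {
    plans[["recall-frz"]] <- schedule_tagging("recall-frz", timeline, beh$labels)
    plans[["recall-no-frz"]] <- schedule_tagging("recall-no-frz", timeline, beh$labels)
  }
  for (g in names(plans)) epochs[[g]] <- plans[[g]]$light_epochs
  tr <- generate_traces(spec, truth, epochs)
  structure(list(spec = spec, truth = truth, timeline = timeline,
                 track = beh$track, labels = beh$labels,
                 condition_epochs = epochs, plans = plans,
                 trace = tr$trace, event_times = tr$event_times,
                 positions = generate_positions(n_cells, seed = seed)),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %s: %d cells, %g s, %d planted group(s), seed %d\n",
              x$spec$context_label, x$spec$n_cells, x$spec$duration_s,
              length(x$truth$membership), x$spec$seed))
  invisible(x)
}

#' Write a synthetic session to disk
#'
#' Writes the trace matrix, pose track, condition-epoch tables,
#' ground-truth membership and positions of a [synth_session()] result as
#' plain TSV files with provenance headers.
#'
#' @param session a `"synthetic_session"`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_session <- function(session, out_dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("seed: %d", session$spec$seed),
           sprintf("context: %s", session$spec$context_label))
  write_trace_matrix(session$trace, file.path(out_dir, "traces.tsv"), hdr)
  write_pose_track(session$track, file.path(out_dir, "pose.tsv"), hdr)
  write_freezing_labels(session$labels, file.path(out_dir, "freezing.tsv"))
  for (g in names(session$condition_epochs))
    write_epochs(session$condition_epochs[[g]],
                 file.path(out_dir, paste0("epochs_", gsub("[^a-z-]", "", g), ".tsv")),
                 hdr)
  gt <- do.call(rbind, lapply(names(session$truth$membership), function(g)
    data.frame(cell = session$truth$membership[[g]], group = g)))
  if (is.null(gt)) gt <- data.frame(cell = integer(), group = character())
  utils::write.table(gt, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_positions(session$positions, file.path(out_dir, "positions.tsv"), hdr)
  invisible(out_dir)
}
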