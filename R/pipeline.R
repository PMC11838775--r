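#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one place. Each
#' stochastic stage derives its own seed from the global `seed`, so a
#' config determines the whole result bundle. The config round-trips
#' through serialization (it is a plain named list).
#'
#' @param seed global integer seed.
#' @param n_cells cells per synthetic session.
#' @param immobility_threshold online immobility threshold, cm/s.
#' @param min_parts_freezing,min_parts_no_freezing immobile-part counts of
#'   the two closed-loop criteria (7 and 6 of 10).
#' @param z_cut event-extraction threshold in SD units.
#' @param n_shifts circular shifts of the statistical detector.
#' @param n_resamples bootstrap resamples of the overlap test.
#' @param denominator overlap denominator (`"union"`, `"min"`,
#'   `"n_cells"`).
#' @param keep_prob cross-session tracking probability.
#' @param cm_per_unit pixel-to-cm calibration applied when loading pose
#'   files.
#' @param out_dir optional output directory for TSV artifacts.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, n_cells = 90,
                            immobility_threshold = 0.5,
                            min_parts_freezing = 7,
                            min_parts_no_freezing = 6,
                            z_cut = 2, n_shifts = 1000, n_resamples = 1000,
                            denominator = "union", keep_prob = 0.7,
                            cm_per_unit = 1, out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 immobility_threshold = immobility_threshold,
                 min_parts_freezing = min_parts_freezing,
                 min_parts_no_freezing = min_parts_no_freezing,
                 z_cut = z_cut, n_shifts = n_shifts,
                 n_resamples = n_resamples, denominator = denominator,
                 keep_prob = keep_prob, cm_per_unit = cm_per_unit,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# cheap deterministic config fingerprint for provenance headers
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' Run the full synthetic-session analysis pipeline
#'
#' Orchestrates every stage on a synthetic fear-conditioning (FC) session
#' and a synthetic recall session linked by a registration map: behavior
#' classification (both closed-loop criteria), tagging-epoch scheduling,
#' event extraction, ensemble detection by both methods, pairwise overlap
#' verdicts, cross-session reactivation metrics, recall-group composition
#' and group correlation tests against circular-shift nulls. Identical
#' configs produce identical bundles. Excluded cells are reported with
#' reasons, never silently dropped.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `"pipeline_result"`; see elements `fc`,
#'   `recall`, `detection`, `overlaps`, `cross_session`, `correlations`,
#'   `agreement`, `exclusions`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  ## --- FC session -----------------------------------------------------
  fc <- synth_session("fc", seed = config$seed, n_cells = config$n_cells)
  note("FC session: %d cells, %d planted groups", config$n_cells,
       length(fc$truth$membership))

  # behavior re-classified from the pose track with both online criteria
  speeds <- compute_speeds(fc$track)
  labels7 <- classify_freezing_online(speeds, config$immobility_threshold,
                                      config$min_parts_freezing)
  labels6 <- classify_freezing_online(speeds, config$immobility_threshold,
                                      config$min_parts_no_freezing)
  plans <- list(
    `pre-shock` = schedule_tagging("pre-shock", fc$timeline),
    shock = schedule_tagging("shock", fc$timeline),
    freezing = schedule_tagging("freezing", fc$timeline, labels7),
    `no-freezing` = schedule_tagging("no-freezing", fc$timeline, labels6))
  epochs <- lapply(plans, `[[`, "light_epochs")
  note("tagging plans: %s",
       paste(sprintf("%s=%.1fs", names(plans),
                     vapply(plans, `[[`, numeric(1), "total_light_s")),
             collapse = ", "))

  z_fc <- bin_and_zscore(fc$trace, config$z_cut)
  raster_fc <- detect_events(z_fc)
  note("FC raster: %d bins, %d zero-variance cell(s) flagged",
       ncol(raster_fc$events), length(z_fc$flagged))

  det_rank <- detect_ensembles(fc$trace, epochs, "rank")
  det_stat <- detect_ensembles(fc$trace, epochs, "statistical",
                               n_shifts = config$n_shifts,
                               seed = stage_seed(config$seed, 10))
  note("rank members: %s",
       paste(vapply(det_rank$membership, length, 1L), collapse = "/"))

  agreement <- vapply(names(det_rank$membership), function(g) {
    a <- fc$trace$cell_ids %in% det_rank$membership[[g]]
    b <- fc$trace$cell_ids %in% det_stat$membership[[g]]
    mean(a == b)
  }, numeric(1))

  overlaps <- overlap_pairs(det_rank, n_resamples = config$n_resamples,
                            seed = stage_seed(config$seed, 20),
                            denominator = config$denominator)
  note("overlaps: %d pair verdicts", nrow(overlaps))

  ## --- recall session -------------------------------------------------
  reg <- generate_registration(config$n_cells, config$keep_prob,
                               seed = stage_seed(config$seed, 30))
  # tracked FC cells carry their planted tuning into recall
  recall_membership <- list(
    `recall-frz` = reg$cell_B[reg$cell_A %in% fc$truth$membership[["freezing"]]],
    `recall-no-frz` = reg$cell_B[reg$cell_A %in% fc$truth$membership[["no-freezing"]]])
  recall_truth <- ground_truth(nrow(reg), membership = recall_membership)
  recall <- synth_session("recall", seed = stage_seed(config$seed, 31),
                          n_cells = max(nrow(reg), 1), truth = recall_truth)
  z_rec <- bin_and_zscore(recall$trace, config$z_cut)
  raster_rec <- detect_events(z_rec)
  rec_groups <- recall_groups(recall$trace, recall$labels, "rank")
  note("recall session: %d tracked cells, frz-recall %d member(s)",
       nrow(reg), length(rec_groups$membership[["frz-recall"]]))

  rel <- vapply(names(det_rank$membership), function(g) {
    m <- det_rank$membership[[g]]
    if (length(m) == 0) return(NA_real_)
    relative_reactivation(reg, m, config$n_cells)
  }, numeric(1))
  react <- recall_activity(reg, det_rank$membership, raster_rec, recall$labels)
  comp <- recall_group_composition(reg, det_rank$membership,
                                   rec_groups$membership[["frz-recall"]])

  ## --- correlations ---------------------------------------------------
  ct <- pairwise_correlations(raster_fc)
  nc <- null_correlations(raster_fc, ct,
                          n_replicates = min(config$n_shifts, 200),
                          seed = stage_seed(config$seed, 40))
  corr <- lapply(names(det_rank$membership), function(g) {
    m <- intersect(det_rank$membership[[g]], ct$included)
    sl <- if (length(m) >= 2) pair_slice(ct$pairs, m, m) else integer()
    if (length(sl) == 0) return(NULL)
    compare_group_to_null(ct, nc, m, group_pair = c(g, g))
  })
  names(corr) <- names(det_rank$membership)
  corr <- corr[!vapply(corr, is.null, logical(1))]
  note("correlations: %d intra-group comparisons", length(corr))

  exclusions <- rbind(
    if (length(z_fc$flagged) > 0)
      data.frame(session = "fc", cell = z_fc$flagged, reason = "zero binned variance"),
    if (nrow(ct$excluded) > 0)
      data.frame(session = "fc", cell = ct$excluded$cell,
                 reason = paste("correlations:", ct$excluded$reason)),
    if (length(z_rec$flagged) > 0)
      data.frame(session = "recall", cell = z_rec$flagged,
                 reason = "zero binned variance"))
  if (is.null(exclusions))
    exclusions <- data.frame(session = character(), cell = integer(),
                             reason = character())

  result <- structure(list(
    config = config, fc = fc, recall = recall, registration = reg,
    labels = list(freezing7 = labels7, no_freezing6 = labels6),
    plans = plans, raster_fc = raster_fc, raster_recall = raster_rec,
    detection = list(rank = det_rank, statistical = det_stat,
                     recall = rec_groups),
    agreement = agreement, overlaps = overlaps,
    cross_session = list(relative_reactivation = rel, activity = react,
                         composition = comp),
    correlations = corr, exclusions = exclusions, log = log),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

# write the bundle's tabular artifacts with provenance headers
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("seed: %d", result$config$seed),
           sprintf("config_hash: %d", config_hash(result$config)),
           sprintf("stage_version: %s",
                   as.character(utils::packageVersion("engram"))))
  for (g in names(result$detection$rank$membership)) {
    m_rank <- result$detection$rank$membership[[g]]
    m_stat <- result$detection$statistical$membership[[g]]
    df <- rbind(
      if (length(m_rank) > 0) data.frame(cell = m_rank, method = "rank"),
      if (length(m_stat) > 0) data.frame(cell = m_stat, method = "statistical"))
    if (is.null(df)) df <- data.frame(cell = integer(), method = character())
    f <- file.path(out_dir, paste0("membership_", gsub("[^a-z-]", "", g), ".tsv"))
    con <- file(f, "w")
    for (h in hdr) writeLines(paste("#", h), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  con <- file(file.path(out_dir, "overlaps.tsv"), "w")
  for (h in hdr) writeLines(paste("#", h), con)
  utils::write.table(result$overlaps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_registration(result$registration,
                     file.path(out_dir, "registration.tsv"), hdr)
  utils::write.table(result$exclusions, file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
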