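#' Session timelines of the behavioral protocols
#'
#' Builds the fixed session timeline (duration and foot-shock epochs) for
#' each behavioral protocol:
#' \describe{
#'   \item{FC}{7-min fear conditioning with four 2-s foot shocks at minutes
#'     2, 3, 4 and 5.}
#'   \item{RECALL}{8-min recall session in the conditioning context, no
#'     shocks.}
#'   \item{ctxB}{7-min neutral-context session, no shocks.}
#'   \item{ctxC}{8-min neutral-context session, no shocks.}
#'   \item{sweeping}{8-min session with visual-threat sweeps, no shocks.}
#'   \item{immediate_shock}{40-s session with four 2-s shocks at seconds
#'     2, 8, 14 and 20.}
#'   \item{grouped_shock}{5-min session with four 2-s shocks at 2:00, 2:06,
#'     2:12 and 2:18.}
#' }
#'
#' @param protocol_label one of `"FC"`, `"RECALL"`, `"ctxB"`, `"ctxC"`,
#'   `"sweeping"`, `"immediate_shock"`, `"grouped_shock"`.
#' @param shock_duration_s shock duration in seconds (default 2).
#' @return An object of class `"session_timeline"`: list with `duration_s`,
#'   `shocks` (an [epoch_set()]) and `protocol_label`.
#' @examples
#' build_timeline("FC")$shocks
#' @export
build_timeline <- function(protocol_label, shock_duration_s = 2) {
  onsets <- switch(protocol_label,
    FC              = c(120, 180, 240, 300),
    RECALL          = numeric(),
    ctxB            = numeric(),
    ctxC            = numeric(),
    sweeping        = numeric(),
    immediate_shock = c(2, 8, 14, 20),
    grouped_shock   = c(120, 126, 132, 138),
    stop("unknown protocol label: ", protocol_label))
  duration <- switch(protocol_label,
    FC = 420, RECALL = 480, ctxB = 420, ctxC = 480, sweeping = 480,
    immediate_shock = 40, grouped_shock = 300)
  shocks <- epoch_set(rep("shock", length(onsets)), onsets,
                      onsets + shock_duration_s)
  structure(list(duration_s = duration, shocks = shocks,
                 protocol_label = protocol_label),
            class = "session_timeline")
}

#' @export
print.session_timeline <- function(x, ...) {
  cat(sprintf("<session_timeline> %s: %g s, %d shock(s)\n",
              x$protocol_label, x$duration_s, nrow(x$shocks)))
  invisible(x)
}

# accumulate epochs in temporal order until `budget` seconds; clip the last
accumulate_budget <- function(epochs, budget, label) {
  epochs <- as_epoch_set(epochs)
  out_s <- numeric(); out_e <- numeric(); used <- 0
  for (i in seq_len(nrow(epochs))) {
    if (used >= budget) break
    len <- epochs$end[i] - epochs$start[i]
    take <- min(len, budget - used)
    out_s <- c(out_s, epochs$start[i])
    out_e <- c(out_e, epochs$start[i] + take)
    used <- used + take
  }
  list(epochs = epoch_set(rep(label, length(out_s)), out_s, out_e),
       used = used)
}

#' Schedule light-delivery epochs for a tagging condition
#'
#' Computes the light-delivery (tagging) epochs that the closed-loop
#' activity-tagging protocol delivers for a given experimental condition
#' on a given session timeline:
#' \describe{
#'   \item{pre-shock}{the two minutes preceding the first shock, a single
#'     epoch `[t1 - 120, t1)`.}
#'   \item{shock}{10 s of light during and after every shock (2-s shock
#'     plus 8 s), one epoch `[onset, onset + 10)` per shock — 40 s total
#'     on the standard timeline.}
#'   \item{freezing}{light whenever the animal freezes after the third
#'     shock's offset, accumulated in order until the 40-s budget; the last
#'     bout is truncated at the budget.}
#'   \item{no-freezing}{light whenever the animal is not freezing, starting
#'     after the second shock's offset, 40-s budget. Callers should supply
#'     labels from the permissive 6-of-10 immobility criterion so that the
#'     complement excludes ambiguous frames.}
#'   \item{recall-frz / recall-no-frz}{the same accumulation over the whole
#'     recall session, freezing bouts or their complement, 40-s budget,
#'     without additional conditions.}
#'   \item{sweeping}{the caller-supplied sweep epochs, passed through
#'     verbatim.}
#'   \item{imm-shock}{light for the entire (40-s) immediate-shock session.}
#'   \item{grouped-shock}{light from the first grouped shock's onset for
#'     40 s (2:00 to 2:40 on the grouped timeline).}
#' }
#' Budget shortfalls (eligible time below the budget) are flagged, not
#' raised: the plan carries a `shortfall` flag.
#'
#' @param condition one of `"pre-shock"`, `"shock"`, `"freezing"`,
#'   `"no-freezing"`, `"recall-frz"`, `"recall-no-frz"`, `"sweeping"`,
#'   `"imm-shock"`, `"grouped-shock"`.
#' @param timeline a [build_timeline()] result.
#' @param labels a [freezing_labels()] object; required for the freezing,
#'   no-freezing and recall conditions.
#' @param budget_s light budget in seconds for budgeted conditions
#'   (default 40).
#' @param sweep_epochs an [epoch_set()] of sweep presentations (sweeping
#'   condition only).
#' @return An object of class `"tagging_plan"`: list with `condition`,
#'   `light_epochs` (an [epoch_set()] labeled `"light"`), `budget_s`,
#'   `eligibility_start_s`, `total_light_s` and `shortfall`.
#' @examples
#' plan <- schedule_tagging("shock", build_timeline("FC"))
#' plan$total_light_s  # 40
#' @export
schedule_tagging <- function(condition, timeline, labels = NULL,
                             budget_s = 40, sweep_epochs = NULL) {
  stopifnot(inherits(timeline, "session_timeline"))
  needs_labels <- condition %in% c("freezing", "no-freezing",
                                   "recall-frz", "recall-no-frz")
  if (needs_labels && is.null(labels))
    stop("condition '", condition, "' requires freezing labels")
  if (!is.null(labels)) stopifnot(inherits(labels, "freezing_labels"))
  dur <- timeline$duration_s
  shocks <- timeline$shocks
  shortfall <- FALSE
  elig <- 0
  budget <- budget_s

  if (condition == "pre-shock") {
    if (nrow(shocks) < 1) stop("pre-shock condition needs at least one shock")
    t1 <- shocks$start[1]
    light <- epoch_set("light", max(0, t1 - 120), t1)
    budget <- NA_real_
    elig <- max(0, t1 - 120)
    used <- epoch_duration(light)
  } else if (condition == "shock") {
    if (nrow(shocks) < 1) stop("shock condition needs shocks")
    light <- epoch_set("light", shocks$start,
                       pmin(shocks$start + 10, dur))
    budget <- NA_real_
    elig <- shocks$start[1]
    used <- epoch_duration(light)
  } else if (condition %in% c("freezing", "no-freezing",
                              "recall-frz", "recall-no-frz")) {
    if (condition == "freezing") {
      if (nrow(shocks) < 3) stop("freezing condition needs three shocks")
      elig <- shocks$end[3]
      eligible <- epoch_intersect(labels$bouts, epoch_set("w", elig, dur))
    } else if (condition == "no-freezing") {
      if (nrow(shocks) < 2) stop("no-freezing condition needs two shocks")
      elig <- shocks$end[2]
      not_frozen <- epoch_complement(labels$bouts,
                                     length(labels$per_frame) / labels$frame_rate)
      eligible <- epoch_intersect(not_frozen, epoch_set("w", elig, dur))
    } else if (condition == "recall-frz") {
      eligible <- epoch_intersect(labels$bouts, epoch_set("w", 0, dur))
    } else {
      not_frozen <- epoch_complement(labels$bouts,
                                     length(labels$per_frame) / labels$frame_rate)
      eligible <- epoch_intersect(not_frozen, epoch_set("w", 0, dur))
    }
    acc <- accumulate_budget(eligible, budget_s, "light")
    light <- acc$epochs
    used <- acc$used
    shortfall <- used < budget_s - 1e-9
  } else if (condition == "sweeping") {
    if (is.null(sweep_epochs)) stop("sweeping condition needs sweep_epochs")
    se <- as_epoch_set(sweep_epochs)
    light <- epoch_set(rep("light", nrow(se)), se$start, se$end)
    budget <- NA_real_
    used <- epoch_duration(light)
  } else if (condition == "imm-shock") {
    light <- epoch_set("light", 0, dur)
    used <- dur
    shortfall <- used < budget_s - 1e-9
  } else if (condition == "grouped-shock") {
    if (nrow(shocks) < 1) stop("grouped-shock condition needs shocks")
    light <- epoch_set("light", shocks$start[1],
                       min(shocks$start[1] + budget_s, dur))
    used <- epoch_duration(light)
    shortfall <- used < budget_s - 1e-9
  } else stop("unknown tagging condition: ", condition)

  structure(list(condition = condition, light_epochs = light,
                 budget_s = budget, eligibility_start_s = elig,
                 total_light_s = used, shortfall = shortfall),
            class = "tagging_plan")
}

#' @export
print.tagging_plan <- function(x, ...) {
  cat(sprintf("<tagging_plan> %s: %d light epoch(s), %.2f s total%s\n",
              x$condition, nrow(x$light_epochs), x$total_light_s,
              if (x$shortfall) " [SHORTFALL]" else ""))
  invisible(x)
}
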