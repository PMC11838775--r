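test_that("identical spec and seed give bit-identical outputs", {
  s1 <- synth_session("fc", seed = 4, n_cells = 20,
                      truth = ground_truth(20, n_per_group = 2))
  s2 <- synth_session("fc", seed = 4, n_cells = 20,
                      truth = ground_truth(20, n_per_group = 2))
  expect_identical(s1$track$positions, s2$track$positions)
  expect_identical(s1$labels$per_frame, s2$labels$per_frame)
  expect_identical(s1$trace$values, s2$trace$values)
  expect_identical(s1$event_times, s2$event_times)
  s3 <- synth_session("fc", seed = 5, n_cells = 20,
                      truth = ground_truth(20, n_per_group = 2))
  expect_false(identical(s1$trace$values, s3$trace$values))
})

test_that("session specs enforce their invariants", {
  expect_error(session_spec(100, shock_onsets_s = c(10, 99.5)), "end within")
  expect_error(session_spec(100, shock_onsets_s = c(20, 10)), "strictly increasing")
  expect_error(ground_truth(10, n_per_group = 5), "exceed the cell count")
  expect_error(ground_truth(10, membership = list(a = 1:3, b = 3:5)), "disjoint")
})

test_that("freezing occupancy matches the dwell-process stationary fraction", {
  # mean bout 4 s, mean inter-bout 16 s -> stationary fraction 4/20 = 0.2
  fr <- vapply(1:100, function(sd) {
    spec <- session_spec(420, n_cells = 1, seed = sd)
    beh <- generate_behavior(spec, ground_truth(1, membership = list()))
    mean(beh$labels$per_frame)
  }, numeric(1))
  expect_equal(mean(fr), 0.2, tolerance = 0.1)
})

test_that("degenerate dwell parameters behave as documented", {
  spec <- session_spec(60, n_cells = 1, seed = 2)
  none <- generate_behavior(spec, ground_truth(1, membership = list(),
                                               mean_bout_s = 0))
  expect_false(any(none$labels$per_frame))
  expect_equal(nrow(none$labels$bouts), 0)
  expect_error(generate_behavior(spec, ground_truth(1, membership = list(),
                                                    mean_bout_s = -1)),
               "dwell parameters")
  expect_error(generate_behavior(spec, ground_truth(1, membership = list(),
                                                    mean_bout_s = 2,
                                                    mean_inter_s = 0)),
               "dwell parameters")
})

test_that("pose speeds respect the freezing geometry", {
  for (sd in 1:2) {
    spec <- session_spec(200, n_cells = 1, seed = sd)
    beh <- generate_behavior(spec, ground_truth(1, membership = list()))
    sp <- compute_speeds(beh$track)$speeds
    frz <- beh$labels$per_frame
    if (any(frz)) expect_lt(max(sp[frz, ]), 0.5)
    moving <- which(!frz)[-1]
    expect_true(all(rowSums(sp[moving, , drop = FALSE] > 0.5) >= 8))
  }
})

test_that("noiseless traces equal the kernel-filtered ground-truth events", {
  spec <- session_spec(120, n_cells = 3, seed = 9)
  truth <- ground_truth(3, membership = list(), baseline_event_rate = 0.05,
                        noise_sd = 0)
  out <- generate_traces(spec, truth)
  fs <- spec$sample_rate_trace
  a <- exp(-1 / (fs * truth$kernel_tau_s))
  for (i in 1:3) {
    ev <- rep(0, ncol(out$trace$values))
    ev[round(out$event_times[[i]] * fs + 0.5)] <- 1
    expect_equal(unname(out$trace$values[i, ]),
                 as.numeric(stats::filter(ev, a, method = "recursive")))
  }
  expect_true(all(out$trace$values >= 0))
})

test_that("planted groups without condition epochs are rejected", {
  spec <- session_spec(120, n_cells = 5, seed = 1)
  truth <- ground_truth(5, membership = list(shock = 1:2))
  expect_error(generate_traces(spec, truth), "no condition epochs")
  expect_error(generate_traces(spec, truth,
                               list(shock = epoch_set("s", 0, 130))),
               "beyond the session")
})

test_that("untuned cells are selected at chance regardless of planting labels", {
  # gain 1: planted and background cells are exchangeable for the detector
  sel <- vapply(1:30, function(sd) {
    truth <- ground_truth(30, n_per_group = 5, gain_in_period = 1,
                          baseline_event_rate = 0.1)
    s <- synth_session("fc", seed = sd, n_cells = 30, truth = truth)
    d <- detect_ensembles(s$trace, s$condition_epochs, "rank")
    planted <- unlist(s$truth$membership)
    bg <- setdiff(1:30, planted)
    c(mean(planted %in% unlist(d$membership)), mean(bg %in% unlist(d$membership)))
  }, numeric(2))
  expect_lt(abs(mean(sel[1, ]) - mean(sel[2, ])), 0.08)
})

test_that("strong planted tuning raises in-epoch over out-of-epoch means", {
  hits <- vapply(1:20, function(sd) {
    truth <- ground_truth(20, n_per_group = 3, gain_in_period = 10)
    s <- synth_session("fc", seed = sd, n_cells = 20, truth = truth)
    ok <- TRUE
    for (g in names(truth$membership)) {
      ep <- s$condition_epochs[[g]]
      mids <- (seq_len(ncol(s$trace$values)) - 0.5) / s$trace$sample_rate
      sel <- in_epochs(mids, ep)
      cells <- truth$membership[[g]]
      ok <- ok && (mean(s$trace$values[cells, sel]) >
                   mean(s$trace$values[cells, !sel]))
    }
    ok
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("registration drop-out follows the keep probability", {
  full <- generate_registration(50, 1, seed = 1)
  expect_equal(full$cell_A, 1:50)
  expect_equal(full$cell_B, 1:50)
  expect_equal(nrow(generate_registration(50, 0, seed = 1)), 0)
  counts <- vapply(1:1000, function(sd)
    nrow(generate_registration(100, 0.7, seed = sd)), numeric(1))
  expect_equal(mean(counts), 70, tolerance = 3 / 70)
  # per-group keep probabilities override the global one
  m <- generate_registration(100, 1, seed = 2,
                             keep_prob_by_group = list(g = 0),
                             membership = list(g = 1:50))
  expect_equal(m$cell_A, 51:100)
  expect_error(generate_registration(100, 1, seed = 2,
                                     keep_prob_by_group = list(g = 0)))
})

test_that("sessions serialize to a complete plain-text bundle", {
  s <- synth_session("fc", seed = 3, n_cells = 12,
                     truth = ground_truth(12, n_per_group = 2))
  d <- withr::local_tempdir()
  write_session(s, d)
  files <- list.files(d)
  expect_true(all(c("traces.tsv", "pose.tsv", "freezing.tsv", "ground_truth.tsv",
                    "positions.tsv") %in% files))
  expect_equal(sum(grepl("^epochs_", files)), 4)
  back <- read_trace_matrix(file.path(d, "traces.tsv"))
  expect_equal(back$values, s$trace$values, tolerance = 1e-6, ignore_attr = TRUE)
})
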