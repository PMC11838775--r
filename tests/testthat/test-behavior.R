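test_that("speeds are displacement times frame rate, first frame zero", {
  # stationary track
  pos <- array(5, dim = c(10, 10, 2))
  expect_true(all(compute_speeds(pose_track(pos, 15))$speeds == 0))

  # 0.1 cm per frame along x at 15 Hz -> 1.5 cm/s
  pos <- array(0, dim = c(20, 10, 2))
  pos[, 1, 1] <- seq(0, by = 0.1, length.out = 20)
  sp <- compute_speeds(pose_track(pos, 15))
  expect_equal(unname(sp$speeds[-1, 1]), rep(1.5, 19))
  expect_equal(unname(sp$speeds[1, ]), rep(0, 10))

  # diagonal (0.3, 0.4) cm step at 30 Hz -> 0.5 * 30 = 15 cm/s
  pos <- array(0, dim = c(2, 10, 2))
  pos[2, 3, ] <- c(0.3, 0.4)
  sp <- compute_speeds(pose_track(pos, 30))
  expect_equal(unname(sp$speeds[2, 3]), 15)

  expect_error(compute_speeds(pose_track(array(0, dim = c(1, 10, 2)), 15)),
               "at least 2 frames")
})

test_that("online classifier counts immobile parts against the threshold", {
  n <- 30
  # all parts immobile
  still <- track_from_speeds(matrix(0, n, 10))
  expect_true(all(classify_freezing_online(compute_speeds(still), 0.5, 7)$per_frame))
  # exactly 6 of 10 parts immobile: freezing under the 6-part (no-freezing-tag)
  # criterion, not under the 7-part (freezing-tag) criterion
  sp <- matrix(1, n, 10); sp[, 1:6] <- 0
  tr <- track_from_speeds(sp)
  s <- compute_speeds(tr)
  f6 <- classify_freezing_online(s, 0.5, 6)$per_frame
  f7 <- classify_freezing_online(s, 0.5, 7)$per_frame
  expect_true(all(f6[-1]))
  expect_false(any(f7[-1]))
  # all parts moving at 1.0 cm/s: no freezing under either criterion
  mov <- track_from_speeds(matrix(1, n, 10))
  expect_false(any(classify_freezing_online(compute_speeds(mov), 0.5, 6)$per_frame[-1]))
  expect_error(classify_freezing_online(s, 0.5, 11), "min_immobile_parts")
})

test_that("lowering the part criterion never shrinks the freezing set", {
  set.seed(42)
  for (rep in 1:5) {
    sp <- matrix(runif(50 * 10, 0, 1.2), 50, 10)
    s <- compute_speeds(track_from_speeds(sp))
    f7 <- classify_freezing_online(s, 0.5, 7)$per_frame
    f6 <- classify_freezing_online(s, 0.5, 6)$per_frame
    expect_true(all(f6[f7]))   # 7-part set is a subset of the 6-part set
  }
})

test_that("bouts rasterize back to the per-frame labels exactly", {
  set.seed(7)
  for (rep in 1:5) {
    frames <- runif(200) < 0.3
    lab <- labels_from_frames(frames, frame_rate = 15)
    mids <- (seq_along(frames) - 0.5) / 15
    expect_identical(in_epochs(mids, lab$bouts), frames)
  }
})

test_that("classifiers are invariant under rigid translation", {
  set.seed(11)
  s <- synth_session("fc", seed = 5, n_cells = 1,
                     truth = ground_truth(1, membership = list()))
  tr <- s$track
  shifted <- pose_track(tr$positions + rep(c(7, -3), each = prod(dim(tr$positions)[1:2])),
                        tr$frame_rate, tr$part_names)
  expect_identical(classify_freezing_online(compute_speeds(tr))$per_frame,
                   classify_freezing_online(compute_speeds(shifted))$per_frame)
  expect_identical(classify_freezing_posthoc(tr)$per_frame,
                   classify_freezing_posthoc(shifted)$per_frame)
})

test_that("post-hoc classifier: stationary track is one bout, fast track none", {
  n <- 300  # 10 s at 30 Hz
  pos <- array(rep(c(1:10 / 10, 1:10 / 10), each = n), dim = c(n, 10, 2))
  still <- pose_track(pos, 30)
  lab <- classify_freezing_posthoc(still)
  expect_true(all(lab$per_frame))
  expect_equal(nrow(lab$bouts), 1)
  expect_equal(lab$bouts$start, 0)
  expect_equal(lab$bouts$end, 10)

  # centroid at 5 cm/s throughout
  mov <- pos
  mov[, , 1] <- mov[, , 1] + seq(0, by = 5 / 30, length.out = n)
  expect_false(any(classify_freezing_posthoc(pose_track(mov, 30))$per_frame))

  expect_error(classify_freezing_posthoc(pose_track(pos[1:20, , ], 30)),
               "shorter than the classifier window")
})

test_that("post-hoc min-duration rejects a 0.4-s stationary interval", {
  # 20 s at 30 Hz; motion except a 0.4-s (12-frame) stationary interval
  fr <- 30; n <- 20 * fr
  set.seed(3)
  sp <- matrix(6, n, 10)             # strong motion
  still_idx <- 301:312               # 0.4 s
  sp[still_idx, ] <- 0
  track <- track_from_speeds(sp, fr)
  lab <- classify_freezing_posthoc(track)
  oracle <- oracle_freeze_posthoc(track, posthoc_params())
  expect_identical(lab$per_frame, oracle)
  # the stationary interval is too short to survive min_duration = 0.5 s
  expect_false(any(lab$per_frame[still_idx]))
})

test_that("freezing percentages and delta-freezing follow the ON-OFF contract", {
  fr <- 10
  # 40 s session: ON = [0,10), [20,30); OFF = [10,20), [30,40)
  epochs <- epoch_set(c("ON", "OFF", "ON", "OFF"), c(0, 10, 20, 30), c(10, 20, 30, 40))

  # always frozen: every epoch 100%, delta 0
  lab <- labels_from_frames(rep(TRUE, 40 * fr), fr)
  m <- freezing_metrics(lab, epochs)
  expect_equal(m$per_epoch$pct_freezing, rep(100, 4))
  expect_equal(m$delta_freezing, 0)

  # frozen exactly during ON epochs: delta = 100
  t <- (seq_len(40 * fr) - 0.5) / fr
  lab <- labels_from_frames(in_epochs(t, epochs[epochs$label == "ON", ]), fr)
  expect_equal(freezing_metrics(lab, epochs)$delta_freezing, 100)

  # frozen half of each ON epoch, quarter of each OFF epoch: delta = 25
  frozen <- (t >= 0 & t < 5) | (t >= 20 & t < 25) |   # half of each ON
            (t >= 10 & t < 12.5) | (t >= 30 & t < 32.5)  # quarter of each OFF
  m <- freezing_metrics(labels_from_frames(frozen, fr), epochs)
  expect_equal(m$delta_freezing, 25)

  expect_error(freezing_metrics(lab, epoch_set("ON", 0, 60)), "beyond")
})

test_that("pose tracks round-trip through the wide TSV layout", {
  s <- synth_session("fc", seed = 2, n_cells = 1,
                     truth = ground_truth(1, membership = list()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pose_track(s$track, f)
  back <- read_pose_track(f)
  expect_equal(back$frame_rate, s$track$frame_rate)
  expect_equal(back$part_names, s$track$part_names)
  expect_equal(back$positions, s$track$positions, tolerance = 1e-6)
})
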