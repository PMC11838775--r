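test_that("rank detection thresholds at mean plus one population SD, strictly", {
  ep <- epoch_set("w", 0, 60)
  # all in-epoch means equal: population SD 0, strict > never satisfied
  expect_length(detect_rank(constant_trace(rep(2, 5)), ep), 0)

  # means [0, 0, 0, 10]: mu = 2.5, sigma = sqrt(75)/2 ~ 4.33, cut ~ 6.83
  m <- detect_rank(constant_trace(c(0, 0, 0, 10)), ep)
  expect_equal(as.integer(m), 4L)
  expect_equal(attr(m, "threshold"), 2.5 + sqrt(mean((c(0, 0, 0, 10) - 2.5)^2)))

  # normal in-epoch means: member fraction approaches the Phi(1) tail
  set.seed(31)
  big <- detect_rank(constant_trace(rnorm(10000)), ep)
  expect_equal(length(big) / 10000, 1 - pnorm(1), tolerance = 0.07)
})

test_that("rank detection is invariant under common affine rescaling", {
  set.seed(12)
  v <- matrix(rexp(30 * 120), 30)
  ep <- epoch_set("w", 10, 60)
  m1 <- detect_rank(trace_matrix(v, 1), ep)
  m2 <- detect_rank(trace_matrix(v * 3.7 + 11, 1), ep)
  expect_equal(as.integer(m1), as.integer(m2))
})

test_that("statistical detection: concentrated cells are members, flat cells are not", {
  n_bins <- 200
  ep <- epoch_set("w", 0, 20)           # 10% of the session
  active <- rep(0, n_bins); active[c(3, 8, 16)] <- 1
  flat <- rep(0.5, n_bins)
  silent <- rep(0, n_bins)
  tr <- trace_matrix(rbind(active, flat, silent), sample_rate = 1)
  for (sd in 1:20) {
    m <- detect_statistical(tr, ep, n_shifts = 200, seed = sd)
    expect_true(1 %in% m)      # events only inside the epochs
    expect_false(2 %in% m)     # constant cell ties its whole null
    expect_false(3 %in% m)     # all-zero cell
    expect_equal(attr(m, "flagged"), 3L)
  }
})

test_that("statistical detection respects in/out ratio arithmetic", {
  # cell active only in-epoch has an infinite ratio
  n_bins <- 100
  ep <- epoch_set("w", 0, 50)
  x <- rep(0, n_bins); x[10] <- 2
  tr <- trace_matrix(rbind(x, rep(c(1, 2), 50)), sample_rate = 1)
  m <- detect_statistical(tr, ep, n_shifts = 100, seed = 4)
  expect_true(is.infinite(attr(m, "statistic")[1]))
  expect_error(detect_statistical(tr, epoch_set("w", 0, 100)), "nonzero")
})

test_that("recall groups use freezing bouts and their complement", {
  s <- synth_session("recall", seed = 6, n_cells = 30,
                     truth = ground_truth(30, membership = list()))
  rg <- recall_groups(s$trace, s$labels, "rank")
  expect_named(rg$membership, c("frz-recall", "no-frz-recall"))
  # complement relation over the binned session
  dur <- floor(ncol(s$trace$values) / s$trace$sample_rate)
  frz <- epoch_intersect(s$labels$bouts, epoch_set("w", 0, dur))
  no_frz <- epoch_complement(s$labels$bouts, dur)
  expect_equal(epoch_duration(frz) + epoch_duration(no_frz), dur)
  expect_equal(nrow(epoch_intersect(frz, no_frz)), 0)

  empty <- freezing_labels(rep(FALSE, 100), 15)
  expect_error(recall_groups(s$trace, empty, "rank"), "frz-recall group undefined")
})

test_that("planted recall-freezing ensembles are recovered", {
  prs <- vapply(1:8, function(sd) {
    s <- synth_session("recall", seed = sd, n_cells = 90)
    rg <- recall_groups(s$trace, s$labels, "rank")
    det <- rg$membership[["frz-recall"]]
    tru <- s$truth$membership[["recall-frz"]]
    c(length(intersect(det, tru)) / max(length(det), 1),
      length(intersect(det, tru)) / length(tru))
  }, numeric(2))
  expect_gte(mean(prs[1, ]), 0.8)  # precision
  expect_gte(mean(prs[2, ]), 0.8)  # recall
})

test_that("nearest-neighbor group distances are asymmetric means of minima", {
  pos <- data.frame(cell = 1:4, x = c(0, 3, 10, 0), y = c(0, 4, 0, 0))
  expect_equal(nearest_group_distance(pos, 1, 2), 5)
  # coincident cells in distinct groups: distance 0
  expect_equal(nearest_group_distance(pos, 1, 4), 0)
  # X = {(0,0), (10,0)}, Y = {(0,0)}: X->Y mean 5, Y->X mean 0
  expect_equal(nearest_group_distance(pos, c(1, 3), 4), 5)
  expect_equal(nearest_group_distance(pos, 4, c(1, 3)), 0)
  expect_equal(nearest_group_distance(pos, 1, c(1, 3)), 10)  # self excluded
  expect_error(nearest_group_distance(pos, integer(), 1), "nonempty")
})

test_that("membership and position tables round-trip", {
  asg <- ensemble_assignment(list(a = c(1L, 3L), b = integer()), "rank", 1:5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_membership(asg, f)
  expect_equal(read_membership(f), list(a = c(1L, 3L)))
  pos <- generate_positions(10, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_positions(pos, f2)
  expect_equal(read_positions(f2), pos, tolerance = 1e-6)
})
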