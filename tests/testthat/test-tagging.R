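test_that("protocol timelines carry the printed shock times", {
  fc <- build_timeline("FC")
  expect_equal(fc$duration_s, 420)
  expect_equal(fc$shocks$start, c(120, 180, 240, 300))
  expect_equal(fc$shocks$end, c(122, 182, 242, 302))

  imm <- build_timeline("immediate_shock")
  expect_equal(imm$duration_s, 40)
  expect_equal(imm$shocks$start, c(2, 8, 14, 20))

  grp <- build_timeline("grouped_shock")
  expect_equal(grp$duration_s, 300)
  expect_equal(grp$shocks$start, c(120, 126, 132, 138))

  expect_equal(build_timeline("RECALL")$duration_s, 480)
  expect_equal(nrow(build_timeline("RECALL")$shocks), 0)
  expect_error(build_timeline("nope"), "unknown protocol")
})

test_that("shock and pre-shock plans match the protocol geometry", {
  fc <- build_timeline("FC")
  shock <- schedule_tagging("shock", fc)
  expect_equal(nrow(shock$light_epochs), 4)
  expect_equal(shock$light_epochs$start, c(120, 180, 240, 300))
  expect_equal(shock$light_epochs$end, c(130, 190, 250, 310))
  expect_equal(shock$total_light_s, 40)

  pre <- schedule_tagging("pre-shock", fc)
  expect_equal(pre$light_epochs$start, 0)
  expect_equal(pre$light_epochs$end, 120)
})

test_that("freezing plan accumulates bouts after the third shock up to the budget", {
  fc <- build_timeline("FC")
  fr <- 15
  frames_from <- function(t0) {
    mids <- (seq_len(420 * fr) - 0.5) / fr
    labels_from_frames(mids >= t0, fr)
  }
  # frozen continuously from 240 s: eligibility starts at the 3rd shock
  # offset (242 s), so the plan is the single epoch [242, 282)
  plan <- schedule_tagging("freezing", fc, frames_from(240))
  expect_equal(plan$eligibility_start_s, 242)
  expect_equal(nrow(plan$light_epochs), 1)
  expect_equal(plan$light_epochs$start, 242)
  expect_equal(plan$light_epochs$end, 282)
  expect_equal(plan$total_light_s, 40)
  expect_false(plan$shortfall)

  # frozen only from 250 s: accumulation starts where freezing starts
  plan <- schedule_tagging("freezing", fc, frames_from(250))
  expect_equal(plan$light_epochs$start, 250)
  expect_equal(plan$light_epochs$end, 290)

  expect_error(schedule_tagging("freezing", fc), "requires freezing labels")
})

test_that("budget conservation: light equals min(budget, eligible time)", {
  fc <- build_timeline("FC")
  fr <- 15
  set.seed(9)
  for (rep in 1:6) {
    lab <- labels_from_frames(runif(420 * fr) < 0.12, fr)
    for (cond in c("freezing", "no-freezing")) {
      plan <- schedule_tagging(cond, fc, lab)
      elig <- if (cond == "freezing") {
        epoch_duration(epoch_intersect(lab$bouts, epoch_set("w", 242, 420)))
      } else {
        epoch_duration(epoch_intersect(epoch_complement(lab$bouts, 420),
                                       epoch_set("w", 182, 420)))
      }
      expect_equal(plan$total_light_s, min(40, elig), tolerance = 1e-9)
      expect_equal(epoch_duration(plan$light_epochs), plan$total_light_s)
      expect_equal(plan$shortfall, elig < 40 - 1e-9)
    }
  }
})

test_that("freezing and no-freezing plans from the same labels never intersect", {
  fc <- build_timeline("FC")
  set.seed(21)
  for (rep in 1:4) {
    lab <- labels_from_frames(runif(420 * 15) < 0.3, 15)
    a <- schedule_tagging("freezing", fc, lab)$light_epochs
    b <- schedule_tagging("no-freezing", fc, lab)$light_epochs
    expect_equal(nrow(epoch_intersect(a, b)), 0)
  }
})

test_that("recall, sweeping and fixed-window plans follow their protocols", {
  rec <- build_timeline("RECALL")
  fr <- 15
  lab <- labels_from_frames(rep(c(TRUE, FALSE), each = 240 * fr), fr)
  frz <- schedule_tagging("recall-frz", rec, lab)
  expect_equal(frz$light_epochs$start, 0)
  expect_equal(frz$light_epochs$end, 40)
  nofrz <- schedule_tagging("recall-no-frz", rec, lab)
  expect_equal(nofrz$light_epochs$start, 240)
  expect_equal(nofrz$total_light_s, 40)

  sw <- schedule_tagging("sweeping", build_timeline("sweeping"),
                         sweep_epochs = epoch_set("sweep", c(30, 100, 200, 300),
                                                  c(40, 110, 210, 310)))
  expect_equal(sw$total_light_s, 40)

  imm <- schedule_tagging("imm-shock", build_timeline("immediate_shock"))
  expect_equal(imm$light_epochs$start, 0)
  expect_equal(imm$light_epochs$end, 40)

  grp <- schedule_tagging("grouped-shock", build_timeline("grouped_shock"))
  expect_equal(grp$light_epochs$start, 120)
  expect_equal(grp$light_epochs$end, 160)
})
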