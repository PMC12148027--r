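# Event detection from CoP and GRF, stutter exclusion, midstance anchors.

test_that("force-threshold detection finds rising and falling 100 N crossings", {
  rate <- 1000
  t <- seq(0, 3, by = 1 / rate)
  # ramp 0 -> 800 N between 1.0 and 1.2 s: crosses 100 N at 1.025 s
  ramp <- pmin(pmax((t - 1.0) / 0.2, 0), 1) * 800
  ev <- detect_events_force(ramp, rep(0, length(t)), rate)
  hs <- ev[ev$type == "heel_strike" & ev$side == "left", ]
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$time, 1.025, tolerance = 0.005)

  # noise bounded below threshold -> no events
  set.seed(1)
  ev2 <- detect_events_force(runif(3000, 0, 90), runif(3000, 0, 90), rate)
  expect_equal(nrow(ev2), 0L)

  # rectangular stance pulse -> exactly one heel strike and one toe-off
  pulse <- ifelse(t > 1 & t < 1.7, 700, 0)
  ev3 <- detect_events_force(rep(0, length(t)), pulse, rate)
  expect_equal(sum(ev3$type == "heel_strike"), 1L)
  expect_equal(sum(ev3$type == "toe_off"), 1L)
  expect_true(all(ev3$side == "right"))
  expect_lt(ev3$time[ev3$type == "heel_strike"] - 1.0, 0.02)
})

test_that("paired fore-aft / ML candidates keep the earlier event, window by trial kind", {
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  gap <- 0.14   # candidate separation lands between the 150 ms (perturbed)
                # and 200 ms (steady) pairing windows
  cop_x <- -0.2 * t + pmin(pmax((t - 2.0) / 0.15, 0), 1) * 0.8
  cop_y <- pmin(pmax((t - (2.0 + gap)) / 0.15, 0), 1) * 0.25
  steady <- detect_heel_strikes_cop(cop_x, cop_y, rate, "steady")
  expect_equal(nrow(steady), 1L)            # merged within the 200 ms window
  expect_lt(abs(steady$time - 2.0), 0.05)   # the earlier (fore-aft) candidate
  pert <- detect_heel_strikes_cop(cop_x, cop_y, rate, "perturbed")
  expect_equal(nrow(pert), 2L)              # 150 ms window keeps them separate
})

test_that("heel strikes on synthetic steady walking match ground truth within 10 ms", {
  pp <- base_params()
  tr <- generate_trial(pp, "steady", 60, seed = 31)
  gt <- attr(tr, "ground_truth")
  ev <- detect_pipeline(tr)
  expect_equal(sum(ev$valid), nrow(gt$steps))   # no spurious, none missed
  err <- vapply(gt$steps$hs_time,
                function(tt) min(abs(ev$time[ev$valid] - tt)), numeric(1))
  expect_lt(max(err), 0.010)
  idx <- vapply(gt$steps$hs_time,
                function(tt) which.min(abs(ev$time[ev$valid] - tt)), integer(1))
  expect_equal(ev$side[ev$valid][idx], gt$steps$side)
  expect_equal(sum(!ev$valid), 0L)              # clean walking: zero exclusions
})

test_that("stutter steps are excluded and valid heel strikes alternate sides", {
  pp <- base_params()
  pp$stutter_probability <- list(ml_high = 1, ml_low = 1, fa_high = 0, fa_low = 0)
  tr <- generate_trial(pp, "perturbed", seed = 21)
  gt <- attr(tr, "ground_truth")
  expect_gt(nrow(gt$stutters), 0)
  ev <- detect_pipeline(tr)
  valid_t <- ev$time[ev$valid]
  # every injected stutter is excluded: no valid event near a stutter touch
  for (ts in gt$stutters$time) {
    expect_gt(min(abs(valid_t - ts)), 0.15)
  }
  # no proper step is excluded: every true heel strike is matched
  err <- vapply(gt$steps$hs_time, function(tt) min(abs(valid_t - tt)), numeric(1))
  expect_lt(max(err), 0.010)
  expect_equal(length(valid_t), nrow(gt$steps))
  v <- ev[ev$valid, ]
  expect_true(all(v$side[-1] != v$side[-nrow(v)]))
})

test_that("candidates with a raised calcaneus are excluded as marker-height", {
  # one valid strike, then a candidate while the foot marker is at 0.25 m
  marker_time <- seq(0, 3, by = 0.01)
  n <- length(marker_time)
  zl <- ifelse(marker_time > 1.8, 0.25, 0.02)
  mk <- list(
    l_calcaneus = cbind(rep(0.4, n), rep(0.1, n), zl),
    r_calcaneus = cbind(rep(-0.2, n), rep(-0.1, n), rep(0.02, n))
  )
  ev <- gaitbalance:::new_event_table(
    time = c(1.0, 2.0), type = "heel_strike", side = c("left", "left"),
    source = "cop", valid = TRUE, reason = "none")
  out <- exclude_stutter_steps(ev, mk, marker_time)
  expect_true(out$valid[1])
  expect_false(out$valid[2])
  expect_equal(out$reason[2], "marker_height")
})

test_that("midstance is the temporal midpoint of ipsilateral stance", {
  ev <- gaitbalance:::new_event_table(
    time = c(1.0, 1.7, 2.1), type = c("heel_strike", "toe_off", "heel_strike"),
    side = c("left", "left", "left"), source = "force", valid = TRUE,
    reason = "none")
  ms <- find_midstance(ev)
  expect_equal(ms$time, 1.35)            # (1.0 + 1.7) / 2
  expect_equal(nrow(ms), 1L)             # no toe-off after the final strike
})

test_that("detected left-leg midstances coincide with perturbation onsets", {
  pp <- base_params()
  tr <- generate_trial(pp, "perturbed", seed = 33)
  ev <- detect_pipeline(tr)
  fe <- detect_events_force(tr$forces$grf_left, tr$forces$grf_right,
                            tr$meta$force_rate)
  ms <- find_midstance(combine_event_tables(ev, fe))
  lm_t <- ms$time[ms$side == "left"]
  for (on in tr$perturbations$onset_s) {
    expect_lt(min(abs(lm_t - on)), 0.06)
  }
})
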