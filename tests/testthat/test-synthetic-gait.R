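# Synthetic cohort generator: protocol structure, determinism, and the
# statistical ground truth the rest of the pipeline is validated against.

test_that("default cohort has the full subject x condition x trial layout", {
  cohort <- generate_cohort(cohort_config(seed = 7))
  cfg <- cohort$config
  expect_length(cohort$subjects, 10)
  expect_equal(nrow(cohort$ground_truth), 40)
  cc <- cohort$subjects[[3]]$conditions[["eyes_blocked"]]
  expect_named(cc$trials, c("steady_1", "perturbed", "steady_2"))
  pert <- cc$trials$perturbed$perturbations
  expect_equal(nrow(pert), 16)
  tab <- table(pert$direction, pert$magnitude_pct_bw)
  expect_true(all(tab == 2))          # 8 unique types, twice each
  expect_equal(nrow(unique(pert[, c("direction", "magnitude_pct_bw")])), 8)
})

test_that("perturbation onsets sit at left-leg midstances, 25-30 s apart", {
  pp <- base_params()
  sd1 <- generate_step_data(pp, "perturbed", seed = 5)
  pert <- sd1$perturbations
  gaps <- diff(pert$onset_s)
  expect_true(all(gaps >= 25 & gaps <= 30))
  st <- sd1$steps
  expect_true(all(st$side[pert$onset_step] == "left"))
  expect_equal(pert$onset_s, st$ms_time[match(pert$onset_step, st$step)])
  # recording covers >= 10 s before each onset and >= 11 s after
  expect_gte(pert$onset_s[1], 10)
  expect_gte(sd1$duration - pert$onset_s[nrow(pert)], 11)
})

test_that("generation is deterministic and streams are independent per trial", {
  pp <- base_params()
  a <- generate_step_data(pp, "steady", 60, seed = 42)
  b <- generate_step_data(pp, "steady", 60, seed = 42)
  expect_identical(a$steps, b$steps)
  c2 <- generate_step_data(pp, "steady", 60, seed = 43)
  expect_false(isTRUE(all.equal(a$steps$width, c2$steps$width)))
  cohort1 <- generate_cohort(cohort_config(n_subjects = 2,
                                           steady_trial_duration = 40, seed = 9))
  cohort2 <- generate_cohort(cohort_config(n_subjects = 2,
                                           steady_trial_duration = 40, seed = 9))
  expect_identical(cohort1$ground_truth, cohort2$ground_truth)
  expect_identical(cohort1$subjects[[2]]$conditions[[3]]$trials$perturbed$steps,
                   cohort2$subjects[[2]]$conditions[[3]]$trials$perturbed$steps)
})

test_that("unit impairment multipliers leave ground truth at baseline", {
  ones <- list(step_width_sd = 1, step_time_sd = 1, placement_sd = 1,
               divergence = 1, mean_step_width = 1, com_response = 1)
  cfg <- cohort_config(n_subjects = 3, seed = 4,
                       impairment_multipliers = list(ankle_braces = ones,
                                                     eyes_blocked = ones,
                                                     pneumatic_jets = ones))
  cohort <- generate_cohort(cfg)
  gt <- cohort$ground_truth
  for (s in 1:3) {
    g <- gt[gt$subject == s, ]
    expect_equal(length(unique(g$step_width_sd)), 1L)
    expect_equal(length(unique(g$step_time_sd)), 1L)
    expect_equal(length(unique(g$placement_sd)), 1L)
  }
})

test_that("noiseless placement residuals vanish and step counts match duration", {
  pp <- base_params(placement_sd = 0, mean_step_time = 0.55)
  sd0 <- generate_step_data(pp, "steady", 120, seed = 3)
  fit <- fit_foot_placement_model(step_series_from_truth(sd0))
  expect_lt(fit$residual_sd, 1e-10)
  expect_equal(unname(fit$coefficients[2]), pp$placement_gain_position,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[3]), pp$placement_gain_velocity,
               tolerance = 1e-8)
  sd1 <- generate_step_data(base_params(mean_step_time = 0.55), "steady", 180,
                            seed = 3)
  expect_lt(abs(nrow(sd1$steps) - 327), 13)   # ~ duration / mean step time
  expect_error(generate_step_data(base_params(), "steady", 1.5),
               "two strides")
})

test_that("configured step-width SD is recovered at the source over 2000+ steps", {
  pp <- base_params()
  sd1 <- generate_step_data(pp, "steady", 1300, seed = 8)
  expect_gte(nrow(sd1$steps), 2000)
  expect_lt(abs(sd(sd1$steps$width) / pp$step_width_sd - 1), 0.05)
  expect_lt(abs(mean(sd1$steps$width) - pp$mean_step_width),
            3 * pp$step_width_sd / sqrt(nrow(sd1$steps)))
})

test_that("CoP stays in the convex hull of the feet and tracks the stance foot", {
  pp <- base_params()
  tr <- generate_trial(pp, "steady", 30, seed = 6)
  sd1 <- attr(tr, "ground_truth")
  t_f <- tr$force_time
  ctl <- gaitbalance:::foot_contacts(sd1, "left")
  ctr <- gaitbalance:::foot_contacts(sd1, "right")
  fl <- gaitbalance:::foot_trajectory(t_f, ctl, pp$treadmill_speed)
  fr <- gaitbalance:::foot_trajectory(t_f, ctr, pp$treadmill_speed)
  tol <- 1e-9
  expect_true(all(tr$forces$cop_x <= pmax(fl[, 1], fr[, 1]) + tol))
  expect_true(all(tr$forces$cop_x >= pmin(fl[, 1], fr[, 1]) - tol))
  expect_true(all(tr$forces$cop_y <= pmax(fl[, 2], fr[, 2]) + tol))
  expect_true(all(tr$forces$cop_y >= pmin(fl[, 2], fr[, 2]) - tol))
  ss_left <- tr$forces$grf_right < 1e-6 & tr$forces$grf_left > 1
  expect_gt(sum(ss_left), 1000)
  expect_lt(max(abs(tr$forces$cop_x[ss_left] - fl[ss_left, 1])), tol)
  expect_lt(max(abs(tr$forces$cop_y[ss_left] - fl[ss_left, 2])), tol)
})

test_that("invalid configurations are refused with the offending field named", {
  expect_error(cohort_config(marker_rate = -1), "marker_rate")
  expect_error(cohort_config(step_width_sd = 0.005), "placement_residual_sd")
  expect_error(cohort_config(impairment_multipliers = list(
    ankle_braces = list(step_width_sd = -2, step_time_sd = 1, placement_sd = 1,
                        divergence = 1),
    eyes_blocked = list(step_width_sd = 1, step_time_sd = 1, placement_sd = 1,
                        divergence = 1),
    pneumatic_jets = list(step_width_sd = 1, step_time_sd = 1, placement_sd = 1,
                          divergence = 1))),
    "impairment_multipliers")
  expect_error(cohort_config(perturbations = list(count = 7)), "perturbations")
  expect_error(cohort_config(bogus_field = 1), "bogus_field")
})

test_that("trial tables round-trip through the delimited dialect exactly", {
  pp <- base_params()
  tr <- generate_trial(pp, "steady", 8, seed = 2)
  dir <- file.path(tempdir(), "trial_rt")
  write_trial_tables(tr, dir)
  back <- read_trial_tables(dir)
  expect_equal(back$marker_time, tr$marker_time, tolerance = 0)
  for (nm in names(tr$markers)) {
    expect_equal(unname(back$markers[[nm]]), unname(tr$markers[[nm]]),
                 tolerance = 0)
  }
  expect_equal(back$forces$cop_x, tr$forces$cop_x, tolerance = 0)
  expect_equal(back$forces$grf_left, tr$forces$grf_left, tolerance = 0)
  expect_equal(back$meta$body_mass, tr$meta$body_mass, tolerance = 0)
  unlink(dir, recursive = TRUE)
})
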