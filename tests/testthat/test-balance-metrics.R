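# The six balance metrics: step geometry conventions, variability estimators,
# the foot-placement model, stride normalization/embedding/divergence, the
# margin of stability and perturbation CoM displacement, and regime selection.

steps_df <- function(width, side = rep(c("left", "right"), length.out = length(width)),
                     step_time = NULL, time = NULL) {
  n <- length(width)
  data.frame(time = time %||% seq(0.55, by = 0.55, length.out = n),
             side = side,
             width = width,
             step_time = step_time %||% rep(0.55, n),
             placement = ifelse(side == "left", 1, -1) * width)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("step widths are signed ML calcaneus separations at heel strike", {
  marker_time <- seq(0, 4, by = 0.01)
  mk <- list(l_calcaneus = cbind(0.2, 0.10, 0.02),
             r_calcaneus = cbind(-0.2, -0.10, 0.02))
  mk <- lapply(mk, function(m) m[rep(1, length(marker_time)), ])
  ev <- gaitbalance:::new_event_table(
    time = c(1, 1.5), type = "heel_strike", side = c("left", "right"),
    source = "cop", valid = TRUE, reason = "none")
  ss <- compute_step_series(ev, mk, marker_time)
  expect_equal(ss$width, c(0.20, 0.20))           # +0.10 vs -0.10 -> +0.20
  expect_equal(ss$placement, c(0.20, -0.20))
  # crossed configuration: right foot lateral (left) of the left foot
  mk2 <- list(l_calcaneus = mk$r_calcaneus, r_calcaneus = mk$l_calcaneus)
  ss2 <- compute_step_series(ev, mk2, marker_time)
  expect_true(all(ss2$width < 0))
})

test_that("step-width variability is the SD of the first `budget` widths", {
  expect_equal(step_width_variability(steps_df(rep(0.12, 600)), 570), 0)
  set.seed(4)
  w <- rnorm(700, 0.12, 0.025)
  st <- steps_df(w)
  expect_equal(step_width_variability(st, 570), sd(w[1:570]))   # exactly 570 used
  expect_error(step_width_variability(steps_df(w[1:100]), 570), "shortfall")
})

test_that("step-time variability removes left/right asymmetry before pooling", {
  st <- steps_df(rep(0.12, 600),
                 step_time = rep(c(0.60, 0.50), 300))
  expect_equal(step_time_variability(st, 570), 0)   # pure asymmetry -> 0
  set.seed(5)
  tt <- rep(c(0.60, 0.50), 300) + rnorm(600, 0, 0.015)
  st2 <- steps_df(rep(0.12, 600), step_time = tt)
  # oracle: demean per side, concatenate, n-1 SD
  sel <- st2[!is.na(st2$step_time), ][1:570, ]
  l <- sel$step_time[sel$side == "left"]; r <- sel$step_time[sel$side == "right"]
  expect_equal(step_time_variability(st2, 570),
               sd(c(l - mean(l), r - mean(r))))
  expect_lt(abs(step_time_variability(st2, 570) - 0.015), 0.0025)
})

test_that("variability metrics are location invariant and scale linearly", {
  set.seed(6)
  w <- rnorm(600, 0.12, 0.03)
  base <- step_width_variability(steps_df(w), 570)
  expect_equal(step_width_variability(steps_df(w + 0.05), 570), base)
  expect_equal(step_width_variability(steps_df(2 * w), 570), 2 * base)
})

test_that("the placement model recovers a known law and its residual scale", {
  set.seed(7)
  n <- 700
  x1 <- rnorm(n, 0.09, 0.02)
  x2 <- rnorm(n, 0.15, 0.05)
  sigma <- 0.012
  eps <- rnorm(n, 0, sigma)
  st <- steps_df(rep(0.12, n))
  st$com_ms_rel <- x1; st$com_ms_vel <- x2
  st$placement <- 0.01 + 1.3 * x1 + 0.25 * x2 + eps
  fit <- fit_foot_placement_model(st)
  expect_equal(unname(fit$coefficients), c(0.01, 1.3, 0.25), tolerance = 0.05)
  est <- foot_placement_predictability(st, 570)
  band <- sigma * sqrt(qchisq(c(0.005, 0.995), 567) / 569)
  expect_gt(est, band[1]); expect_lt(est, band[2])
  # noiseless: exact recovery
  st$placement <- 0.01 + 1.3 * x1 + 0.25 * x2
  expect_lt(foot_placement_predictability(st, 570), 1e-12)
  # constant regressor is refused
  st$com_ms_vel <- 0.15
  expect_error(fit_foot_placement_model(st), "rank-deficient|constant")
})

test_that("two subjects with different laws yield distinct fitted models", {
  mk_steps <- function(b1, seed) {
    set.seed(seed)
    st <- steps_df(rep(0.12, 600))
    st$com_ms_rel <- rnorm(600, 0.09, 0.02)
    st$com_ms_vel <- rnorm(600, 0.15, 0.05)
    st$placement <- b1 * st$com_ms_rel + 0.25 * st$com_ms_vel + rnorm(600, 0, 0.005)
    st
  }
  f1 <- fit_foot_placement_model(mk_steps(1.0, 1))
  f2 <- fit_foot_placement_model(mk_steps(1.8, 2))
  expect_gt(abs(f1$coefficients[2] - f2$coefficients[2]), 0.5)
})

test_that("predictability never exceeds the placement SD on the same steps", {
  for (s in 1:5) {
    sd1 <- generate_step_data(base_params("pneumatic_jets"), "steady", 340,
                              seed = s)
    st <- step_series_from_truth(sd1)
    st <- st[complete.cases(st[, c("placement", "com_ms_rel", "com_ms_vel")]), ]
    st <- st[1:570, ]
    expect_lte(foot_placement_predictability(st, 570),
               sd(st$placement) + 1e-12)
  }
})

test_that("stride normalization preserves endpoints and budgets", {
  time <- seq(0, 12, by = 0.01)
  strides <- data.frame(start = seq(0, 10.9, by = 1.1)[1:10],
                        end = seq(1.1, 11.0, by = 1.1)[1:10])
  const <- time_normalize_strides(rep(2.5, length(time)), time, strides)
  expect_equal(dim(const$values), c(1000L, 1L))
  expect_true(all(const$values == 2.5))
  lin <- time_normalize_strides(3 * time, time, strides)
  v1 <- lin$values[lin$stride == 1, 1]
  expect_equal(v1[1], 0, tolerance = 1e-9)
  expect_equal(v1[100], 3 * 1.1, tolerance = 1e-9)
  expect_equal(max(abs(diff(diff(v1)))), 0, tolerance = 1e-9)  # linear
  expect_error(time_normalize_strides(rep(1, length(time)), time,
                                      data.frame(start = 0, end = 0.015)),
               "3 raw samples")
  # 144 strides in -> 144 x 100 stack
  t2 <- seq(0, 160, by = 0.01)
  s144 <- data.frame(start = seq(0, by = 1.1, length.out = 144),
                     end = seq(1.1, by = 1.1, length.out = 144))
  stk <- time_normalize_strides(sin(t2), t2, s144)
  expect_equal(nrow(stk$values), 144L * 100L)
})

test_that("delay embedding has dimension 3d and respects segment arithmetic", {
  stk <- make_stack(6, function(k, s) cbind(sin(2 * pi * s), cos(2 * pi * s), s + k))
  emb <- delay_embed(stk, d = 5, delay = 10)
  expect_equal(ncol(emb$values), 15L)
  expect_equal(nrow(emb$values), 600L - 40L)    # L - (d-1)*delay per segment
  emb1 <- delay_embed(stk, d = 1, delay = 10)
  expect_equal(emb1$values, stk$values)         # d = 1 is the identity
  stk2 <- make_stack(6, function(k, s) cbind(s, s, s), strides_per_segment = 3)
  emb2 <- delay_embed(stk2, d = 5, delay = 10)
  expect_equal(nrow(emb2$values), 2L * (300L - 40L))
  expect_error(delay_embed(make_stack(1, function(k, s) cbind(s, s, s), sps = 30L)),
               "lookahead")
})

test_that("divergence slope recovers a prescribed exponential rate", {
  for (lam in c(0.35, 0.5)) {
    fit <- max_lyapunov(delay_embed(make_divergent_stack(216, lam)))
    expect_lt(abs(fit$lambda - lam) / lam, 0.05)
  }
})

test_that("near-periodic strides give a near-zero exponent", {
  set.seed(9)
  eps <- 1e-4
  stk <- make_stack(60, function(k, s) {
    cbind(sin(2 * pi * s), cos(2 * pi * s), sin(4 * pi * s)) +
      matrix(rnorm(300, 0, eps), ncol = 3)
  })
  fit <- max_lyapunov(delay_embed(stk))
  expect_lt(abs(fit$lambda), 0.1)
})

test_that("generator divergence multiplier raises the estimated exponent", {
  cfg <- cohort_config(seed = 7)
  sp <- draw_subject_params(cfg, 1)
  for (s in c(51, 52)) {
    l_norm <- trial_lambda(condition_params(cfg, sp, "normal"), seed = s,
                           n_sections = 8, strides_per_section = 9)
    l_imp <- trial_lambda(condition_params(cfg, sp, "pneumatic_jets"), seed = s,
                          n_sections = 8, strides_per_section = 9)
    expect_gt(l_imp, l_norm)
  }
})

test_that("stride plans give 8x9 steady sections and perturbation windows with onset in stride five", {
  left_hs <- seq(0, by = 1.1, length.out = 164)   # one ~3 min steady trial
  plan <- lyapunov_stride_plan(left_hs, n_sections = 8, strides_per_section = 9)
  expect_equal(nrow(plan), 72L)
  expect_equal(as.integer(table(plan$segment)), rep(9L, 8))
  expect_true(all(plan$end > plan$start))
  # perturbed plan: 9 strides per perturbation, onset inside the fifth
  onsets <- c(30.2, 66.9)
  pp <- lyapunov_stride_plan(left_hs, onsets = onsets, strides_per_section = 9)
  expect_equal(nrow(pp), 18L)
  for (i in seq_along(onsets)) {
    w <- pp[pp$segment == i, ]
    expect_equal(nrow(w), 9L)
    expect_gte(onsets[i], w$start[5])
    expect_lt(onsets[i], w$end[5])
  }
  expect_error(lyapunov_stride_plan(left_hs[1:6], onsets = 2.0),
               "shortfall")
})

test_that("margin of stability follows the extrapolated-CoM geometry", {
  expect_equal(round(xcom_offset(0.3132, 1, 9.81), 3), 0.100)
  # static limit: zero CoM velocity -> margin is the plain ML distance
  n <- 70000
  rate <- 100
  com <- structure(list(
    position = matrix(rep(c(0, 0, 0.9), each = n), ncol = 3),
    velocity = matrix(0, n, 3), rate = rate), class = "com_state")
  marker_time <- (seq_len(n) - 1) / rate
  mk <- list(l_ankle = matrix(rep(c(0.05, 0.08, 0.08), each = n), ncol = 3),
             r_ankle = matrix(rep(c(0.05, -0.08, 0.08), each = n), ncol = 3),
             l_meta5 = matrix(rep(c(0.2, 0.15, 0.02), each = n), ncol = 3),
             r_meta5 = matrix(rep(c(0.2, -0.15, 0.02), each = n), ncol = 3))
  ev <- gaitbalance:::new_event_table(
    time = seq(1, by = 1, length.out = 600),
    type = "heel_strike", side = rep(c("left", "right"), 300),
    source = "cop", valid = TRUE, reason = "none")
  mos <- margin_of_stability(com, mk, marker_time, ev, "lateral", budget = 570)
  expect_equal(mos, 0.15, tolerance = 1e-9)   # sign-flipped pooling of sides
  # budget rule: only the first 570 steps enter the mean
  mk2 <- mk
  mk2$l_meta5[marker_time > 575, 2] <- 0.50
  mk2$r_meta5[marker_time > 575, 2] <- -0.50
  mos2 <- margin_of_stability(com, mk2, marker_time, ev, "lateral", budget = 570)
  expect_equal(mos2, 0.15, tolerance = 1e-9)
  # anterior axis: no side flip; static limit is the fore-aft distance
  mos_a <- margin_of_stability(com, mk, marker_time, ev, "anterior", budget = 570)
  expect_equal(mos_a, 0.2, tolerance = 1e-9)
  expect_error(margin_of_stability(com, mk, marker_time, ev[1:100, ], budget = 570),
               "shortfall")
})

test_that("CoM displacement averages the two qualifying perturbations only", {
  com_time <- seq(0, 60, by = 0.01)
  lm_t <- seq(5, 55, by = 1.1)
  ms <- data.frame(time = lm_t, side = "left")
  # CoM steps 0.05 m rightward (negative y) after onsets at lm_t[5], lm_t[20]
  y <- rep(0, length(com_time))
  y[com_time >= lm_t[5] + 0.2] <- -0.05
  y[com_time >= lm_t[20] + 0.2] <- -0.10
  pert <- data.frame(
    onset_s = c(lm_t[5], lm_t[20], lm_t[10], lm_t[14], lm_t[25]),
    direction = c("rightward", "rightward", "leftward", "rightward", "forward"),
    magnitude_pct_bw = c(7.5, 7.5, 7.5, 15, 7.5))
  d <- com_displacement(y, com_time, ms, pert)
  expect_equal(d, 0.05, tolerance = 1e-9)
  # identical CoM at both midstances -> 0
  d0 <- com_displacement(rep(0.3, length(com_time)), com_time, ms, pert)
  expect_equal(d0, 0)
  expect_error(com_displacement(y, com_time, ms, pert[-1, ]),
               "fewer than two qualifying")
})

test_that("CoM displacement matches the generator's injected response", {
  pp <- base_params(step_width_sd = 2e-6, placement_sd = 1e-6,
                    step_time_sd = 1e-6, com_midstance_speed_sd = 0)
  sd0 <- generate_step_data(pp, "perturbed", seed = 3)
  st <- sd0$steps
  q <- sd0$perturbations
  q <- q[q$direction == "rightward" & q$magnitude_pct_bw == 7.5, ]
  for (k in q$onset_step) {
    d <- -(st$com_ms_y[st$step == k + 2] - st$com_ms_y[st$step == k])
    expect_equal(d, pp$com_response_displacement, tolerance = 0.01)
  }
})

test_that("regime selection applies the pre- and post-perturbation windows", {
  pp <- base_params()
  sd1 <- generate_step_data(pp, "perturbed", seed = 13)
  steps <- step_series_from_truth(sd1)
  steps$trial_kind <- "perturbed"
  pert <- sd1$perturbations
  post <- select_regime(steps, pert, "perturbation_only")
  # ~16 perturbations x 7 s of post windows at the generator's step rate
  expect_gt(nrow(post), 150)
  expect_lt(nrow(post), 260)
  for (i in seq_len(nrow(post))) {
    dt <- post$time[i] - pert$onset_s
    expect_true(any(dt > 0 & dt <= 7))
  }
  steady_sel <- select_regime(steps, pert, "steady")
  for (i in seq_len(nrow(steady_sel))) {
    dt <- steady_sel$time[i] - pert$onset_s
    expect_true(any(dt > 18 & dt <= 23))
  }
  # steady trials contribute wholesale; zero perturbations -> empty post set
  sd2 <- generate_step_data(pp, "steady", 60, seed = 14)
  st2 <- step_series_from_truth(sd2)
  st2$trial_kind <- "steady"
  expect_equal(nrow(select_regime(st2, NULL, "perturbation_only")), 0L)
  expect_equal(nrow(select_regime(st2, NULL, "steady")), nrow(st2))
  both <- rbind(cbind(st2, trial = "steady"),
                cbind(steps, trial = "perturbed")[, c(names(st2), "trial")])
  pert$trial <- "perturbed"
  sp <- select_regime(both, pert, "steady_plus_perturbation")
  expect_gte(nrow(sp), nrow(st2) + 150)
})
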