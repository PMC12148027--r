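# Shared fixtures, all built in code.

# resolved parameter list for one subject x condition, with optional overrides
base_params <- function(cond = "normal", cfg_seed = 7, subject = 1, ...) {
  cfg <- cohort_config(seed = cfg_seed)
  pp <- condition_params(cfg, draw_subject_params(cfg, subject), cond)
  utils::modifyList(pp, list(...))
}

# run the CoP detector + stutter exclusion on a synthesized trial
detect_pipeline <- function(trial) {
  ev <- detect_heel_strikes_cop(trial$forces$cop_x, trial$forces$cop_y,
                                trial$meta$force_rate,
                                if (trial$meta$kind == "perturbed") "perturbed" else "steady")
  exclude_stutter_steps(ev, trial$markers, trial$marker_time)
}

# score table for detection tests: one unimpaired + k impaired per subject
make_scores <- function(values, n_subjects = 10, n_impaired = 3,
                        higher_is_worse = TRUE) {
  conds <- c("unimpaired", paste0("imp", seq_len(n_impaired)))
  grid <- expand.grid(condition = conds, subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  data.frame(subject = grid$subject, condition = grid$condition,
             impaired = grid$condition != "unimpaired",
             value = values, higher_is_worse = higher_is_worse)
}

# stride stack built from a per-stride 3-D generator function f(stride, s01)
make_stack <- function(n_strides, f, sps = 100L, strides_per_segment = n_strides) {
  s01 <- seq(0, 1, length.out = sps + 1L)[seq_len(sps)]
  vals <- do.call(rbind, lapply(seq_len(n_strides), function(k) f(k, s01)))
  structure(list(values = vals,
                 stride = rep(seq_len(n_strides), each = sps),
                 segment = rep(ceiling(seq_len(n_strides) / strides_per_segment),
                               each = sps),
                 samples_per_stride = as.integer(sps)),
            class = "stride_stack")
}

# stride stack with a prescribed divergence rate. A strong shared periodic
# orbit phase-locks nearest neighbors, so the base cancels out of every pair
# distance. The deviation carries independent chaotic chains from a zigzag
# (fold) map whose slope magnitude is exp(lam) everywhere, so *every*
# neighbor-pair difference multiplies by exactly exp(lam) per stride; with
# exp(lam * s) within-stride growth, each record's log distance is exactly
# linear in time with slope lam, and the chain states are stationary, so
# initial distances are unrelated to record position.
make_divergent_stack <- function(n_strides, lam, strides_per_segment = n_strides,
                                 seed = 7, amplitude = 0.02) {
  stopifnot(lam > 0, lam <= log(2))
  rho <- exp(lam)
  tri <- function(y) { y2 <- y %% 2; 1 - abs(1 - y2) }
  states <- withr::with_seed(seed, {
    a <- numeric(n_strides + 1L)
    a[1] <- runif(1, 0.05, 0.95)
    for (k in seq_len(n_strides)) {
      a[k + 1L] <- tri(rho * a[k] + runif(1, 0, 1e-9))
    }
    a
  })
  # one chaotic axis: 1-D states give tight nearest-neighbor matching, so
  # neighbor intervals almost never straddle a fold of the map
  make_stack(n_strides, function(k, s) {
    dev <- amplitude * (states[k] - 0.5) * exp(lam * s)
    cbind(sin(2 * pi * s) + dev, cos(2 * pi * s), sin(4 * pi * s))
  }, strides_per_segment = strides_per_segment)
}

# estimate the Lyapunov exponent of a steady trial's C7 signal
trial_lambda <- function(params, seed, n_sections = 8, strides_per_section = 9) {
  tr <- generate_trial(params, "steady", 180, seed = seed, channels = "markers")
  gt <- attr(tr, "ground_truth")
  lhs <- gt$steps$hs_time[gt$steps$side == "left"]
  plan <- lyapunov_stride_plan(lhs, n_sections = n_sections,
                               strides_per_section = strides_per_section)
  v <- c7_velocity(tr$markers$c7, tr$meta$marker_rate)
  max_lyapunov(delay_embed(time_normalize_strides(v, tr$marker_time, plan)))$lambda
}
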