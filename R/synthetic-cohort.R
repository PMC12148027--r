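# Cohort assembly: per-subject baselines, per-condition multipliers, and the
# subject x condition x trial layout (steady ~3 min, perturbation bout,
# steady ~3 min), mirroring the protocol the analysis assumes.

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Draw one subject's baseline gait parameters
#'
#' Baselines are drawn once per subject and shared across that subject's
#' conditions, so inter-subject offsets are unrelated to impairment. A single
#' latent variability scale multiplies the subject's step-width SD, step-time
#' SD and placement residual SD together; its spread is set by
#' `inter_subject_sd$placement_noise` relative to the base placement SD.
#'
#' @param config a [cohort_config()].
#' @param subject integer subject index (1-based).
#' @return a named list of subject-level parameters.
#' @export
draw_subject_params <- function(config, subject) {
  cfg <- config
  with_rng(derive_seed(cfg$seed, subject, 0L, 0L), {
    iss <- cfg$inter_subject_sd
    rel <- iss$placement_noise / cfg$placement_residual_sd
    scale <- rnorm_trunc(1, 1, rel, lo = 0.4)
    list(
      subject = subject,
      body_mass = rnorm_trunc(1, 68, 13, lo = 45, hi = 110),
      mean_step_width = rnorm_trunc(1, cfg$mean_step_width, iss$step_width, lo = 0.05),
      mean_step_time = rnorm_trunc(1, cfg$mean_step_time, iss$step_time,
                                   lo = 0.42, hi = 0.70),
      variability_scale = scale,
      step_width_sd = cfg$step_width_sd * scale,
      step_time_sd = cfg$step_time_sd * scale,
      placement_sd = cfg$placement_residual_sd * scale,
      divergence_rate = cfg$divergence_rate * rnorm_trunc(1, 1, 0.08, lo = 0.7)
    )
  })
}

#' Resolve the flat parameter list for one subject x condition
#'
#' Applies the condition's impairment multipliers to the subject's baseline
#' parameters. The unimpaired condition uses multipliers of exactly 1, so
#' setting every impairment multiplier to 1 makes impaired and unimpaired
#' ground truths identical per subject.
#'
#' @param config a [cohort_config()].
#' @param subject_params output of [draw_subject_params()].
#' @param condition a condition label from `config$conditions`.
#' @return a flat named list consumed by [generate_step_data()] and
#'   [generate_trial()].
#' @export
condition_params <- function(config, subject_params, condition) {
  cfg <- config
  sp <- subject_params
  if (!condition %in% cfg$conditions) {
    stop(sprintf("unknown condition `%s`", condition), call. = FALSE)
  }
  m <- list(step_width_sd = 1, step_time_sd = 1, placement_sd = 1,
            divergence = 1, mean_step_width = 1, com_response = 1)
  if (condition != cfg$unimpaired_condition) {
    m <- utils::modifyList(m, cfg$impairment_multipliers[[condition]])
  }
  drift <- cfg$drift_per_min %||% list()
  list(
    subject = sp$subject,
    condition = condition,
    unimpaired = condition == cfg$unimpaired_condition,
    body_mass = sp$body_mass,
    treadmill_speed = cfg$treadmill_speed,
    steady_trial_duration = cfg$steady_trial_duration,
    mean_step_width = sp$mean_step_width * m$mean_step_width,
    mean_step_time = sp$mean_step_time,
    step_time_asymmetry = cfg$step_time_asymmetry,
    stance_fraction = cfg$stance_fraction,
    step_width_sd = sp$step_width_sd * m$step_width_sd,
    step_time_sd = sp$step_time_sd * m$step_time_sd,
    placement_sd = sp$placement_sd * m$placement_sd,
    placement_gain_position = cfg$placement_gain_position,
    placement_gain_velocity = cfg$placement_gain_velocity,
    com_midstance_speed = cfg$com_midstance_speed,
    com_midstance_speed_sd = cfg$com_midstance_speed_sd,
    divergence_rate = min(sp$divergence_rate * m$divergence, 0.66),
    c7_periodic_amplitude = unlist(cfg$c7_periodic_amplitude),
    c7_deviation_amplitude = cfg$c7_deviation_amplitude,
    c7_noise_sd = cfg$c7_noise_sd,
    com_response_displacement = cfg$com_response_displacement,
    com_response_mult = m$com_response,
    perturbations = list(
      count = cfg$perturbations$count,
      magnitudes_pct_bw = unlist(cfg$perturbations$magnitudes_pct_bw),
      duration_s = cfg$perturbations$duration_s,
      directions = unlist(cfg$perturbations$directions),
      spacing_s = unlist(cfg$perturbations$spacing_s)
    ),
    stutter_probability = cfg$stutter_probability,
    marker_rate = cfg$marker_rate,
    force_rate = cfg$force_rate,
    drift_step_time_sd = drift$step_time_sd %||% 0,
    drift_step_width_sd = drift$step_width_sd %||% 0,
    drift_mean_step_width = drift$mean_step_width %||% 0
  )
}

#' Generate a synthetic cohort
#'
#' Builds the full subject x condition x trial layout at the step level: for
#' every subject and condition, two steady-state trials and one perturbation
#' bout (16 perturbations, 8 unique direction x magnitude types twice each, in
#' pseudorandom order, onsets at left-leg midstance). Each trial has its own
#' RNG stream derived from the root seed and the (subject, condition, trial)
#' triple, so the same configuration and seed always reproduce an identical
#' cohort and regenerating one trial never shifts another. Continuous signals
#' are synthesized on demand with [synthesize_trial()] to keep the cohort
#' object small.
#'
#' @param config a [cohort_config()].
#' @return an object of class `gait_cohort`: list with `config`, `subjects`
#'   (nested subject -> condition -> trials of class `step_data`) and
#'   `ground_truth`, a data.frame of the true generating parameters per
#'   subject x condition.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2,
#'                                         steady_trial_duration = 40, seed = 3))
#' cohort$ground_truth
generate_cohort <- function(config) {
  cfg <- config
  if (!inherits(cfg, "cohort_config")) cfg <- validate_cohort_config(cfg)
  subjects <- vector("list", cfg$n_subjects)
  gt <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sp <- draw_subject_params(cfg, s)
    conds <- stats::setNames(vector("list", length(cfg$conditions)), cfg$conditions)
    for (ci in seq_along(cfg$conditions)) {
      cond <- cfg$conditions[ci]
      pp <- condition_params(cfg, sp, cond)
      trials <- list(
        steady_1 = generate_step_data(pp, "steady", cfg$steady_trial_duration,
                                      seed = derive_seed(cfg$seed, s, ci, 1L)),
        perturbed = generate_step_data(pp, "perturbed",
                                       seed = derive_seed(cfg$seed, s, ci, 2L)),
        steady_2 = generate_step_data(pp, "steady", cfg$steady_trial_duration,
                                      seed = derive_seed(cfg$seed, s, ci, 3L))
      )
      for (t in seq_along(trials)) {
        trials[[t]]$seed <- derive_seed(cfg$seed, s, ci, t)
      }
      conds[[cond]] <- list(params = pp, trials = trials)
      gt[[length(gt) + 1L]] <- data.frame(
        subject = s, condition = cond, unimpaired = pp$unimpaired,
        step_width_sd = pp$step_width_sd,
        step_time_sd = pp$step_time_sd,
        placement_sd = pp$placement_sd,
        divergence_rate = pp$divergence_rate,
        mean_step_width = pp$mean_step_width,
        com_response_disp = pp$com_response_displacement * pp$com_response_mult
      )
    }
    subjects[[s]] <- list(params = sp, conditions = conds)
  }
  structure(list(config = cfg, subjects = subjects,
                 ground_truth = do.call(rbind, gt)),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %d conditions, 3 trials each (seed %d)\n",
              x$config$n_subjects, length(x$config$conditions), x$config$seed))
  invisible(x)
}
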