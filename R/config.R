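#' Configuration for a synthetic gait cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' are read from the package's parameter file
#' (`system.file("extdata", "default_cohort_params.yaml", package = "gaitbalance")`),
#' which documents every magnitude. The perturbation protocol defaults (16
#' perturbations per bout, 7.5% or 15% bodyweight for 300 ms, four directions,
#' 25-30 s apart, onset at left-leg midstance) match the experimental protocol
#' the analysis assumes; the kinematic and noise magnitudes are invented,
#' field-realistic values and are fully tunable here.
#'
#' @param ... named overrides of any top-level field of the parameter file,
#'   e.g. `n_subjects = 4`, `steady_trial_duration = 60`,
#'   `impairment_multipliers = list(...)`.
#' @param seed integer root seed. Every trial derives its own RNG stream from
#'   this seed and the (subject, condition, trial) triple, so the same
#'   configuration and seed always regenerate an identical cohort.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, steady_trial_duration = 40, seed = 1)
#' cfg$perturbations$count
cohort_config <- function(..., seed = 1L) {
  path <- system.file("extdata", "default_cohort_params.yaml",
                      package = "gaitbalance")
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop_config("...", "overrides must be named")
    }
    unknown <- setdiff(names(over), c(names(cfg), "seed"))
    if (length(unknown)) {
      stop_config(unknown[1], "not a recognised configuration field")
    }
    for (nm in names(over)) {
      if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  cfg$seed <- as.integer(seed)
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  pos_scalar <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_config(field, "must be a single positive finite number")
    }
  }
  for (f in c("n_subjects", "treadmill_speed", "steady_trial_duration",
              "mean_step_width", "mean_step_time", "step_width_sd",
              "step_time_sd", "placement_residual_sd",
              "placement_gain_position", "divergence_rate",
              "marker_rate", "force_rate", "stance_fraction",
              "com_response_displacement")) {
    pos_scalar(f)
  }
  if (cfg$stance_fraction >= 1) {
    stop_config("stance_fraction", "must be below 1")
  }
  if (cfg$placement_residual_sd >= cfg$step_width_sd) {
    stop_config("placement_residual_sd",
                "must be smaller than step_width_sd (the residual cannot exceed the total placement spread)")
  }
  if (!is.character(cfg$conditions) || length(cfg$conditions) < 2L ||
      anyDuplicated(cfg$conditions)) {
    stop_config("conditions", "must be >= 2 distinct labels")
  }
  if (sum(cfg$conditions == cfg$unimpaired_condition) != 1L) {
    stop_config("unimpaired_condition",
                "exactly one condition must be flagged unimpaired")
  }
  impaired <- setdiff(cfg$conditions, cfg$unimpaired_condition)
  mult <- cfg$impairment_multipliers
  if (!setequal(names(mult), impaired)) {
    stop_config("impairment_multipliers",
                "must provide one multiplier set per impaired condition")
  }
  for (cc in impaired) {
    m <- unlist(mult[[cc]])
    if (!all(is.finite(m)) || any(m <= 0)) {
      stop_config("impairment_multipliers", sprintf("all multipliers for `%s` must be > 0", cc))
    }
    need <- c("step_width_sd", "step_time_sd", "placement_sd", "divergence")
    if (!all(need %in% names(m))) {
      stop_config("impairment_multipliers",
                  sprintf("`%s` must name %s", cc, paste(need, collapse = ", ")))
    }
    # scaled law must keep a positive CoM-explained share of width variance
    if ((m[["step_width_sd"]] * cfg$step_width_sd)^2 <=
        (m[["placement_sd"]] * cfg$placement_residual_sd)^2) {
      stop_config("impairment_multipliers",
                  sprintf("`%s`: placement_sd multiplier implies residual SD >= step-width SD", cc))
    }
  }
  pp <- cfg$perturbations
  if (pp$count < 1 || pp$count %% length(pp$directions) %%
      length(pp$magnitudes_pct_bw) < 0) {
    stop_config("perturbations", "count must be positive")
  }
  n_types <- length(pp$directions) * length(pp$magnitudes_pct_bw)
  if (pp$count %% n_types != 0) {
    stop_config("perturbations",
                sprintf("count must be a multiple of the %d unique types", n_types))
  }
  if (pp$duration_s <= 0 || any(pp$magnitudes_pct_bw <= 0)) {
    stop_config("perturbations", "duration and magnitudes must be > 0")
  }
  if (length(pp$spacing_s) != 2L || diff(pp$spacing_s) < 0 || pp$spacing_s[1] <= 0) {
    stop_config("perturbations", "spacing_s must be an increasing positive pair")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects x %d conditions (unimpaired: %s)\n",
              x$n_subjects, length(x$conditions), x$unimpaired_condition))
  cat(sprintf("  treadmill %.2f m/s, steady trials %.0f s, %d perturbations/bout\n",
              x$treadmill_speed, x$steady_trial_duration, x$perturbations$count))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
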