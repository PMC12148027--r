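# Step-based balance metrics: step-width variability, step-time variability,
# and foot-placement predictability. All three enforce the fixed step budget
# (570 steps) so any two subjects/conditions are compared on identical step
# counts, and all use the n-1 standard-deviation convention.

take_budget <- function(steps, budget, what) {
  n <- nrow(steps)
  if (n < budget) {
    stop(sprintf("shortfall: %s needs %d steps, only %d available%s",
                 what, budget, n,
                 if (!is.null(attr(steps, "label"))) {
                   paste0(" for ", attr(steps, "label"))
                 } else ""),
         call. = FALSE)
  }
  steps[seq_len(budget), , drop = FALSE]
}

#' Step-width variability
#'
#' Standard deviation of the first `budget` chronological signed step widths
#' of the selected regime. Higher variability indicates worse balance.
#'
#' @param steps a `step_series` data.frame (regime already selected).
#' @param budget fixed number of steps (default 570); computing on fewer
#'   steps is refused so variability estimates are never biased by unequal
#'   step counts.
#' @return the step-width SD in meters (single numeric).
#' @export
step_width_variability <- function(steps, budget = 570) {
  sel <- take_budget(steps, budget, "step-width variability")
  stats::sd(sel$width)
}

#' Step-time variability
#'
#' Left-landing and right-landing step times are demeaned separately (so
#' left/right asymmetry does not inflate the estimate), pooled, and the
#' standard deviation of the pooled sample is returned. Higher variability
#' indicates worse balance.
#'
#' @inheritParams step_width_variability
#' @return the step-time SD in seconds (single numeric).
#' @export
step_time_variability <- function(steps, budget = 570) {
  steps <- steps[!is.na(steps$step_time), , drop = FALSE]
  sel <- take_budget(steps, budget, "step-time variability")
  left <- sel$step_time[sel$side == "left"]
  right <- sel$step_time[sel$side == "right"]
  pooled <- c(left - mean(left), right - mean(right))
  stats::sd(pooled)
}

#' Fit the linear foot-placement model
#'
#' Ordinary least squares with intercept: ML placement of the swing
#' calcaneus relative to the stance calcaneus at heel strike, explained by
#' the ML CoM position relative to the stance calcaneus and the lab-frame ML
#' CoM velocity, both at the stance foot's midstance. One model is fitted
#' per subject and condition.
#'
#' @param steps a `step_series` with `placement`, `com_ms_rel`, `com_ms_vel`.
#' @return list with `coefficients` (intercept, position gain, velocity
#'   gain), `residual_sd` (SD of the prediction errors, n-1 denominator),
#'   `n`, and the `lm` fit.
#' @export
fit_foot_placement_model <- function(steps) {
  d <- steps[stats::complete.cases(steps[, c("placement", "com_ms_rel",
                                             "com_ms_vel")]), ]
  if (nrow(d) < 4L) stop("too few steps to fit the placement model", call. = FALSE)
  if (stats::sd(d$com_ms_rel) < 1e-12 || stats::sd(d$com_ms_vel) < 1e-12) {
    stop("rank-deficient inputs: constant regressor in the placement model",
         call. = FALSE)
  }
  fit <- stats::lm(placement ~ com_ms_rel + com_ms_vel, data = d)
  if (fit$rank < 3L) {
    stop("rank-deficient inputs in the placement model", call. = FALSE)
  }
  list(coefficients = stats::coef(fit),
       residual_sd = stats::sd(stats::residuals(fit)),
       n = nrow(d),
       fit = fit)
}

#' Foot-placement predictability
#'
#' The standard deviation of the foot-placement model's prediction errors
#' over the first `budget` steps: the part of ML foot-placement variability
#' not explained by CoM state at midstance. Higher values (less predictable
#' placement) indicate worse balance.
#'
#' @inheritParams step_width_variability
#' @return residual SD in meters (single numeric).
#' @export
foot_placement_predictability <- function(steps, budget = 570) {
  steps <- steps[stats::complete.cases(steps[, c("placement", "com_ms_rel",
                                                 "com_ms_vel")]), ]
  sel <- take_budget(steps, budget, "foot-placement predictability")
  fit_foot_placement_model(sel)$residual_sd
}
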