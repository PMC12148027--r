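# Per-step geometry (signed width, step time, lateral placement, CoM state
# at the preceding midstance) and the data-regime selection rules.

#' Compute the per-step series from events and markers
#'
#' For every valid heel strike: the signed step width is the ML distance
#' between the two calcaneus markers at that instant (positive = uncrossed,
#' i.e. the left heel lateral of the right heel; negative = crossed feet);
#' the step time is the interval since the previous valid (contralateral)
#' heel strike; the lateral placement is the ML position of the landing
#' (swing) calcaneus relative to the stance calcaneus. If a CoM state and
#' midstance table are supplied, each step also records the ML CoM position
#' relative to the stance calcaneus and the lab-frame ML CoM velocity at the
#' stance foot's midstance, the inputs of the foot-placement model.
#'
#' @param events a `gait_event_table` with valid heel strikes.
#' @param markers named list with `l_calcaneus` / `r_calcaneus` matrices.
#' @param marker_time marker time vector, s.
#' @param com optional `com_state` from [estimate_com()].
#' @param midstances optional data.frame from [find_midstance()].
#' @return a `step_series` data.frame: columns `time`, `side`, `width`,
#'   `step_time`, `placement`, and (when `com` is given) `com_ms_rel`,
#'   `com_ms_vel`.
#' @export
compute_step_series <- function(events, markers, marker_time,
                                com = NULL, midstances = NULL) {
  hs <- events[events$valid & events$type == "heel_strike", ]
  if (nrow(hs) < 2L) {
    stop("need at least two valid heel strikes", call. = FALSE)
  }
  if (is.null(markers$l_calcaneus) || is.null(markers$r_calcaneus)) {
    stop("calcaneus markers are required", call. = FALSE)
  }
  at <- function(mat, col, tt) stats::approx(marker_time, mat[, col], tt,
                                             rule = 2)$y
  yl <- at(markers$l_calcaneus, 2L, hs$time)
  yr <- at(markers$r_calcaneus, 2L, hs$time)
  width <- yl - yr
  sgn <- ifelse(hs$side == "left", 1, -1)
  out <- data.frame(
    time = hs$time,
    side = hs$side,
    width = width,
    step_time = c(NA_real_, diff(hs$time)),
    placement = sgn * width
  )
  if (!is.null(com)) {
    if (is.null(midstances)) {
      stop("`midstances` must accompany `com`", call. = FALSE)
    }
    ctime <- (seq_len(nrow(com$position)) - 1L) / com$rate
    com_y <- function(tt) stats::approx(ctime, com$position[, 2L], tt, rule = 2)$y
    com_vy <- function(tt) stats::approx(ctime, com$velocity[, 2L], tt, rule = 2)$y
    out$com_ms_rel <- NA_real_
    out$com_ms_vel <- NA_real_
    for (k in seq_len(nrow(out))[-1]) {
      stance_side <- out$side[k - 1L]
      m <- midstances[midstances$side == stance_side &
                        midstances$time > out$time[k - 1L] - 1e-9 &
                        midstances$time < out$time[k], ]
      if (!nrow(m)) next
      tm <- m$time[1]
      stance_mat <- if (stance_side == "left") markers$l_calcaneus else markers$r_calcaneus
      out$com_ms_rel[k] <- com_y(tm) - at(stance_mat, 2L, tm)
      out$com_ms_vel[k] <- com_vy(tm)
    }
  }
  class(out) <- c("step_series", "data.frame")
  out
}

#' Step series directly from a step-level synthetic realization
#'
#' Fast path used for cohort-scale statistical work: reads the per-step
#' geometry and CoM midstance states straight from a [generate_step_data()]
#' result, bypassing signal synthesis and event detection (which are
#' validated separately against the same ground truth).
#'
#' @param step_data a `step_data` object.
#' @return a `step_series` data.frame as from [compute_step_series()], plus
#'   the generating trial's kind in attribute `trial_kind`.
#' @export
step_series_from_truth <- function(step_data) {
  st <- step_data$steps
  out <- data.frame(
    time = st$hs_time,
    side = st$side,
    width = st$width,
    step_time = st$step_time,
    placement = st$placement,
    com_ms_rel = c(NA_real_, st$com_ms_rel[-nrow(st)]),
    com_ms_vel = c(NA_real_, st$com_ms_vy[-nrow(st)]),
    # stance geometry and CoM state at heel strike (margin-of-stability inputs)
    foot_y = st$foot_y,
    to_time = st$to_time,
    com_hs_y = st$com_hs_y,
    com_hs_vy = st$com_hs_vy
  )
  class(out) <- c("step_series", "data.frame")
  attr(out, "trial_kind") <- step_data$kind
  out
}

#' Select the analysis data regime
#'
#' Applies the data-regime rules used by the step-based metrics. Steps must
#' carry a `trial_kind` column (`"steady"` / `"perturbed"`) and, for
#' perturbed trials, onsets are taken from `perturbations` (matched by the
#' optional `trial` column when present).
#'
#' * `steady`: all steps of steady trials, plus steps of perturbation trials
#'   occurring 18-23 s after the previous perturbation onset (the subject is
#'   back at steady state, just before the next perturbation);
#' * `steady_plus_perturbation`: all steps of steady trials, plus steps in
#'   the 7 s immediately following each onset;
#' * `perturbation_only`: only the steps in the 7 s after each onset.
#'
#' @param steps a `step_series` data.frame with columns `time`, `trial_kind`
#'   and optionally `trial`.
#' @param perturbations perturbation log with `onset_s` (and optionally
#'   `trial`).
#' @param regime one of `"steady"`, `"steady_plus_perturbation"`,
#'   `"perturbation_only"`.
#' @return the selected steps, chronological within trial, with a `regime`
#'   column added.
#' @export
select_regime <- function(steps, perturbations = NULL,
                          regime = c("steady", "steady_plus_perturbation",
                                     "perturbation_only")) {
  regime <- match.arg(regime)
  if (is.null(steps$trial_kind)) {
    stop("steps need a `trial_kind` column to apply regime rules", call. = FALSE)
  }
  steady_steps <- steps$trial_kind == "steady"
  in_window <- function(lo, hi) {
    sel <- rep(FALSE, nrow(steps))
    pert_rows <- which(steps$trial_kind == "perturbed")
    if (!length(pert_rows) || is.null(perturbations) || !nrow(perturbations)) {
      return(sel)
    }
    for (i in pert_rows) {
      ons <- perturbations$onset_s
      if (!is.null(perturbations$trial) && !is.null(steps$trial)) {
        ons <- perturbations$onset_s[perturbations$trial == steps$trial[i]]
      }
      dt <- steps$time[i] - ons
      if (any(dt > lo & dt <= hi)) sel[i] <- TRUE
    }
    sel
  }
  keep <- switch(regime,
    steady = steady_steps | in_window(18, 23),
    steady_plus_perturbation = steady_steps | in_window(0, 7),
    perturbation_only = in_window(0, 7)
  )
  out <- steps[keep, , drop = FALSE]
  out$regime <- rep(regime, nrow(out))
  out
}

#' Pool the step series of one subject x condition at a given regime
#'
#' Convenience for cohort work: extracts the two steady trials and the
#' perturbation bout of one subject x condition from a `gait_cohort`,
#' applies [select_regime()], and returns the pooled chronological steps
#' (steady trial 1, perturbation bout, steady trial 2).
#'
#' @param cohort a `gait_cohort`.
#' @param subject subject index.
#' @param condition condition label.
#' @param regime passed to [select_regime()].
#' @return a `step_series` data.frame.
#' @export
cohort_step_pool <- function(cohort, subject, condition, regime = "steady") {
  cc <- cohort$subjects[[subject]]$conditions[[condition]]
  pieces <- lapply(names(cc$trials), function(tn) {
    td <- cc$trials[[tn]]
    ss <- step_series_from_truth(td)
    ss$trial_kind <- td$kind
    ss$trial <- tn
    ss
  })
  steps <- do.call(rbind, pieces)
  pert <- cc$trials$perturbed$perturbations
  pert$trial <- "perturbed"
  sel <- select_regime(steps, pert, regime)
  sel[!is.na(sel$step_time), , drop = FALSE]
}
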