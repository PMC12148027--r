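# Inverted-pendulum stability metrics: lateral (or anterior) margin of
# stability and perturbation-induced CoM displacement.

#' Extrapolated center of mass offset
#'
#' The extrapolated CoM adds the CoM velocity divided by the natural
#' frequency of the equivalent pendulum, omega0 = sqrt(g / l), to the CoM
#' position. This helper returns the velocity-dependent offset v / omega0.
#'
#' @param velocity CoM velocity component, m/s.
#' @param pendulum_length equivalent pendulum length l, m (> 0).
#' @param g gravitational acceleration, m/s^2 (default 9.81).
#' @return offset in meters.
#' @export
#' @examples
#' xcom_offset(0.3132, 1)   # 0.100 m
xcom_offset <- function(velocity, pendulum_length, g = 9.81) {
  if (any(pendulum_length <= 0)) {
    stop("pendulum length must be positive", call. = FALSE)
  }
  velocity / sqrt(g / pendulum_length)
}

#' Margin of stability
#'
#' Per heel strike: the equivalent pendulum length is the distance between
#' the stance-side ankle marker and the CoM; the extrapolated CoM is the CoM
#' position plus CoM velocity / sqrt(g / l); the margin is the axis component
#' of the distance from the extrapolated CoM to the stance-side
#' fifth-metatarsal marker. For the lateral axis the sign is flipped per
#' stance side (positive toward the stance-side lateral boundary) so left
#' and right steps pool coherently. The metric is the mean over the first
#' `budget` steps. By the convention adopted for this metric, a *higher*
#' lateral margin of stability indicates lower balance ability.
#'
#' @param com a `com_state` from [estimate_com()].
#' @param markers named list with `l_ankle`, `r_ankle`, `l_meta5`, `r_meta5`.
#' @param marker_time marker time vector, s.
#' @param events a `gait_event_table` with valid heel strikes.
#' @param axis `"lateral"` (headline metric) or `"anterior"`.
#' @param budget fixed number of steps averaged (default 570).
#' @param g gravitational acceleration, m/s^2.
#' @return the mean margin of stability, m (single numeric).
#' @export
margin_of_stability <- function(com, markers, marker_time, events,
                                axis = c("lateral", "anterior"),
                                budget = 570, g = 9.81) {
  axis <- match.arg(axis)
  need <- c("l_ankle", "r_ankle", "l_meta5", "r_meta5")
  if (!all(need %in% names(markers))) {
    stop("ankle and fifth-metatarsal markers are required", call. = FALSE)
  }
  hs <- events[events$valid & events$type == "heel_strike", ]
  if (nrow(hs) < budget) {
    stop(sprintf("shortfall: margin of stability needs %d steps, have %d",
                 budget, nrow(hs)), call. = FALSE)
  }
  hs <- hs[seq_len(budget), ]
  ctime <- (seq_len(nrow(com$position)) - 1L) / com$rate
  interp3 <- function(mat, tt) {
    vapply(1:3, function(c) stats::approx(marker_time, mat[, c], tt,
                                          rule = 2)$y, numeric(length(tt)))
  }
  com_at <- function(mat, tt) {
    vapply(1:3, function(c) stats::approx(ctime, mat[, c], tt, rule = 2)$y,
           numeric(length(tt)))
  }
  cp <- com_at(com$position, hs$time)
  cv <- com_at(com$velocity, hs$time)
  is_left <- hs$side == "left"
  ankle <- matrix(NA_real_, nrow(hs), 3L)
  meta <- matrix(NA_real_, nrow(hs), 3L)
  if (any(is_left)) {
    ankle[is_left, ] <- interp3(markers$l_ankle, hs$time[is_left])
    meta[is_left, ] <- interp3(markers$l_meta5, hs$time[is_left])
  }
  if (any(!is_left)) {
    ankle[!is_left, ] <- interp3(markers$r_ankle, hs$time[!is_left])
    meta[!is_left, ] <- interp3(markers$r_meta5, hs$time[!is_left])
  }
  ell <- sqrt(rowSums((ankle - cp)^2))
  if (any(!is.finite(ell)) || any(ell <= 0)) {
    stop("invalid pendulum length at a heel strike", call. = FALSE)
  }
  ax <- if (axis == "lateral") 2L else 1L
  xcom <- cp[, ax] + xcom_offset(cv[, ax], ell, g)
  mos <- meta[, ax] - xcom
  if (axis == "lateral") {
    # outward is +y for left stance, -y for right stance
    mos <- ifelse(is_left, mos, -mos)
  }
  mean(mos)
}

#' Margin of stability from a step-level realization
#'
#' Fast path for cohort-scale work: evaluates the lateral margin of
#' stability directly from a [generate_step_data()] result, using the same
#' foot-marker geometry the signal synthesis uses (fifth metatarsal 0.05 m
#' lateral of the calcaneus, ankle 0.02 m medial and 0.08 m up, CoM height
#' 0.93 m) instead of interpolating synthesized marker channels.
#'
#' @param step_data a `step_data` object (or a data.frame of its `steps`).
#' @param budget number of steps averaged (default 570).
#' @param g gravitational acceleration, m/s^2.
#' @return mean lateral margin of stability, m.
#' @export
margin_of_stability_from_truth <- function(step_data, budget = 570, g = 9.81) {
  st <- if (is.data.frame(step_data)) step_data else step_data$steps
  speed <- if (is.data.frame(step_data)) 1.25 else step_data$params$treadmill_speed
  if (nrow(st) < budget) {
    stop(sprintf("shortfall: margin of stability needs %d steps, have %d",
                 budget, nrow(st)), call. = FALSE)
  }
  st <- st[seq_len(budget), , drop = FALSE]
  hs_time <- st$hs_time %||% st$time
  out_sign <- ifelse(st$side == "left", 1, -1)
  meta_y <- st$foot_y + out_sign * 0.05
  ankle_y <- st$foot_y - out_sign * 0.02
  ankle_x <- speed * (st$to_time - hs_time) / 2 + 0.06   # landing position
  ell <- sqrt((0.93 - 0.08)^2 + (st$com_hs_y - ankle_y)^2 + ankle_x^2)
  xcom <- st$com_hs_y + xcom_offset(st$com_hs_vy, ell, g)
  mean(out_sign * (meta_y - xcom))
}

#' Center-of-mass displacement after lateral perturbations
#'
#' The perturbation-recovery metric: for each qualifying perturbation (low
#' magnitude, 7.5% bodyweight, rightward, onset at left-leg midstance), the
#' ML CoM displacement from the onset midstance to the next left-leg
#' midstance is measured, projected onto the perturbation direction. The
#' metric is the arithmetic mean over the qualifying perturbations (the
#' protocol provides exactly two). Larger displacement indicates worse
#' balance.
#'
#' @param com_y ML CoM position series, m (or a `com_state`).
#' @param com_time time vector for `com_y`, s (ignored when `com_y` is a
#'   `com_state`).
#' @param midstances data.frame from [find_midstance()] (left side used).
#' @param perturbations perturbation log with `onset_s`, `direction`,
#'   `magnitude_pct_bw`.
#' @param magnitude qualifying magnitude, %BW (default 7.5).
#' @param direction qualifying direction (default `"rightward"`).
#' @return mean displacement, m (single numeric).
#' @export
com_displacement <- function(com_y, com_time = NULL, midstances,
                             perturbations, magnitude = 7.5,
                             direction = "rightward") {
  if (inherits(com_y, "com_state")) {
    com_time <- (seq_len(nrow(com_y$position)) - 1L) / com_y$rate
    com_y <- com_y$position[, 2L]
  }
  q <- perturbations[perturbations$magnitude_pct_bw == magnitude &
                       perturbations$direction == direction, ]
  if (nrow(q) < 2L) {
    stop(sprintf("fewer than two qualifying perturbations (%s, %.1f%% BW)",
                 direction, magnitude), call. = FALSE)
  }
  lm_times <- sort(midstances$time[midstances$side == "left"])
  dir_sign <- if (direction == "rightward") -1 else 1
  disp <- vapply(seq_len(nrow(q)), function(i) {
    on <- q$onset_s[i]
    k <- which.min(abs(lm_times - on))
    if (abs(lm_times[k] - on) > 0.2) {
      stop("perturbation onset does not coincide with a left-leg midstance",
           call. = FALSE)
    }
    if (k + 1L > length(lm_times)) {
      stop("no left-leg midstance after a qualifying perturbation", call. = FALSE)
    }
    y0 <- stats::approx(com_time, com_y, lm_times[k], rule = 2)$y
    y1 <- stats::approx(com_time, com_y, lm_times[k + 1L], rule = 2)$y
    dir_sign * (y1 - y0)
  }, numeric(1))
  mean(disp)
}
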