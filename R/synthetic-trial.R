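# Signal-level trial synthesis: turns a step-level realization into marker,
# ground-reaction-force, center-of-pressure and perturbation-force channels.
#
# Conventions: x = fore-aft (+ forward), y = medial-lateral (+ leftward),
# z = up; the lab frame is fixed to the treadmill, so stance feet travel
# backward at belt speed. Stance is transferred to the newly placed foot over
# the double-support interval with a smooth (cubic smoothstep) load-share
# ramp, so the fore-aft CoP velocity crosses zero within a few milliseconds
# of the true heel strike and CoP-velocity event detection can be validated
# against the generator's ground truth.

cubic_smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^2 * (3 - 2 * s)
}

# Load-transfer ramp shape (cubic smoothstep) and fixed transfer duration.
# A constant transfer duration keeps the CoP-velocity zero crossing at a
# fixed, near-zero offset from the true heel strike; duration-dependent
# transfer would modulate the crossing by tens of milliseconds.
transfer_ramp <- cubic_smoothstep
TRANSFER_DURATION <- 0.17

# Piecewise-smooth scalar: constant between transition events, transfer ramp
# within them. `ev` is a data.frame(start, end, from, to), sorted,
# non-overlapping.
eval_transitions <- function(t, ev, init) {
  out <- rep(init, length(t))
  if (!nrow(ev)) return(out)
  idx <- findInterval(t, ev$start)
  has <- idx >= 1L
  i <- idx[has]
  frac <- (t[has] - ev$start[i]) / pmax(ev$end[i] - ev$start[i], 1e-9)
  out[has] <- ev$from[i] + (ev$to[i] - ev$from[i]) * transfer_ramp(frac)
  out
}

# Foot trajectory from a sorted contact table (start, end, x_land, y).
# Stance: on the belt (backward at `speed`), z = 0. Swing: smoothstep
# interpolation to the next landing with a sinusoidal lift of height `apex`.
foot_trajectory <- function(t, contacts, speed, apex = 0.12) {
  ct <- contacts
  n <- length(t)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  idx <- findInterval(t, ct$start)
  pre <- idx < 1L
  if (any(pre)) {
    x[pre] <- ct$x_land[1] - speed * (t[pre] - ct$start[1])
    y[pre] <- ct$y[1]
  }
  ii <- idx[!pre]
  tt <- t[!pre]
  stance <- tt <= ct$end[ii] | ii == nrow(ct)
  # stance (or hold on the final contact)
  is_st <- which(!pre)[stance]
  i_st <- ii[stance]
  x[is_st] <- ct$x_land[i_st] - speed * pmin(t[is_st] - ct$start[i_st],
                                             ct$end[i_st] - ct$start[i_st] +
                                               (t[is_st] > ct$end[i_st]) * 1e9)
  # final-contact hold keeps moving with the belt until the trial ends
  x[is_st] <- ct$x_land[i_st] - speed * (t[is_st] - ct$start[i_st])
  y[is_st] <- ct$y[i_st]
  # swing
  is_sw <- which(!pre)[!stance]
  i_sw <- ii[!stance]
  s <- (t[is_sw] - ct$end[i_sw]) / pmax(ct$start[i_sw + 1L] - ct$end[i_sw], 1e-9)
  x_end <- ct$x_land[i_sw] - speed * (ct$end[i_sw] - ct$start[i_sw])
  x[is_sw] <- x_end + (ct$x_land[i_sw + 1L] - x_end) * cubic_smoothstep(s)
  y[is_sw] <- ct$y[i_sw] + (ct$y[i_sw + 1L] - ct$y[i_sw]) * cubic_smoothstep(s)
  z[is_sw] <- apex * sin(pi * pmin(pmax(s, 0), 1))^2
  cbind(x = x, y = y, z = z)
}

# Contact table for one foot, including pre-trial pseudo-contact and stutters.
foot_contacts <- function(sd, side_label) {
  p <- sd$params
  st <- sd$steps
  rows <- st[st$side == side_label, ]
  swing <- 0.35 * 2 * p$mean_step_time
  first_end <- rows$hs_time[1] - swing
  y0 <- st$foot_y[1] - st$placement[1]
  pre_y <- if (st$side[1] == side_label) rows$foot_y[1] else y0
  ct <- data.frame(
    start = c(first_end - 0.7, rows$hs_time),
    end = c(first_end, rows$to_time),
    y = c(pre_y, rows$foot_y)
  )
  if (nrow(sd$stutters)) {
    su <- sd$stutters[sd$stutters$side == side_label, ]
    if (nrow(su)) {
      # the stuttering foot briefly touches down behind the contralateral
      # foot, then swings on to its proper landing
      prev_y <- vapply(su$step, function(k) {
        prior <- st$foot_y[st$side == side_label & st$step < k]
        if (length(prior)) prior[length(prior)] else y0
      }, numeric(1))
      contra_x <- vapply(seq_len(nrow(su)), function(i) {
        k <- su$step[i]
        krow <- st[st$step == k - 1L, ]
        stance_len <- krow$to_time - krow$hs_time
        x_land <- sd$params$treadmill_speed * stance_len / 2
        x_land - sd$params$treadmill_speed * (su$time[i] - krow$hs_time)
      }, numeric(1))
      ct <- rbind(ct, data.frame(start = su$time, end = su$time + 0.22,
                                 y = prev_y + 0.01))
      ct <- ct[order(ct$start), ]
      # x_land for stutter rows is overridden below
      attr(ct, "stutter_x") <- data.frame(start = su$time, x = contra_x - 0.15)
    }
  }
  ct$x_land <- sd$params$treadmill_speed * (ct$end - ct$start) / 2
  sx <- attr(ct, "stutter_x")
  if (!is.null(sx)) {
    ct$x_land[match(sx$start, ct$start)] <- sx$x
  }
  ct
}

# Continuous stride phase (stride index + fraction) from left heel strikes.
stride_phase <- function(t, starts, nominal) {
  if (length(starts) < 2L) {
    return((t - starts[1]) / nominal)
  }
  idx <- findInterval(t, starts)
  ph <- numeric(length(t))
  pre <- idx < 1L
  ph[pre] <- (t[pre] - starts[1]) / nominal
  post <- idx >= length(starts)
  ph[post] <- (length(starts) - 1) +
    (t[post] - starts[length(starts)]) / nominal
  mid <- !(pre | post)
  i <- idx[mid]
  ph[mid] <- (i - 1) + (t[mid] - starts[i]) / (starts[i + 1L] - starts[i])
  ph
}

#' Synthesize continuous trial signals from a step-level realization
#'
#' Builds the marker channels (left/right calcaneus, fifth metatarsal and
#' ankle; four pelvis markers whose centroid is the CoM; C7), the per-belt
#' vertical ground reaction forces, the combined center of pressure and the
#' perturbation force channels implied by a [generate_step_data()] result.
#'
#' @param step_data a `step_data` object.
#' @param channels which channel groups to build: any of `"markers"`,
#'   `"forces"`. Dropping `"forces"` makes synthesis much cheaper when only
#'   kinematics are needed.
#' @param seed RNG seed for the C7 measurement noise; defaults to the trial's
#'   own stream.
#' @return an object of class `trial_timeseries` with elements `meta`,
#'   `marker_time`, `markers` (named list of n x 3 matrices), `force_time`,
#'   `forces` (data.frame: grf_left, grf_right, cop_x, cop_y, pert_fx,
#'   pert_fy), and `perturbations`. The generating `step_data` is attached as
#'   attribute `ground_truth`.
#' @export
synthesize_trial <- function(step_data, channels = c("markers", "forces"),
                             seed = NULL) {
  sd <- step_data
  p <- sd$params
  seed <- seed %||% (if (is.na(sd$seed)) 1L else sd$seed)
  channels <- match.arg(channels, c("markers", "forces"), several.ok = TRUE)
  st <- sd$steps
  dur <- sd$duration
  speed <- p$treadmill_speed
  out <- list(meta = list(subject = p$subject, condition = p$condition,
                          kind = sd$kind, treadmill_speed = speed,
                          marker_rate = p$marker_rate, force_rate = p$force_rate,
                          body_mass = p$body_mass, duration = dur),
              perturbations = sd$perturbations)

  ct_l <- foot_contacts(sd, "left")
  ct_r <- foot_contacts(sd, "right")

  if ("markers" %in% channels) {
    t_m <- seq(0, dur, by = 1 / p$marker_rate)
    fl <- foot_trajectory(t_m, ct_l, speed)
    fr <- foot_trajectory(t_m, ct_r, speed)
    off <- function(f, dx, dy, dz) sweep(f, 2L, -c(dx, dy, dz))
    markers <- list(
      l_calcaneus = off(fl, 0, 0, 0.03),
      r_calcaneus = off(fr, 0, 0, 0.03),
      l_meta5 = off(fl, 0.15, 0.05, 0.02),
      r_meta5 = off(fr, 0.15, -0.05, 0.02),
      l_ankle = off(fl, 0.06, -0.02, 0.08),
      r_ankle = off(fr, 0.06, 0.02, 0.08)
    )

    ph <- stride_phase(t_m, sd$lyapunov$stride_starts, 2 * p$mean_step_time)
    com_y <- hermite_interp(st$ms_time, st$com_ms_y, st$com_ms_vy, t_m)
    com_x <- 0.015 * sin(4 * pi * ph + 0.5)
    com_z <- 0.93 + 0.015 * cos(4 * pi * ph)
    if (nrow(sd$perturbations)) {
      fa <- sd$perturbations[sd$perturbations$direction %in%
                               c("forward", "backward"), ]
      for (i in seq_len(nrow(fa))) {
        gx <- if (fa$direction[i] == "forward") 1 else -1
        u <- (t_m - fa$onset_s[i]) / 1.2
        bump <- ifelse(u > 0, u * exp(1 - u), 0)
        com_x <- com_x + 0.05 * (fa$magnitude_pct_bw[i] / 7.5) * gx * bump
      }
    }
    com <- cbind(x = com_x, y = com_y, z = com_z)
    pelvis_offsets <- list(
      lasi = c(0.10, 0.115, -0.005), rasi = c(0.10, -0.115, -0.005),
      lpsi = c(-0.10, 0.105, 0.005), rpsi = c(-0.10, -0.105, 0.005)
    )
    for (nm in names(pelvis_offsets)) {
      markers[[nm]] <- sweep(com, 2L, -pelvis_offsets[[nm]])
    }

    # C7 velocity = CoM velocity + stride-periodic component + chaotic
    # stride-to-stride deviation + white measurement noise
    states <- sd$lyapunov$states
    j <- pmin(pmax(floor(ph) + 1L, 1L), nrow(states) - 1L)
    frac <- pmin(pmax(ph - (j - 1L), 0), 1)
    dtm <- 1 / p$marker_rate
    amp <- p$c7_periodic_amplitude
    phase_off <- c(0, 1.2, 2.1)
    v_extra <- vapply(1:3, function(i) {
      dev <- states[j, i] + frac * (states[j + 1L, i] - states[j, i]) - 0.5
      amp[i] * sin(2 * pi * ph + phase_off[i]) +
        p$c7_deviation_amplitude * dev
    }, numeric(length(t_m)))
    v_extra <- v_extra + with_rng(seed, matrix(
      stats::rnorm(length(t_m) * 3L, 0, p$c7_noise_sd), ncol = 3L))
    pos_extra <- apply(v_extra, 2L, cumsum) * dtm
    markers$c7 <- sweep(com + pos_extra, 2L, -c(-0.03, 0, 0.62))
    out$marker_time <- t_m
    out$markers <- markers
  }

  if ("forces" %in% channels) {
    t_f <- seq(0, dur, by = 1 / p$force_rate)
    ev <- load_share_events(sd)
    share_l <- eval_transitions(t_f, ev, init = if (st$side[1] == "left") 0 else 1)
    share_l <- pmin(pmax(share_l, 0), 1)
    fl <- foot_trajectory(t_f, ct_l, speed)
    fr <- foot_trajectory(t_f, ct_r, speed)
    w <- p$body_mass * 9.81
    pert_fx <- numeric(length(t_f))
    pert_fy <- numeric(length(t_f))
    for (i in seq_len(nrow(sd$perturbations))) {
      pe <- sd$perturbations[i, ]
      on <- t_f >= pe$onset_s & t_f < pe$onset_s + pe$duration_s
      f <- pe$magnitude_pct_bw / 100 * w
      if (pe$direction == "forward") pert_fx[on] <- pert_fx[on] + f
      if (pe$direction == "backward") pert_fx[on] <- pert_fx[on] - f
      if (pe$direction == "leftward") pert_fy[on] <- pert_fy[on] + f
      if (pe$direction == "rightward") pert_fy[on] <- pert_fy[on] - f
    }
    out$force_time <- t_f
    out$forces <- data.frame(
      grf_left = w * share_l,
      grf_right = w * (1 - share_l),
      cop_x = share_l * fl[, "x"] + (1 - share_l) * fr[, "x"],
      cop_y = share_l * fl[, "y"] + (1 - share_l) * fr[, "y"],
      pert_fx = pert_fx,
      pert_fy = pert_fy
    )
  }

  structure(out, class = "trial_timeseries", ground_truth = sd)
}

# Left-belt load-share transition events: a cubic-smoothstep ramp to the new
# stance foot over each double-support interval, plus brief partial transfers
# for stutter touches (sharp loading, gentle unloading).
load_share_events <- function(sd) {
  st <- sd$steps
  n <- nrow(st)
  ds <- rep(TRANSFER_DURATION, n)
  if (n > 1L) {
    # never let a transfer run into the next heel strike
    gap <- c(diff(st$hs_time), Inf)
    ds <- pmax(pmin(ds, 0.8 * gap), 0.05)
  }
  ev <- data.frame(
    start = st$hs_time,
    end = st$hs_time + ds,
    from = ifelse(st$side == "left", 0, 1),
    to = ifelse(st$side == "left", 1, 0)
  )
  if (nrow(sd$stutters)) {
    su <- sd$stutters
    # share of the *left* belt during a right-foot stutter: 1 -> 0.2 -> 1
    lvl_from <- ifelse(su$side == "right", 1, 0)
    lvl_to <- ifelse(su$side == "right", 0.2, 0.8)
    ev <- rbind(ev,
                data.frame(start = su$time, end = su$time + 0.04,
                           from = lvl_from, to = lvl_to),
                data.frame(start = su$time + 0.10, end = su$time + 0.26,
                           from = lvl_to, to = lvl_from))
  }
  ev <- ev[order(ev$start), ]
  # clip any overlap so transitions stay well-ordered
  if (nrow(ev) > 1L) {
    ev$end <- pmin(ev$end, c(ev$start[-1L] - 1e-4, Inf))
    ev$end <- pmax(ev$end, ev$start + 1e-4)
  }
  ev
}

#' Generate one synthetic walking trial with continuous signals
#'
#' Convenience wrapper: draws the step-level ground truth with
#' [generate_step_data()] and synthesizes the continuous channels with
#' [synthesize_trial()].
#'
#' @inheritParams generate_step_data
#' @inheritParams synthesize_trial
#' @return a `trial_timeseries` (with the `step_data` ground truth attached
#'   as attribute `ground_truth`).
#' @export
generate_trial <- function(params, kind = c("steady", "perturbed"),
                           duration = NULL, seed = 1L,
                           channels = c("markers", "forces")) {
  sd <- generate_step_data(params, kind, duration, seed)
  sd$seed <- as.integer(seed)
  synthesize_trial(sd, channels = channels)
}

#' @export
print.trial_timeseries <- function(x, ...) {
  cat(sprintf("<trial_timeseries> subject %s, %s, %s trial, %.0f s\n",
              x$meta$subject, x$meta$condition, x$meta$kind, x$meta$duration))
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %s (%g Hz)\n",
                paste(names(x$markers), collapse = ", "), x$meta$marker_rate))
  }
  if (!is.null(x$forces)) {
    cat(sprintf("  forces: %s (%g Hz)\n",
                paste(names(x$forces), collapse = ", "), x$meta$force_rate))
  }
  invisible(x)
}
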