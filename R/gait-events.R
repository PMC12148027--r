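# Heel-strike / toe-off detection from CoP and per-belt GRF, stutter-step
# exclusion, and midstance anchors.

new_event_table <- function(time = numeric(), type = character(),
                            side = character(), source = character(),
                            valid = logical(), reason = character()) {
  structure(data.frame(time = time, type = type, side = side, source = source,
                       valid = valid, reason = reason,
                       stringsAsFactors = FALSE),
            class = c("gait_event_table", "data.frame"))
}

# rising crossings of `x` above `level`, with linear sub-sample interpolation
# and a per-detector refractory interval
rising_crossings <- function(x, time, level, refractory) {
  i <- which(x[-length(x)] <= level & x[-1] > level) + 1L
  if (!length(i)) return(numeric())
  tt <- time[i - 1L] + (time[i] - time[i - 1L]) *
    (level - x[i - 1L]) / (x[i] - x[i - 1L])
  keep <- rep(TRUE, length(tt))
  last <- tt[1]
  for (k in seq_along(tt)[-1]) {
    if (tt[k] - last < refractory) keep[k] <- FALSE else last <- tt[k]
  }
  tt[keep]
}

#' Detect heel strikes from treadmill center-of-pressure velocity
#'
#' Implements the post-hoc CoP detector: the combined CoP is low-pass
#' filtered (fourth-order zero-lag Butterworth, 6 Hz), and candidate heel
#' strikes are marked where the fore-aft CoP velocity rises above 0 m/s in
#' the lab frame and where the medial-lateral CoP speed rises above 0.7 m/s.
#' When both detectors fire within the pairing window (150 ms for perturbed
#' trials, where steps succeed rapidly; 200 ms for steady walking) the
#' earlier candidate is kept as the single valid detection. The landing side
#' is assigned from the direction of ML CoP transfer just after the event
#' (+y transfer = left foot).
#'
#' @param cop_x,cop_y combined CoP fore-aft and ML position (m), uniformly
#'   sampled at `rate`.
#' @param rate CoP sampling rate, Hz.
#' @param trial_kind `"steady"` or `"perturbed"`; selects the pairing window.
#' @param ml_threshold ML CoP speed threshold, m/s (default 0.7).
#' @param refractory per-detector refractory interval, s (default 0.1),
#'   suppressing double-crossings near stance transfer.
#' @return a `gait_event_table` (columns time, type, side, source, valid,
#'   reason), all heel strikes, all initially valid.
#' @export
detect_heel_strikes_cop <- function(cop_x, cop_y, rate,
                                    trial_kind = c("steady", "perturbed"),
                                    ml_threshold = 0.7, refractory = 0.1) {
  trial_kind <- match.arg(trial_kind)
  if (length(cop_x) != length(cop_y)) {
    stop("CoP channels must have equal length", call. = FALSE)
  }
  if (anyNA(cop_x) || anyNA(cop_y)) {
    stop("CoP contains NA; detection requires gap-free, uniformly sampled CoP",
         call. = FALSE)
  }
  window <- if (trial_kind == "perturbed") 0.150 else 0.200
  fx <- zero_lag_butterworth(cop_x, 4, 6, rate)
  fy <- zero_lag_butterworth(cop_y, 4, 6, rate)
  time <- (seq_along(fx) - 1L) / rate
  vx <- finite_difference(fx, rate)
  vy <- finite_difference(fy, rate)

  t_fa <- rising_crossings(vx, time, 0, refractory)
  t_ml <- rising_crossings(abs(vy), time, ml_threshold, refractory)
  cand <- rbind(
    data.frame(time = t_fa, source = "cop_fa"),
    data.frame(time = t_ml, source = "cop_ml")
  )
  cand <- cand[order(cand$time), ]
  keep <- rep(TRUE, nrow(cand))
  i <- 1L
  while (i < nrow(cand)) {
    if (keep[i] && cand$source[i + 1L] != cand$source[i] &&
        cand$time[i + 1L] - cand$time[i] <= window) {
      keep[i + 1L] <- FALSE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(new_event_table())

  # landing side from the net ML CoP transfer just after the event
  side <- vapply(cand$time, function(tt) {
    i0 <- pmin(pmax(round(tt * rate) + 1L, 1L), length(fy))
    i1 <- pmin(i0 + round(0.08 * rate), length(fy))
    if (fy[i1] - fy[i0] >= 0) "left" else "right"
  }, character(1))

  new_event_table(time = cand$time,
                  type = "heel_strike",
                  side = side,
                  source = "cop",
                  valid = TRUE,
                  reason = "none")
}

#' Detect gait events from per-belt vertical ground reaction force
#'
#' Heel strikes are rising crossings and toe-offs falling crossings of a
#' 100 N threshold on each belt's vertical GRF, after low-pass filtering
#' (second-order Butterworth, 60 Hz cutoff, applied zero-lag). The side is
#' the belt.
#'
#' @param grf_left,grf_right per-belt vertical GRF (N) at `rate`.
#' @param rate force sampling rate, Hz.
#' @param threshold force threshold, N (default 100).
#' @return a `gait_event_table` sorted by time (empty if no crossings).
#' @export
detect_events_force <- function(grf_left, grf_right, rate, threshold = 100) {
  one_belt <- function(g, side) {
    if (length(g) < 30L) return(new_event_table())
    f <- zero_lag_butterworth(g, 2, 60, rate)
    time <- (seq_along(f) - 1L) / rate
    hs <- rising_crossings(f, time, threshold, refractory = 0.05)
    to <- rising_crossings(-f, time, -threshold, refractory = 0.05)
    if (!length(hs) && !length(to)) return(new_event_table())
    new_event_table(
      time = c(hs, to),
      type = c(rep("heel_strike", length(hs)), rep("toe_off", length(to))),
      side = side, source = "force", valid = TRUE, reason = "none"
    )
  }
  ev <- rbind(one_belt(grf_left, "left"), one_belt(grf_right, "right"))
  ev <- ev[order(ev$time), ]
  class(ev) <- c("gait_event_table", "data.frame")
  ev
}

#' Exclude stutter steps and implausible heel-strike candidates
#'
#' Walks the candidate heel strikes in time order and invalidates those that
#' do not correspond to a proper alternating step: a candidate whose foot is
#' not placed in front of the contralateral foot (fore-aft calcaneus
#' comparison at the candidate time), or whose side repeats the previous
#' valid heel strike, is marked a stutter; a candidate whose calcaneus marker
#' is at or above `height_threshold` (0.2 m) above the treadmill surface is
#' excluded as a marker-height violation. Toe-offs and already-invalid rows
#' pass through unchanged.
#'
#' @param events a `gait_event_table` with heel-strike candidates.
#' @param markers named list with `l_calcaneus` and `r_calcaneus` n x 3
#'   matrices.
#' @param marker_time time vector for the marker channels, s.
#' @param height_threshold exclusion height for the calcaneus marker, m.
#' @return the event table with `valid` / `reason` updated.
#' @export
exclude_stutter_steps <- function(events, markers, marker_time,
                                  height_threshold = 0.2) {
  if (is.null(markers$l_calcaneus) || is.null(markers$r_calcaneus)) {
    stop("foot (calcaneus) markers are required for stutter exclusion",
         call. = FALSE)
  }
  ev <- events
  at <- function(mat, col, tt) stats::approx(marker_time, mat[, col], tt,
                                             rule = 2)$y
  hs_idx <- which(ev$type == "heel_strike" & ev$valid)
  last_side <- NA_character_
  for (i in hs_idx) {
    tt <- ev$time[i]
    s <- ev$side[i]
    own <- if (s == "left") markers$l_calcaneus else markers$r_calcaneus
    other <- if (s == "left") markers$r_calcaneus else markers$l_calcaneus
    if (at(own, 3L, tt) >= height_threshold) {
      ev$valid[i] <- FALSE
      ev$reason[i] <- "marker_height"
      next
    }
    in_front <- at(own, 1L, tt) > at(other, 1L, tt)
    if (!in_front || (!is.na(last_side) && s == last_side)) {
      ev$valid[i] <- FALSE
      ev$reason[i] <- "stutter"
      next
    }
    last_side <- s
  }
  ev
}

#' Combine CoP heel strikes with force-plate toe-offs
#'
#' The CoP detector gives refined heel strikes; the per-belt force detector
#' supplies toe-offs. This helper merges the two into one event table for
#' midstance computation.
#'
#' @param cop_events heel-strike table from [detect_heel_strikes_cop()]
#'   (after exclusion).
#' @param force_events table from [detect_events_force()].
#' @return a merged `gait_event_table`, time-sorted.
#' @export
combine_event_tables <- function(cop_events, force_events) {
  ev <- rbind(cop_events[cop_events$type == "heel_strike", ],
              force_events[force_events$type == "toe_off", ])
  ev <- ev[order(ev$time), ]
  class(ev) <- c("gait_event_table", "data.frame")
  ev
}

#' Midstance anchors from paired heel strikes and toe-offs
#'
#' Midstance of a stance is defined operationally as the temporal midpoint
#' between a foot's heel strike and that same foot's subsequent toe-off.
#' Stances whose toe-off is missing (e.g. the final heel strike of a trial)
#' are skipped.
#'
#' @param events a `gait_event_table` containing valid heel strikes and
#'   toe-offs with sides.
#' @return data.frame with columns `time` (s) and `side`.
#' @export
find_midstance <- function(events) {
  ev <- events[events$valid, ]
  hs <- ev[ev$type == "heel_strike", ]
  to <- ev[ev$type == "toe_off", ]
  out <- lapply(seq_len(nrow(hs)), function(i) {
    nxt <- to$time[to$side == hs$side[i] & to$time > hs$time[i]]
    if (!length(nxt)) return(NULL)
    data.frame(time = (hs$time[i] + nxt[1]) / 2, side = hs$side[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(time = numeric(), side = character()) else out
}
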