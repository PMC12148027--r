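# Step-level synthetic gait generator.
#
# The generator works in two layers. This file builds the statistical layer:
# heel-strike times, signed step widths, the lateral foot-placement law, the
# CoM midstance knots, the perturbation schedule and the hidden per-stride
# divergence states. `synthesize_trial()` (synthetic-trial.R) turns one of
# these step-level realizations into marker / force-plate / CoP channels.
#
# Construction notes (see the methods vignette for the full rationale):
# * step widths are drawn iid Gaussian and the CoM midstance state is solved
#   from the placement law (inverse construction), so the law
#   placement = b1 * (CoM - stance heel) + b2 * CoM velocity + residual
#   holds exactly at every step, including perturbed ones, and the residual SD
#   is exactly the configured value;
# * perturbation responses enter through the CoM regressors, so recoveries
#   show transiently shifted, wider steps while the law keeps holding;
# * per-stride hidden states iterate a skew-tent map whose Lyapunov exponent
#   equals the configured divergence rate, giving the C7 signal a genuinely
#   positive, controllable injected divergence.

# Solve the skew-tent branch point whose Lyapunov exponent (binary entropy)
# equals `lambda` (1/stride). Capped just below log(2).
tent_parameter <- function(lambda) {
  lambda <- min(lambda, 0.66)
  if (lambda <= 0) stop("divergence rate must be > 0", call. = FALSE)
  ent <- function(q) -q * log(q) - (1 - q) * log(1 - q) - lambda
  stats::uniroot(ent, c(1e-9, 0.5))$root
}

iterate_tent <- function(n, q, x0) {
  x <- numeric(n)
  x[1] <- x0
  for (k in seq_len(n - 1L)) {
    xk <- x[k]
    xn <- if (xk < q) xk / q else (1 - xk) / (1 - q)
    # tiny jitter keeps float orbits off the map's eventually-periodic points
    x[k + 1L] <- (xn + stats::runif(1L, 0, 1e-9)) %% 1
  }
  x
}

#' Generate one trial's step-level ground truth
#'
#' Produces the statistical skeleton of a walking trial: heel-strike,
#' toe-off and midstance times for alternating feet, signed step widths and
#' lateral foot placements generated exactly by the linear
#' foot-placement law, CoM midstance knots, the perturbation schedule (for
#' perturbed trials) with injected CoM responses and optional stutter steps,
#' and hidden per-stride divergence states for the C7 signal.
#'
#' @param params flat parameter list for one subject x condition, as returned
#'   by [condition_params()].
#' @param kind `"steady"` (no perturbations) or `"perturbed"` (a bout of
#'   `params$n_perturbations` pelvis perturbations, onsets at left-leg
#'   midstance, spacing uniform within the configured band).
#' @param duration trial length in seconds; for perturbed trials the duration
#'   is schedule-driven and this argument is ignored.
#' @param seed integer seed for this trial's private RNG stream.
#'
#' @return an object of class `step_data`: a list with elements `steps`
#'   (one row per heel strike), `perturbations`, `stutters`, `lyapunov`
#'   (hidden stride states and the injected rate), `params`, `kind`,
#'   `duration` and `seed`.
#' @export
generate_step_data <- function(params, kind = c("steady", "perturbed"),
                               duration = NULL, seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  stopifnot(is.list(p), is.finite(p$mean_step_time), is.finite(p$mean_step_width))
  if (kind == "steady") {
    duration <- duration %||% p$steady_trial_duration
    if (duration <= 2 * 2 * p$mean_step_time) {
      stop("trial duration must exceed two strides", call. = FALSE)
    }
  }
  with_rng(seed, build_step_data(p, kind, duration))
}

build_step_data <- function(p, kind, duration) {
  Ts <- p$mean_step_time
  b1 <- p$placement_gain_position
  b2 <- p$placement_gain_velocity

  # perturbation schedule (times are provisional until snapped to midstances)
  sched <- NULL
  if (kind == "perturbed") {
    pc <- p$perturbations
    types <- expand.grid(direction = pc$directions,
                         magnitude_pct_bw = pc$magnitudes_pct_bw,
                         stringsAsFactors = FALSE)
    types <- types[rep(seq_len(nrow(types)), length.out = pc$count), ]
    types <- types[sample.int(nrow(types)), ]           # pseudorandom order
    # spacing drawn from the interior of the configured band so that
    # midstance alignment (+ <= 1 stride) and stutter delays (+0.25 s) keep
    # realized inter-onset gaps inside the band
    lo <- pc$spacing_s[1] + 1.2
    hi <- pc$spacing_s[2] - 1.5
    gaps <- stats::runif(pc$count, lo, hi)
    sched <- list(times = cumsum(gaps), types = types)
    duration <- sched$times[length(sched$times)] + 12
  }

  t0 <- 1.0
  n <- ceiling((duration - t0) / (0.9 * Ts)) + 8L
  side <- rep(c("left", "right"), length.out = n)
  s <- ifelse(side == "left", 1, -1)

  # drifting parameter tracks (defaults are stationary); evaluated on the
  # nominal clock so the draws stay vectorized
  tnom <- (t0 + (seq_len(n) - 1) * Ts) / 60
  sd_t <- pmax(1e-4, p$step_time_sd + p$drift_step_time_sd * tnom)
  sd_w <- pmax(p$placement_sd + 1e-4, p$step_width_sd + p$drift_step_width_sd * tnom)
  W <- pmax(0.02, p$mean_step_width + p$drift_mean_step_width * tnom)

  dt <- Ts + p$step_time_asymmetry * s + stats::rnorm(n, 0, sd_t)
  dt <- pmax(dt, 0.25)
  hs <- t0 + c(0, cumsum(dt[-1]))

  event_times <- function(hs) {
    stride <- c(hs[-(1:2)] - hs[seq_len(length(hs) - 2L)], 2 * Ts, 2 * Ts)
    to <- hs + p$stance_fraction * stride
    list(to = to, ms = (hs + to) / 2)
  }
  ev <- event_times(hs)

  perturbations <- data.frame()
  stutters <- data.frame()
  dpos <- numeric(n)
  dvel <- numeric(n)
  if (kind == "perturbed") {
    left_idx <- which(side == "left")
    onset_step <- integer(length(sched$times))
    prev <- 0L
    for (i in seq_along(sched$times)) {
      cand <- left_idx[ev$ms[left_idx] >= sched$times[i] & left_idx > prev]
      if (!length(cand)) stop("trial too short for the perturbation schedule",
                              call. = FALSE)
      onset_step[i] <- cand[1]
      prev <- cand[1]
    }
    ty <- sched$types
    is_ml <- ty$direction %in% c("leftward", "rightward")
    is_high <- ty$magnitude_pct_bw == max(p$perturbations$magnitudes_pct_bw)
    sp <- p$stutter_probability
    prob <- ifelse(is_ml, ifelse(is_high, sp$ml_high, sp$ml_low),
                   ifelse(is_high, sp$fa_high, sp$fa_low))
    has_stutter <- stats::runif(length(prob)) < prob

    # a stutter delays the first recovery step; recompute the event times
    delay_idx <- onset_step[has_stutter] + 1L
    delay_idx <- delay_idx[delay_idx <= n]
    if (length(delay_idx)) {
      dt[delay_idx] <- dt[delay_idx] + 0.25
      hs <- t0 + c(0, cumsum(dt[-1]))
      ev <- event_times(hs)
    }

    g <- ifelse(ty$direction == "leftward", 1,
                ifelse(ty$direction == "rightward", -1, 0))
    rel <- ty$magnitude_pct_bw / 7.5
    amp <- p$com_response_displacement * p$com_response_mult * rel * g
    dv_imp <- ty$magnitude_pct_bw / 100 * 9.81 * p$perturbations$duration_s * g
    # absolute ML CoM displacement targets at the midstances following the
    # onset (peak, value at the next ipsilateral midstance = the configured
    # response displacement, then recovery). Because foot placement chases
    # the displaced CoM through the law, the regressor offsets are solved
    # sequentially net of the accumulated foot response.
    shape_abs <- c(0.9, 1.0, 0.5, 0.2, 0.05, 0)
    shape_v <- c(0.5, 0.2, 0.05, 0, 0, 0)
    for (i in seq_along(onset_step)) {
      K <- onset_step[i]
      foot <- 0
      for (j in seq_along(shape_abs)) {
        if (K + j > n) break
        dv_j <- shape_v[j] * dv_imp[i]
        dp_j <- shape_abs[j] * amp[i] - foot
        dpos[K + j] <- dpos[K + j] + dp_j
        dvel[K + j] <- dvel[K + j] + dv_j
        foot <- foot + b1 * dp_j + b2 * dv_j
      }
    }
    perturbations <- data.frame(
      onset_s = ev$ms[onset_step],
      direction = ty$direction,
      magnitude_pct_bw = ty$magnitude_pct_bw,
      duration_s = p$perturbations$duration_s,
      onset_step = onset_step,
      injected_disp = abs(amp),
      stutter = has_stutter,
      row.names = NULL
    )
    st <- which(has_stutter & onset_step + 1L <= n)
    if (length(st)) {
      ks <- onset_step[st] + 1L
      stutters <- data.frame(
        step = ks,
        time = hs[ks] - 0.30,
        side = side[ks],
        duration_s = 0.26,
        row.names = NULL
      )
    }
  }

  # widths iid Gaussian; CoM knots solved from the placement law
  sd_e <- sqrt(pmax(sd_w^2 - p$placement_sd^2, 1e-8))
  e <- stats::rnorm(n, 0, sd_e)
  eps <- stats::rnorm(n, 0, p$placement_sd)
  # CoM ML velocity at the midstance of step k, heading toward the next
  # landing side (-s because sides alternate)
  v_mid <- -s * p$com_midstance_speed + stats::rnorm(n, 0, p$com_midstance_speed_sd)

  dy <- s * (W + e) + eps
  if (n > 1L) {
    k <- 2:n
    dy[k] <- dy[k] + b1 * dpos[k - 1L] + b2 * dvel[k - 1L]
    # the haptic safety boundary of the emulated protocol prevented crossover
    # steps: cap perturbation-driven placement shifts so a recovery step never
    # crosses the stance foot (noise-driven negative widths remain possible)
    off <- b1 * dpos[k - 1L] + b2 * dvel[k - 1L]
    cross <- s[k] * dy[k] < 0.015 & off != 0
    dy[k][cross] <- s[k][cross] * 0.015
  }
  y0 <- -s[1] * W[1] / 2
  y <- y0 + cumsum(dy)
  width <- s * dy

  P <- y + c((s * (W + e))[-1] - b2 * v_mid[-n], 0) / b1 + dpos
  P[n] <- (y[n] + y[n - 1L]) / 2
  Vk <- v_mid + dvel
  Vk[n] <- 0

  com_hs_y <- hermite_interp(ev$ms, P, Vk, hs)
  com_hs_vy <- hermite_deriv(ev$ms, P, Vk, hs)

  # hidden per-stride divergence states (left-to-left strides)
  left_hs <- hs[side == "left"]
  n_strides <- max(length(left_hs) - 1L, 1L)
  q <- tent_parameter(p$divergence_rate)
  states <- vapply(seq_len(3L),
                   function(i) iterate_tent(n_strides + 1L, q, stats::runif(1, 0.05, 0.95)),
                   numeric(n_strides + 1L))

  keep <- hs <= duration - 1.2
  keep[seq_len(min(2L, n))] <- TRUE
  steps <- data.frame(
    step = seq_len(n),
    hs_time = hs,
    side = side,
    step_time = c(NA_real_, dt[-1]),
    width = width,
    placement = dy,
    foot_y = y,
    to_time = ev$to,
    ms_time = ev$ms,
    com_ms_y = P,
    com_ms_vy = Vk,
    com_ms_rel = P - y,
    com_hs_y = com_hs_y,
    com_hs_vy = com_hs_vy,
    row.names = NULL
  )[keep, ]

  structure(list(
    steps = steps,
    perturbations = perturbations,
    stutters = stutters,
    lyapunov = list(lambda = min(p$divergence_rate, 0.66), tent_q = q,
                    states = states, stride_starts = left_hs),
    params = p,
    kind = kind,
    duration = duration,
    seed = NA_integer_
  ), class = "step_data")
}

#' @export
print.step_data <- function(x, ...) {
  cat(sprintf("<step_data> %s trial, %.0f s, %d heel strikes, %d perturbations\n",
              x$kind, x$duration, nrow(x$steps), nrow(x$perturbations)))
  invisible(x)
}
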