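#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design forward and backward (zero phase
#' shift at all frequencies, unit gain at DC). Edge transients are controlled
#' by odd-reflection padding about the signal endpoints before the
#' forward-backward pass; the pad length scales with the filter's transient
#' length (`rate / cutoff`).
#'
#' The net amplitude response is the square of the single-pass Butterworth
#' response, so a sinusoid exactly at the cutoff is attenuated to one half.
#'
#' @param x numeric vector (or matrix; filtered per column), uniformly sampled.
#' @param order single-pass filter order (default 4).
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist rate.
#' @param rate sampling rate, Hz.
#' @return filtered signal, same shape as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' x <- sin(2 * pi * 1 * t) + 0.2 * sin(2 * pi * 80 * t)
#' y <- zero_lag_butterworth(x, 4, 6, 1000)
zero_lag_butterworth <- function(x, order = 4, cutoff, rate) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a positive frequency in Hz", call. = FALSE)
  }
  if (cutoff >= rate / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, rate / 2), call. = FALSE)
  }
  if (is.matrix(x)) {
    return(apply(x, 2L, zero_lag_butterworth, order = order,
                 cutoff = cutoff, rate = rate))
  }
  n <- length(x)
  if (anyNA(x)) stop("signal contains NA; gap-filling is out of scope", call. = FALSE)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- min(n - 1L, max(3L * order, ceiling(10 * rate / cutoff)))
  if (n <= 3L * order + 1L) {
    stop("signal too short for the filter's edge handling", call. = FALSE)
  }
  # tangent reflection about both endpoints: the deviation from the endpoint
  # tangent line is reflected evenly, giving a C2-continuous extension whose
  # mismatch is third order in distance from the edge (plain odd reflection
  # leaves a curvature discontinuity that leaks into the filtered edges)
  s1 <- (4 * x[2] - 3 * x[1] - x[3]) / 2
  sn <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / 2
  # for noisy signals the local slope estimate is unreliable; cap it so the
  # tangent extension never departs the signal's own range
  cap <- (diff(range(x)) + 1e-300) / pad
  s1 <- sign(s1) * min(abs(s1), cap)
  sn <- sign(sn) * min(abs(sn), cap)
  j <- seq_len(pad)
  head_pad <- rev(x[1L + j] - 2 * j * s1)
  tail_pad <- x[n - j] + 2 * j * sn
  xx <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xx)
  y <- rev(signal::filter(bf, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Estimate the center of mass from pelvis markers
#'
#' The CoM position is the per-frame centroid (arithmetic mean) of the pelvis
#' markers; its velocity is the finite difference of the centroid (central
#' difference in the interior, one-sided at the edges). Both are then
#' low-pass filtered with a 25 Hz fourth-order zero-lag Butterworth filter.
#'
#' @param markers a named list of n x 3 matrices (columns x, y, z in m), one
#'   per pelvis marker, all the same length; or a single n x 3 matrix.
#' @param rate marker sampling rate, Hz.
#' @param cutoff final low-pass cutoff in Hz (default 25).
#' @return an object of class `com_state`: list with `position` and
#'   `velocity` (n x 3 matrices), `rate` and `markers_used`.
#' @export
estimate_com <- function(markers, rate, cutoff = 25) {
  if (is.matrix(markers)) markers <- list(pelvis = markers)
  if (!length(markers)) stop("empty pelvis marker set", call. = FALSE)
  dims <- vapply(markers, function(m) nrow(m), integer(1))
  if (length(unique(dims)) != 1L) {
    stop("pelvis markers must share one time base", call. = FALSE)
  }
  pos <- Reduce(`+`, markers) / length(markers)
  vel <- finite_difference(pos, rate)
  structure(list(
    position = zero_lag_butterworth(pos, 4, cutoff, rate),
    velocity = zero_lag_butterworth(vel, 4, cutoff, rate),
    rate = rate,
    markers_used = names(markers)
  ), class = "com_state")
}

# central difference interior, one-sided at the edges
finite_difference <- function(x, rate) {
  one_col <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[1] <- (v[2] - v[1]) * rate
    d[n] <- (v[n] - v[n - 1]) * rate
    if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate / 2
    d
  }
  if (is.matrix(x)) apply(x, 2L, one_col) else one_col(x)
}

#' @export
print.com_state <- function(x, ...) {
  cat(sprintf("<com_state> %d frames at %g Hz (markers: %s)\n",
              nrow(x$position), x$rate,
              paste(x$markers_used, collapse = ", ")))
  invisible(x)
}
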