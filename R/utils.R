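# Internal helpers shared across modules.

# Run `expr` under a private RNG stream, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Stable per-trial stream seed from (root seed, subject, condition, trial) so
# regenerating one trial never shifts the draws of another. Kept below 2^31.
derive_seed <- function(root, subject, condition, trial) {
  h <- as.double(root) %% 2147483647
  for (k in c(subject * 2654435761, condition * 40503, trial * 2246822519,
              7919)) {
    h <- (h * 48271 + (as.double(k) %% 2147483647)) %% 2147483647
  }
  as.integer(h %/% 1 %% 2147483629 + 1)
}

# Quintic smoothstep: 0 -> 1 on s in [0, 1], zero first/second derivative at ends.
smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

# Cubic Hermite interpolation through knots (t, y) with prescribed slopes dy.
# Evaluated at `tout`; constant extrapolation outside the knot range.
hermite_interp <- function(t, y, dy, tout) {
  stopifnot(length(t) == length(y), length(y) == length(dy), length(t) >= 2)
  idx <- findInterval(tout, t, rightmost.closed = TRUE)
  out <- numeric(length(tout))
  lo <- idx < 1L
  hi <- idx >= length(t)
  out[lo] <- y[1]
  out[hi] <- y[length(t)]
  mid <- !(lo | hi)
  i <- idx[mid]
  h <- t[i + 1L] - t[i]
  s <- (tout[mid] - t[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  out[mid] <- h00 * y[i] + h10 * h * dy[i] + h01 * y[i + 1L] + h11 * h * dy[i + 1L]
  out
}

# Derivative of the Hermite interpolant (analytic), constant-extrapolated to 0.
hermite_deriv <- function(t, y, dy, tout) {
  idx <- findInterval(tout, t, rightmost.closed = TRUE)
  out <- numeric(length(tout))
  mid <- idx >= 1L & idx < length(t)
  i <- idx[mid]
  h <- t[i + 1L] - t[i]
  s <- (tout[mid] - t[i]) / h
  d00 <- (6 * s^2 - 6 * s) / h
  d10 <- 3 * s^2 - 4 * s + 1
  d01 <- (6 * s - 6 * s^2) / h
  d11 <- 3 * s^2 - 2 * s
  out[mid] <- d00 * y[i] + d10 * dy[i] + d01 * y[i + 1L] + d11 * dy[i + 1L]
  out
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
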