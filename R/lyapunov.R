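# Short-term maximum Lyapunov exponent of the C7 velocity state:
# time-normalize strides to 100 samples, delay-embed (5 copies, delay 10),
# track nearest-neighbor divergence across strides, fit the first stride.

#' C7 marker velocity state
#'
#' Lab-frame 3-D velocity of the C7 marker: finite difference of the marker
#' position, low-pass filtered (fourth-order zero-lag Butterworth, 25 Hz).
#'
#' @param c7 n x 3 C7 marker position matrix, m.
#' @param rate marker rate, Hz.
#' @return n x 3 velocity matrix, m/s.
#' @export
c7_velocity <- function(c7, rate) {
  zero_lag_butterworth(finite_difference(c7, rate), 4, 25, rate)
}

#' Time-normalize a signal into fixed-length strides
#'
#' Resamples each stride (delimited by consecutive ipsilateral heel strikes)
#' to exactly `n_samples` samples by linear interpolation, endpoints
#' preserved.
#'
#' @param x n x k signal matrix (or vector).
#' @param time time vector for `x`, s.
#' @param strides data.frame with columns `start`, `end` (s) and optionally
#'   `segment` (contiguity id; strides in one segment are treated as one
#'   unbroken recording for embedding and divergence tracking).
#' @param n_samples samples per normalized stride (default 100).
#' @return a `stride_stack`: list with `values` ((n_strides x n_samples) x k
#'   matrix), `stride` and `segment` ids per row, and `samples_per_stride`.
#' @export
time_normalize_strides <- function(x, time, strides, n_samples = 100L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (is.null(strides$segment)) strides$segment <- 1L
  dt <- stats::median(diff(time))
  pieces <- vector("list", nrow(strides))
  for (j in seq_len(nrow(strides))) {
    if ((strides$end[j] - strides$start[j]) / dt < 3) {
      stop("stride shorter than 3 raw samples cannot be normalized",
           call. = FALSE)
    }
    tout <- seq(strides$start[j], strides$end[j], length.out = n_samples)
    pieces[[j]] <- vapply(seq_len(ncol(x)),
                          function(c) stats::approx(time, x[, c], tout,
                                                    rule = 2)$y,
                          numeric(n_samples))
  }
  structure(list(
    values = do.call(rbind, pieces),
    stride = rep(seq_len(nrow(strides)), each = n_samples),
    segment = rep(strides$segment, each = n_samples),
    samples_per_stride = as.integer(n_samples)
  ), class = "stride_stack")
}

#' Delay-embed a normalized stride stack
#'
#' State at normalized time t is the base state at t concatenated with
#' `d - 1` copies advanced by `delay`, `2 * delay`, ... samples, giving a
#' `3 * d`-element embedded state for a 3-D base (15 for the default d = 5,
#' delay = 10). Embedding never crosses segment boundaries; each contiguous
#' segment of length L contributes L - (d - 1) * delay embedded points.
#'
#' @param stack a `stride_stack`.
#' @param d number of copies including the original (default 5).
#' @param delay inter-copy delay in normalized samples (default 10).
#' @return an `embedded_trajectory`: list with `values` (m x (k*d) matrix),
#'   `stride`, `segment`, `samples_per_stride`, `d`, `delay`.
#' @export
delay_embed <- function(stack, d = 5L, delay = 10L) {
  stopifnot(d >= 1L, delay >= 1L)
  look <- (d - 1L) * delay
  vals <- list(); strid <- list(); segm <- list()
  for (sg in unique(stack$segment)) {
    rows <- which(stack$segment == sg)
    L <- length(rows)
    if (L <= look) {
      stop(sprintf("segment %s too short for a %d-sample embedding lookahead",
                   sg, look), call. = FALSE)
    }
    base <- stack$values[rows, , drop = FALSE]
    m <- L - look
    emb <- do.call(cbind, lapply(0:(d - 1L), function(j) {
      base[seq_len(m) + j * delay, , drop = FALSE]
    }))
    vals[[length(vals) + 1L]] <- emb
    strid[[length(strid) + 1L]] <- stack$stride[rows[seq_len(m)]]
    segm[[length(segm) + 1L]] <- rep(sg, m)
  }
  structure(list(
    values = do.call(rbind, vals),
    stride = unlist(strid),
    segment = unlist(segm),
    samples_per_stride = stack$samples_per_stride,
    d = as.integer(d), delay = as.integer(delay)
  ), class = "embedded_trajectory")
}

#' Short-term maximum Lyapunov exponent
#'
#' For every embedded point, the nearest neighbor is sought among points
#' originating in a *different* stride (and at nonzero distance, which
#' guards against bootstrap-duplicated strides). The Euclidean distance
#' between the two forward trajectories is tracked at each subsequent
#' normalized timestep (truncated at segment ends), the natural log taken
#' per record, and the mean over available records formed at each timestep.
#' The exponent is the ordinary least-squares slope of this mean
#' log-divergence curve over the first stride, in units of 1 per normalized
#' stride time.
#'
#' @param emb an `embedded_trajectory`.
#' @param fit_samples number of normalized timesteps used for the fit
#'   (default one stride).
#' @return list of class `lyapunov_fit`: `lambda` (1/stride), `divergence`
#'   (mean log-divergence curve), `n_records`.
#' @export
max_lyapunov <- function(emb, fit_samples = NULL) {
  X <- emb$values
  n <- nrow(X)
  sps <- emb$samples_per_stride
  fit_samples <- fit_samples %||% sps
  if (length(unique(emb$stride)) < 2L) {
    stop("need at least two strides for nearest-neighbor divergence",
         call. = FALSE)
  }
  g <- rowSums(X^2)
  stride_id <- as.integer(factor(emb$stride))
  stride_cols <- split(seq_len(n), stride_id)
  nn <- integer(n)
  nnd2 <- numeric(n)
  # argmin_j ||x_i - x_j||^2 = argmax_j (x_i . x_j - g_j / 2): one BLAS
  # product against candidates augmented with their squared norms
  Xa <- cbind(X, -0.5)
  Ya <- cbind(X, g)
  block <- 1024L
  for (b0 in seq(1L, n, by = block)) {
    b <- b0:min(b0 + block - 1L, n)
    S <- tcrossprod(Xa[b, , drop = FALSE], Ya)
    for (sid in unique(stride_id[b])) {
      rows <- which(stride_id[b] == sid)
      S[rows, stride_cols[[sid]]] <- -Inf
    }
    j <- max.col(S, ties.method = "first")
    d2 <- g[b] - 2 * S[cbind(seq_along(b), j)]
    # zero-distance neighbors (e.g. bootstrap-duplicated strides): retry
    bad <- which(d2 < 1e-20)
    for (i in bad) {
      row <- S[i, ]
      repeat {
        jj <- which.max(row)
        if (!is.finite(row[jj]) || g[b[i]] - 2 * row[jj] >= 1e-20) break
        row[jj] <- -Inf
      }
      j[i] <- jj
      d2[i] <- g[b[i]] - 2 * row[jj]
    }
    nn[b] <- j
    nnd2[b] <- d2
  }
  usable <- is.finite(nnd2) & nnd2 > 1e-20
  if (!any(usable)) {
    stop(paste("no usable nearest neighbors: all candidate pairs are",
               "zero-distance or same-stride; review neighbor exclusion"),
         call. = FALSE)
  }
  I <- which(usable)
  J <- nn[I]

  # position of each row inside its segment, to truncate forward tracking
  seg_pos <- stats::ave(seq_along(emb$segment), emb$segment, FUN = seq_along)
  seg_len <- stats::ave(seq_along(emb$segment), emb$segment, FUN = length)
  avail <- pmin(seg_len[I] - seg_pos[I], seg_len[J] - seg_pos[J])

  div_sum <- numeric(fit_samples)
  div_n <- numeric(fit_samples)
  for (tau in 0:(fit_samples - 1L)) {
    ok <- avail >= tau
    if (!any(ok)) break
    di <- I[ok] + tau
    dj <- J[ok] + tau
    dist <- sqrt(rowSums((X[di, , drop = FALSE] - X[dj, , drop = FALSE])^2))
    lg <- log(pmax(dist, 1e-300))
    div_sum[tau + 1L] <- sum(lg)
    div_n[tau + 1L] <- sum(ok)
  }
  have <- div_n > 0
  div <- div_sum[have] / div_n[have]
  tt <- (which(have) - 1L) / sps          # time axis in strides
  fit <- stats::lm.fit(cbind(1, tt), div)
  structure(list(lambda = unname(fit$coefficients[2]),
                 divergence = div,
                 time_strides = tt,
                 n_records = length(I)),
            class = "lyapunov_fit")
}

#' @export
print.lyapunov_fit <- function(x, ...) {
  cat(sprintf("<lyapunov_fit> lambda = %.4f per stride (%d divergence records)\n",
              x$lambda, x$n_records))
  invisible(x)
}

#' Stride selection plan for the Lyapunov exponent
#'
#' Builds the stride windows the exponent is estimated on. For steady data,
#' the available strides of a trial are split into `n_sections` equal
#' sections and the first `strides_per_section` strides of each are used
#' (8 x 9 from each of two steady trials = 144). For perturbation data, each
#' perturbation contributes `strides_per_section` strides with the onset
#' falling in the fifth stride (16 x 9 = 144).
#'
#' @param left_hs left-foot heel-strike times of one trial, s.
#' @param onsets perturbation onset times (perturbed plan) or `NULL`
#'   (steady plan).
#' @param n_sections number of sections for the steady plan.
#' @param strides_per_section strides taken per section / per perturbation.
#' @param segment_offset added to the emitted segment ids (to keep segments
#'   from different trials distinct).
#' @return data.frame with `start`, `end`, `segment`.
#' @export
lyapunov_stride_plan <- function(left_hs, onsets = NULL, n_sections = 8L,
                                 strides_per_section = 9L, segment_offset = 0L) {
  n_str <- length(left_hs) - 1L
  out <- list()
  if (is.null(onsets)) {
    bounds <- floor(seq(0L, n_str, length.out = n_sections + 1L))
    for (s in seq_len(n_sections)) {
      first <- bounds[s] + 1L
      idx <- first:(first + strides_per_section - 1L)
      if (idx[length(idx)] > n_str) {
        stop(sprintf("shortfall: section %d needs %d strides beyond the %d available",
                     s, strides_per_section, n_str), call. = FALSE)
      }
      out[[s]] <- data.frame(start = left_hs[idx], end = left_hs[idx + 1L],
                             segment = s + segment_offset)
    }
  } else {
    pre <- 4L   # onset falls in the fifth stride of the window
    for (i in seq_along(onsets)) {
      k <- findInterval(onsets[i], left_hs)
      idx <- (k - pre):(k - pre + strides_per_section - 1L)
      if (idx[1] < 1L || idx[length(idx)] > n_str) {
        stop(sprintf("shortfall: perturbation %d lacks the %d-stride window",
                     i, strides_per_section), call. = FALSE)
      }
      out[[i]] <- data.frame(start = left_hs[idx], end = left_hs[idx + 1L],
                             segment = i + segment_offset)
    }
  }
  do.call(rbind, out)
}
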