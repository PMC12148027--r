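# Bootstrap distributions of detection accuracy: resample the raw data each
# metric consumes (steps or strides), recompute the metric (refitting any
# model inside the sample), rerun detection, and collect the accuracies.

resample_pool <- function(pool, m) {
  if (inherits(pool, "stride_stack")) {
    ids <- unique(pool$stride)
    pick <- sample(ids, m, replace = TRUE)
    sps <- pool$samples_per_stride
    rows <- unlist(lapply(pick, function(s) which(pool$stride == s)))
    structure(list(
      values = pool$values[rows, , drop = FALSE],
      stride = rep(seq_len(m), each = sps),
      segment = rep(seq_len(m), each = sps),  # resampled strides are not contiguous
      samples_per_stride = sps
    ), class = "stride_stack")
  } else {
    idx <- sort(sample(nrow(pool), m, replace = TRUE))
    pool[idx, , drop = FALSE]
  }
}

#' Bootstrap distribution of detection accuracy
#'
#' For each bootstrap sample, every subject x condition's raw pool is
#' redrawn with replacement to `resample_size` (the canonical budgets use
#' 400 of the 570 steps for step-based metrics and 99 of the 144 strides for
#' the Lyapunov exponent), the metric is recomputed on the redrawn pool, and
#' detection is run under the requested threshold type. The default number
#' of samples is 1000; the Lyapunov exponent conventionally uses 100 because
#' of its computational cost.
#'
#' @param pools named list of raw pools, one per subject x condition: either
#'   `step_series` data.frames or `stride_stack`s, in the same order as the
#'   rows of `truth`.
#' @param truth data.frame with `subject`, `condition`, `impaired` (one row
#'   per pool).
#' @param metric_fun function(pool) -> numeric metric value.
#' @param threshold_type `"subject_specific"` or `"cohort"`.
#' @param n_samples number of bootstrap samples (>= 2).
#' @param resample_size size of each redraw; defaults to 70% of the pool
#'   (rounded).
#' @param seed RNG seed for the resampling stream.
#' @param higher_is_worse worse-direction flag for the metric.
#' @return a `bootstrap_distribution`: list with `accuracies`, `n_samples`,
#'   `resample_size`, `threshold_type`, `seed`; `mean` and `sd` summaries.
#' @export
bootstrap_accuracy <- function(pools, truth, metric_fun,
                               threshold_type = c("subject_specific", "cohort"),
                               n_samples = 1000L, resample_size = NULL,
                               seed = 1L, higher_is_worse = TRUE) {
  threshold_type <- match.arg(threshold_type)
  if (n_samples < 2L) stop("need at least 2 bootstrap samples", call. = FALSE)
  if (length(pools) != nrow(truth)) {
    stop("`pools` and `truth` must align", call. = FALSE)
  }
  sizes <- vapply(pools, function(p) {
    if (inherits(p, "stride_stack")) length(unique(p$stride)) else nrow(p)
  }, integer(1))
  resample_size <- resample_size %||% round(0.7 * min(sizes))
  if (any(sizes < resample_size)) {
    stop("a pool is smaller than the resample size", call. = FALSE)
  }
  detect <- switch(threshold_type,
                   subject_specific = subject_specific_detect,
                   cohort = cohort_detect_loso)
  acc <- with_rng(seed, vapply(seq_len(n_samples), function(b) {
    values <- vapply(pools, function(p) {
      metric_fun(resample_pool(p, resample_size))
    }, numeric(1))
    sc <- data.frame(subject = truth$subject, condition = truth$condition,
                     impaired = truth$impaired, value = values,
                     higher_is_worse = higher_is_worse)
    detect(sc)$accuracy
  }, numeric(1)))
  structure(list(accuracies = acc,
                 mean = mean(acc), sd = stats::sd(acc),
                 n_samples = as.integer(n_samples),
                 resample_size = as.integer(resample_size),
                 threshold_type = threshold_type,
                 seed = as.integer(seed)),
            class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("<bootstrap_distribution> %s: %.1f%% +/- %.1f%% (%d samples of %d)\n",
              x$threshold_type, 100 * x$mean, 100 * x$sd,
              x$n_samples, x$resample_size))
  invisible(x)
}
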