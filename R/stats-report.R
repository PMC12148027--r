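# Nonparametric statistical comparisons of bootstrap accuracy distributions
# and the learning-effect assessment. All tests are reported against the
# Bonferroni-corrected significance threshold alpha = 0.0071.

new_report <- function(test, groups, statistic, p_value, alpha, extra = NULL) {
  structure(c(list(test = test, groups = groups,
                   statistic = unname(statistic), p_value = unname(p_value),
                   alpha = alpha, significant = is.finite(p_value) && p_value < alpha),
              extra),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%s): stat %.4g, p = %.3g, alpha = %.4g -> %s\n",
              x$test, x$groups, x$statistic, x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

wilcox_exact <- function(n) n <= 25

#' Paired comparison of two accuracy distributions
#'
#' Wilcoxon signed-rank test on paired differences (e.g. subject-specific
#' versus cohort-based accuracies paired across metric variants, or
#' steady-state versus steady-plus-perturbation regimes). Uses the exact
#' distribution for n <= 25 pairs and the normal approximation with
#' continuity correction otherwise. Identical distributions (all
#' differences zero) are reported as not significant with p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alpha corrected significance threshold (default 0.0071).
#' @param groups label for the report.
#' @return a `comparison_report`.
#' @export
compare_paired <- function(a, b, alpha = 0.0071, groups = "a vs b") {
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  d <- b - a
  if (all(d == 0)) {
    return(new_report("wilcoxon_signed_rank", groups, 0, 1, alpha,
                      list(n = length(a))))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    b, a, paired = TRUE, exact = wilcox_exact(sum(d != 0)), correct = TRUE))
  new_report("wilcoxon_signed_rank", groups, ht$statistic, ht$p.value, alpha,
             list(n = length(a)))
}

#' Compare accuracy distributions across metrics
#'
#' Kruskal-Wallis omnibus test across the per-metric accuracy distributions,
#' followed by a Wilcoxon rank-sum contrast of the variability group
#' (step-width variability, step-time variability, foot-placement
#' predictability) against the remaining metrics.
#'
#' @param distributions named list of numeric accuracy distributions, one
#'   per metric.
#' @param variability_group names forming the variability contrast group.
#' @param alpha corrected significance threshold.
#' @return list with `omnibus` and `contrast` `comparison_report`s.
#' @export
compare_metric_groups <- function(distributions,
                                  variability_group = c("step_width_variability",
                                                        "step_time_variability",
                                                        "foot_placement_predictability"),
                                  alpha = 0.0071) {
  if (length(distributions) < 2L) {
    stop("need at least two metrics to compare", call. = FALSE)
  }
  values <- unlist(distributions, use.names = FALSE)
  grp <- factor(rep(names(distributions), lengths(distributions)))
  kw <- stats::kruskal.test(values, grp)
  omnibus <- new_report("kruskal_wallis", "all metrics",
                        kw$statistic, kw$p.value, alpha)
  in_group <- names(distributions) %in% variability_group
  contrast <- NULL
  if (any(in_group) && any(!in_group)) {
    va <- unlist(distributions[in_group], use.names = FALSE)
    vb <- unlist(distributions[!in_group], use.names = FALSE)
    ht <- suppressWarnings(stats::wilcox.test(
      va, vb, exact = wilcox_exact(min(length(va), length(vb))), correct = TRUE))
    contrast <- new_report("wilcoxon_rank_sum",
                           "variability metrics vs others",
                           ht$statistic, ht$p.value, alpha)
  }
  list(omnibus = omnibus, contrast = contrast)
}

#' Learning-effect assessment over a condition
#'
#' For each subject x condition step series, the metric is computed on the
#' first 200 and last 200 steps, and on 200-step windows sliding by 100
#' steps; an ordinary least-squares line of the windowed metric values
#' against window mid-time gives a slope in metric units per minute. A
#' Wilcoxon signed-rank test across the subject x condition slopes against
#' zero assesses whether the metric drifts systematically over a condition.
#'
#' @param step_groups list of `step_series` data.frames (one per subject x
#'   condition, time-ordered, >= 400 steps each).
#' @param metric_fun function(steps) -> numeric, evaluated per window (the
#'   window is passed with `budget` steps available; e.g.
#'   `function(s) step_width_variability(s, budget = 200)`).
#' @param window window length in steps (default 200).
#' @param by window shift in steps (default 100).
#' @param alpha corrected significance threshold.
#' @return list with `slopes` (data.frame: first, last, slope_per_min) and
#'   `test` (`comparison_report` of slopes against zero).
#' @export
learning_effect <- function(step_groups, metric_fun, window = 200L, by = 100L,
                            alpha = 0.0071) {
  res <- lapply(step_groups, function(steps) {
    n <- nrow(steps)
    if (n < 2L * window) {
      stop(sprintf("learning-effect assessment needs >= %d steps, have %d",
                   2L * window, n), call. = FALSE)
    }
    firstv <- metric_fun(steps[seq_len(window), , drop = FALSE])
    lastv <- metric_fun(steps[(n - window + 1L):n, , drop = FALSE])
    starts <- seq(1L, n - window + 1L, by = by)
    vals <- vapply(starts, function(s0) {
      metric_fun(steps[s0:(s0 + window - 1L), , drop = FALSE])
    }, numeric(1))
    mid_min <- vapply(starts, function(s0) {
      mean(steps$time[s0:(s0 + window - 1L)]) / 60
    }, numeric(1))
    slope <- unname(stats::coef(stats::lm(vals ~ mid_min))[2])
    c(first = firstv, last = lastv, slope_per_min = slope)
  })
  slopes <- as.data.frame(do.call(rbind, res))
  d <- slopes$slope_per_min
  if (all(d == 0)) {
    test <- new_report("wilcoxon_signed_rank", "slopes vs zero", 0, 1, alpha)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(
      d, mu = 0, exact = wilcox_exact(sum(d != 0)), correct = TRUE))
    test <- new_report("wilcoxon_signed_rank", "slopes vs zero",
                       ht$statistic, ht$p.value, alpha)
  }
  list(slopes = slopes, test = test)
}
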