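# Impairment detection from metric score tables: subject-specific thresholds
# (each subject's unimpaired score) and cohort-based thresholds (weighted
# logistic regression with leave-one-subject-out cross-validation).

check_scores <- function(scores) {
  need <- c("subject", "condition", "impaired", "value", "higher_is_worse")
  if (!all(need %in% names(scores))) {
    stop(sprintf("score table needs columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(scores$value))) {
    stop("score table contains non-finite values", call. = FALSE)
  }
  scores
}

# inverse-class-frequency weights: each class contributes half the total
# weight regardless of class sizes, which pins a constant classifier's
# weighted accuracy at exactly 1/2
class_weights <- function(truth) {
  n <- length(truth)
  n_pos <- sum(truth)
  n_neg <- n - n_pos
  ifelse(truth, n / (2 * n_pos), n / (2 * n_neg))
}

#' Weighted classification accuracy
#'
#' Accuracy with inverse-class-frequency weights, so chance performance of a
#' constant classifier is exactly 0.5 for any class imbalance.
#'
#' @param predicted logical predictions.
#' @param truth logical ground truth.
#' @return weighted accuracy in \[0, 1\].
#' @export
weighted_accuracy <- function(predicted, truth) {
  w <- class_weights(truth)
  sum(w * (predicted == truth)) / sum(w)
}

#' Impairment detection with subject-specific thresholds
#'
#' For each subject, the detection threshold is that subject's own
#' unimpaired score: an impaired condition is flagged detected iff its score
#' is strictly worse (per the metric's worse direction) than the same
#' subject's unimpaired score; a tie counts as not detected. Accuracy is the
#' fraction of impaired comparisons detected (n_subjects x
#' n_impaired_conditions comparisons; 30 for 10 subjects x 3 impairments).
#'
#' @param scores data.frame with columns `subject`, `condition`, `impaired`
#'   (logical truth), `value`, `higher_is_worse`.
#' @return a `detection_result`: list with `threshold_type`, `accuracy`,
#'   `comparisons` (one row per impaired condition) and `n_comparisons`.
#' @export
subject_specific_detect <- function(scores) {
  scores <- check_scores(scores)
  out <- list()
  for (s in unique(scores$subject)) {
    rows <- scores[scores$subject == s, ]
    base <- rows[!rows$impaired, ]
    if (nrow(base) != 1L) {
      stop(sprintf("subject %s needs exactly one unimpaired baseline score", s),
           call. = FALSE)
    }
    imp <- rows[rows$impaired, ]
    if (!nrow(imp)) {
      stop(sprintf("subject %s has no impaired scores", s), call. = FALSE)
    }
    worse <- if (base$higher_is_worse[1]) imp$value > base$value
             else imp$value < base$value
    out[[length(out) + 1L]] <- data.frame(
      subject = s, condition = imp$condition,
      predicted = worse, truth = TRUE
    )
  }
  comp <- do.call(rbind, out)
  structure(list(threshold_type = "subject_specific",
                 accuracy = mean(comp$predicted),
                 comparisons = comp,
                 n_comparisons = nrow(comp)),
            class = "detection_result")
}

#' Impairment detection with a cohort-based threshold
#'
#' Weighted logistic regression with the scalar metric score as the sole
#' feature, evaluated by leave-one-subject-out cross-validation: for each
#' held-out subject the model is fitted on all other subjects' scores with
#' inverse-class-frequency weights, the held-out subject's condition scores
#' are classified at probability 0.5, and the fold accuracy is computed with
#' the same class weights (balanced accuracy). The reported accuracy is the
#' mean over folds; every condition of every subject is classified once
#' (40 comparisons for 10 subjects x 4 conditions).
#'
#' @inheritParams subject_specific_detect
#' @return a `detection_result` (threshold_type `"cohort"`).
#' @export
cohort_detect_loso <- function(scores) {
  scores <- check_scores(scores)
  subjects <- unique(scores$subject)
  if (length(subjects) < 3L) {
    stop("leave-one-subject-out needs at least 3 subjects", call. = FALSE)
  }
  w_all <- class_weights(scores$impaired)
  fold_acc <- numeric(0)
  comp <- list()
  for (s in subjects) {
    test <- scores$subject == s
    train <- scores[!test, ]
    if (length(unique(train$impaired)) < 2L) {
      warning(sprintf("fold %s skipped: training data has a single class", s))
      next
    }
    w_train <- class_weights(train$impaired)
    fit <- suppressWarnings(stats::glm(
      impaired ~ value, family = stats::binomial(), data = train,
      weights = w_train))
    p <- suppressWarnings(stats::predict(fit, newdata = scores[test, ],
                                         type = "response"))
    pred <- p > 0.5
    w_test <- w_all[test]
    truth <- scores$impaired[test]
    fold_acc <- c(fold_acc, sum(w_test * (pred == truth)) / sum(w_test))
    comp[[length(comp) + 1L]] <- data.frame(
      subject = s, condition = scores$condition[test],
      predicted = pred, truth = truth
    )
  }
  if (!length(fold_acc)) stop("no usable folds", call. = FALSE)
  comp <- do.call(rbind, comp)
  structure(list(threshold_type = "cohort",
                 accuracy = mean(fold_acc),
                 fold_accuracies = fold_acc,
                 comparisons = comp,
                 n_comparisons = nrow(comp)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s threshold: accuracy %.3f over %d comparisons\n",
              x$threshold_type, x$accuracy, x$n_comparisons))
  invisible(x)
}
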