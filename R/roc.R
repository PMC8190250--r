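# Coerce a truth vector to 0/1 with `positive` as 1.
as_binary_truth <- function(truth, positive = "B") {
  if (is.logical(truth)) return(as.integer(truth))
  if (is.numeric(truth)) {
    if (!all(truth %in% c(0, 1))) {
      abort("Numeric truth must be coded 0/1.")
    }
    return(as.integer(truth))
  }
  as.integer(as.character(truth) == positive)
}

#' Empirical ROC curve
#'
#' One point per candidate threshold under the classification rule
#' `score >= threshold` predicts the positive (severe) class; higher scores
#' must indicate more severe disease. The first row (`threshold = Inf`)
#' predicts nobody positive, the last predicts everybody.
#'
#' @param scores Numeric marker values.
#' @param truth Binary outcome (0/1, logical, or factor/character where
#'   `positive` marks the positive class).
#' @param positive Positive-class label used when `truth` is not numeric.
#' @return A tibble with columns `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, truth, positive = "B") {
  y <- as_binary_truth(truth, positive)
  stopifnot(length(scores) == length(y))
  if (anyNA(scores) || anyNA(y)) abort("Scores and truth must be complete.")
  if (length(unique(y)) < 2) {
    abort("Both outcome classes must be present for a ROC curve.")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  sens <- vapply(thresholds, function(t) sum(scores >= t & y == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & y == 0) / n_neg,
                 numeric(1))
  tibble::tibble(threshold = thresholds, sensitivity = sens,
                 specificity = spec)
}

# Trapezoidal area under an empirical ROC curve tibble.
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Area under the ROC curve
#'
#' The trapezoidal integral of the empirical ROC, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted one half. Constant scores give 0.5.
#'
#' @inheritParams roc_curve
#' @return A single number in \[0, 1\].
#' @examples
#' roc_auc(c(1, 4, 2, 3), c(0, 1, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, truth, positive = "B") {
  auc_trapezoid(roc_curve(scores, truth, positive))
}

#' Optimal cutpoint by the closest-to-(0,1) ROC criterion
#'
#' Selects the threshold minimizing the Euclidean distance from the ROC
#' point (1 - specificity, sensitivity) to the perfect classifier (0, 1).
#' Ties are broken by higher sensitivity, then by the lower threshold.
#'
#' @inheritParams roc_curve
#' @return A list with `cutpoint`, `sensitivity`, `specificity`, `distance`
#'   and the full candidate `curve`.
#' @export
optimal_cutpoint_roc01 <- function(scores, truth, positive = "B") {
  curve <- roc_curve(scores, truth, positive)
  cand <- curve[is.finite(curve$threshold), , drop = FALSE]
  d <- sqrt((1 - cand$sensitivity)^2 + (1 - cand$specificity)^2)
  ord <- order(d, -cand$sensitivity, cand$threshold)
  best <- ord[1]
  list(
    cutpoint = cand$threshold[best],
    sensitivity = cand$sensitivity[best],
    specificity = cand$specificity[best],
    distance = d[best],
    curve = curve
  )
}

#' Confusion-matrix metrics of a binary prediction
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 confusion table. A metric whose denominator is zero (e.g. PPV with no
#' predicted positives) is returned as `NA` and listed in the `undefined`
#' attribute rather than silently coerced to 0.
#'
#' @param predicted Binary predictions (0/1 or logical).
#' @param truth Binary outcomes, same length and coding as in [roc_curve()].
#' @param positive Positive-class label for non-numeric `truth`.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`; attribute `undefined` names
#'   any metric with a zero denominator.
#' @export
confusion_metrics <- function(predicted, truth, positive = "B") {
  y <- as_binary_truth(truth, positive)
  p <- as_binary_truth(predicted, positive)
  if (length(p) != length(y)) {
    abort("`predicted` and `truth` must have the same length.")
  }
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0)
  fn <- sum(p == 0 & y == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
  undef <- c("sensitivity", "specificity", "ppv", "npv")[
    is.na(c(out$sensitivity, out$specificity, out$ppv, out$npv))
  ]
  attr(out, "undefined") <- undef
  out
}

#' Full ROC analysis of a marker against a severe-evolution cluster
#'
#' Data-frame-first wrapper tying together the empirical ROC, the
#' trapezoidal AUC, the closest-to-(0,1) optimal cutpoint with its operating
#' metrics, and (optionally) percentile bootstrap confidence intervals for
#' the AUC and for sensitivity/specificity at the selected cutpoint.
#' Bootstrap resampling is by patient; resamples that lose an outcome class
#' are redrawn (capped retries). Sensitivity/specificity intervals are
#' computed at the cutpoint selected on the original sample, so they reflect
#' the reported operating point.
#'
#' @param data A data frame.
#' @param score Column holding the marker (unquoted, tidy-eval).
#' @param truth Column holding the outcome (unquoted).
#' @param positive Positive-class label for non-numeric outcomes.
#' @param boot_b Number of bootstrap replicates; 0 skips the bootstrap.
#' @param seed Seed for the bootstrap (required when `boot_b > 0`).
#' @param level Confidence level for bootstrap intervals.
#' @return An object of class `roc_analysis` with elements `score_name`,
#'   `curve`, `auc`, `n_pos`, `n_neg`, `cutpoint` (list), `metrics`
#'   (one-row tibble) and, when bootstrapped, `boot` (tibble of intervals).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
#' glance(roc_analysis(d, s, y))
#' @export
roc_analysis <- function(data, score, truth, positive = "B",
                         boot_b = 0, seed = NULL, level = 0.95) {
  score_q <- enquo(score)
  truth_q <- enquo(truth)
  s <- dplyr::pull(data, !!score_q)
  y <- as_binary_truth(dplyr::pull(data, !!truth_q), positive)
  curve <- roc_curve(s, y)
  cut <- optimal_cutpoint_roc01(s, y)
  metrics <- confusion_metrics(as.integer(s >= cut$cutpoint), y)
  out <- list(
    score_name = as_name(score_q),
    curve = curve,
    auc = auc_trapezoid(curve),
    n_pos = sum(y == 1),
    n_neg = sum(y == 0),
    cutpoint = cut[c("cutpoint", "sensitivity", "specificity", "distance")],
    metrics = metrics,
    boot = NULL
  )
  if (boot_b > 0) {
    if (is.null(seed)) abort("A `seed` is required when bootstrapping.")
    stat_fn <- function(s_b, y_b) {
      m <- confusion_metrics(as.integer(s_b >= cut$cutpoint), y_b)
      c(auc = roc_auc(s_b, y_b),
        sensitivity = m$sensitivity, specificity = m$specificity)
    }
    reps <- boot_resample_paired(s, s, y, boot_b, seed,
                                 function(s1, s2, y_b) stat_fn(s1, y_b))
    qs <- apply(reps, 2, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                na.rm = TRUE, names = FALSE)
    out$boot <- tibble::tibble(
      metric = colnames(reps),
      estimate = c(out$auc, metrics$sensitivity, metrics$specificity),
      lower = qs[1, ],
      upper = qs[2, ],
      level = level,
      B = boot_b,
      seed = seed
    )
  }
  class(out) <- "roc_analysis"
  out
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("ROC analysis of `", x$score_name, "` (", x$n_pos, " positive / ",
      x$n_neg, " negative)\n", sep = "")
  cat(sprintf("  AUC %.3f; optimal cutpoint %g (closest to (0,1)): se %.3f, sp %.3f\n",
              x$auc, x$cutpoint$cutpoint, x$cutpoint$sensitivity,
              x$cutpoint$specificity))
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap %d%% CIs over B = %d replicates (seed %d)\n",
                round(100 * x$boot$level[1]), x$boot$B[1], x$boot$seed[1]))
  }
  invisible(x)
}
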