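# Patient-level bootstrap over paired scores. stat_fn(s1, s2, y) returns a
# named numeric vector; resamples with a single outcome class are redrawn
# (up to max_retry per replicate). Returns a B x k matrix.
boot_resample_paired <- function(s1, s2, y, B, seed, stat_fn,
                                 max_retry = 100) {
  n <- length(y)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(B), function(b) {
      for (try in seq_len(max_retry)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) {
          return(stat_fn(s1[idx], s2[idx], y[idx]))
        }
      }
      abort("Degenerate bootstrap resample: a single outcome class persisted.")
    })
    do.call(rbind, rows)
  })
}

#' Paired McNemar comparison of two classifiers' sensitivity or specificity
#'
#' Restricts to the true positives (for sensitivity) or true negatives (for
#' specificity) and counts the discordant subjects: `b` classified correctly
#' by the first classifier only, `c` by the second only. The two-sided p is
#' the exact binomial test of b against b + c at probability one half when
#' b + c < 25, and the continuity-corrected chi-square McNemar statistic
#' otherwise. Zero discordance returns p = 1 with a flag.
#'
#' @param pred_1,pred_2 Binary predictions of the two classifiers (0/1 or
#'   logical), same subjects in the same order.
#' @param truth Binary outcomes.
#' @param restrict `"positives"` (compare sensitivity) or `"negatives"`
#'   (compare specificity).
#' @param positive Positive-class label for non-numeric inputs.
#' @return A one-row tibble with `restrict`, `b`, `c`, `method`, `p_value`,
#'   `zero_discordance`.
#' @examples
#' y <- rep(1, 12)
#' p1 <- rep(1, 12); p2 <- c(rep(0, 10), 1, 1)
#' mcnemar_paired(p1, p2, y)  # b = 10, c = 0
#' @export
mcnemar_paired <- function(pred_1, pred_2, truth,
                           restrict = c("positives", "negatives"),
                           positive = "B") {
  restrict <- match.arg(restrict)
  y <- as_binary_truth(truth, positive)
  p1 <- as_binary_truth(pred_1, positive)
  p2 <- as_binary_truth(pred_2, positive)
  if (length(p1) != length(y) || length(p2) != length(y)) {
    abort("All vectors must have the same length.")
  }
  keep <- if (restrict == "positives") y == 1 else y == 0
  target <- if (restrict == "positives") 1L else 0L
  c1 <- p1[keep] == target
  c2 <- p2[keep] == target
  b <- sum(c1 & !c2)
  cc <- sum(!c1 & c2)
  if (b + cc == 0) {
    return(tibble::tibble(restrict = restrict, b = b, c = cc,
                          method = "exact", p_value = 1,
                          zero_discordance = TRUE))
  }
  if (b + cc < 25) {
    p <- binom.test(b, b + cc, p = 0.5)$p.value
    method <- "exact"
  } else {
    p <- mcnemar.test(matrix(c(0, cc, b, 0), nrow = 2),
                      correct = TRUE)$p.value
    method <- "chi-square (continuity corrected)"
  }
  tibble::tibble(restrict = restrict, b = b, c = cc, method = method,
                 p_value = min(p, 1), zero_discordance = FALSE)
}

#' Bootstrap comparison of two paired AUCs
#'
#' Resamples patients with replacement, recomputing both AUCs on each
#' resample; reports the observed AUC difference, a percentile confidence
#' interval for it, and the two-sided bootstrap p-value
#' 2 min(frac \eqn{\le} 0, frac \eqn{\ge} 0), floored at 1/B and capped at 1.
#'
#' @param data A data frame with one row per patient.
#' @param score_1,score_2 Marker columns (unquoted), paired on the same
#'   patients.
#' @param truth Outcome column (unquoted).
#' @param positive Positive-class label for non-numeric outcomes.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed; the comparison is reproducible given the seed.
#' @param level Confidence level of the percentile interval.
#' @return A one-row tibble with `auc_1`, `auc_2`, `auc_diff`, `lower`,
#'   `upper`, `p_value`, `B`, `seed`.
#' @export
bootstrap_compare_auc <- function(data, score_1, score_2, truth,
                                  positive = "B", B = 2000, seed,
                                  level = 0.95) {
  if (B < 100) abort("`B` must be at least 100.")
  s1 <- dplyr::pull(data, {{ score_1 }})
  s2 <- dplyr::pull(data, {{ score_2 }})
  y <- as_binary_truth(dplyr::pull(data, {{ truth }}), positive)
  auc_1 <- roc_auc(s1, y)
  auc_2 <- roc_auc(s2, y)
  reps <- boot_resample_paired(s1, s2, y, B, seed, function(a, b, yy) {
    c(diff = roc_auc(a, yy) - roc_auc(b, yy))
  })
  d <- reps[, 1]
  ci <- quantile(d, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  tibble::tibble(
    auc_1 = auc_1, auc_2 = auc_2, auc_diff = auc_1 - auc_2,
    lower = ci[1], upper = ci[2],
    p_value = min(1, max(p, 1 / B)),
    B = B, seed = seed
  )
}

#' Percentile bootstrap confidence interval for an arbitrary statistic
#'
#' Resamples the rows (data frame) or elements (vector) of `data` with
#' replacement and takes the percentile interval of `metric_fn` over the
#' replicates.
#'
#' @param data A data frame or vector of per-patient observations.
#' @param metric_fn Function mapping a resampled `data` to a single number.
#' @param B Number of replicates (at least 100).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A one-row tibble with `estimate`, `lower`, `upper`, `level`, `B`.
#' @examples
#' bootstrap_ci(rbinom(20, 1, 0.5), mean, B = 200, seed = 1)
#' @export
bootstrap_ci <- function(data, metric_fn, B = 2000, seed, level = 0.95) {
  if (B < 100) abort("`B` must be at least 100.")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) abort("`data` is empty.")
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  est <- metric_fn(data)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      metric_fn(take(sample.int(n, n, replace = TRUE)))
    }, numeric(1))
  })
  ci <- quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  tibble::tibble(estimate = est, lower = ci[1], upper = ci[2],
                 level = level, B = B)
}
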