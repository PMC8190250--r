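#' Logistic regression of cluster membership on a score
#'
#' Fits P(severe cluster) = logit^-1(b0 + b1 * score) by maximum likelihood
#' (iteratively reweighted least squares, convergence tolerance 1e-8, at
#' most 100 iterations) and reports the odds ratio per score point with its
#' Wald 95% confidence interval and p-value. Complete separation of the
#' score by outcome is an explicit error — no silently enormous
#' coefficients — as is a constant score or a single-class outcome.
#'
#' @param data A data frame.
#' @param score Numeric predictor column (unquoted), e.g. the VISUAL total.
#' @param truth Outcome column (unquoted); coerced as in [roc_curve()].
#' @param positive Positive-class label for non-numeric outcomes.
#' @param level Confidence level of the Wald interval.
#' @return An object of class `cvid_logit` with elements `beta_0`, `beta_1`,
#'   `se_1`, `odds_ratio`, `ci` (lower/upper), `p_wald`, `n`, `converged`,
#'   `iterations`, `score_name`, `level`. Supports [tidy()] and [glance()].
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x = rnorm(200))
#' d$y <- rbinom(200, 1, plogis(-0.5 + 0.8 * d$x))
#' glance(fit_logistic(d, x, y))
#' @export
fit_logistic <- function(data, score, truth, positive = "B", level = 0.95) {
  x <- dplyr::pull(data, {{ score }})
  y <- as_binary_truth(dplyr::pull(data, {{ truth }}), positive)
  score_name <- as_name(enquo(score))
  if (anyNA(x) || anyNA(y)) abort("Score and outcome must be complete.")
  if (length(unique(y)) < 2) {
    abort("Both outcome classes must be present; the MLE is undefined.")
  }
  if (length(unique(x)) < 2) abort("The score is constant; no fit possible.")
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    abort(paste("Complete separation: the score perfectly splits the",
                "outcome classes; the MLE does not exist."))
  }
  fit <- glm(y ~ x, family = binomial(),
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  b <- coef(fit)
  if (!fit$converged || abs(b[2]) > 15) {
    abort("Logistic fit did not converge to a finite coefficient (separation?).")
  }
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(
    beta_0 = unname(b[1]), beta_1 = unname(b[2]), se_1 = unname(se[2]),
    odds_ratio = exp(unname(b[2])),
    ci = exp(unname(b[2]) + c(-1, 1) * z * unname(se[2])),
    p_wald = unname(2 * pnorm(-abs(b[2] / se[2]))),
    n = length(y),
    converged = fit$converged,
    iterations = fit$iter,
    score_name = score_name,
    level = level
  )
  class(out) <- "cvid_logit"
  out
}

#' @export
print.cvid_logit <- function(x, ...) {
  cat("Logistic fit: severe cluster ~ ", x$score_name, " (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  OR per point %.3f (%d%% CI %.3f-%.3f), Wald p = %.4g\n",
              x$odds_ratio, round(100 * x$level), x$ci[1], x$ci[2],
              x$p_wald))
  invisible(x)
}

#' Fisher exact test and odds ratio for a 2x2 table
#'
#' The two-sided p-value sums, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than the observed table's.
#' The odds ratio is the sample cross-product ratio ad/bc with a log-scale
#' Wald interval; when any cell is zero the Haldane-Anscombe 0.5 correction
#' is applied to the OR and interval (never to the p-value) and flagged.
#' A zero row or column margin makes the test degenerate: p = 1, flagged.
#'
#' @param tab A 2x2 matrix of non-negative integer counts
#'   (rows = exposure, columns = outcome), or a length-4 vector (a, b, c, d)
#'   filling the table by row.
#' @param level Confidence level of the Wald interval.
#' @return A one-row tibble with `a`, `b`, `c`, `d`, `odds_ratio`, `lower`,
#'   `upper`, `p_value`, `haldane`, `degenerate`.
#' @examples
#' fisher_exact_2x2(c(3, 1, 1, 3))
#' @export
fisher_exact_2x2 <- function(tab, level = 0.95) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2, 2)))
    cells <- as.numeric(t(tab))
  } else {
    stopifnot(length(tab) == 4)
    cells <- as.numeric(tab)
  }
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Counts must be non-negative integers.")
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  n <- a + b + cc + d
  if (n == 0) abort("The table is empty.")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  degenerate <- any(c(r1, r2, c1, c2) == 0)

  if (degenerate) {
    p <- 1
  } else {
    # a ~ Hypergeometric(c1 successes, c2 failures, r1 draws), margins fixed
    support <- max(0, r1 - c2):min(r1, c1)
    probs <- dhyper(support, c1, c2, r1)
    p_obs <- dhyper(a, c1, c2, r1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }

  haldane <- any(cells == 0) && !degenerate
  oc <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (oc[1] * oc[4]) / (oc[2] * oc[3])
  z <- qnorm(1 - (1 - level) / 2)
  se_log <- sqrt(sum(1 / oc))
  ci <- exp(log(or) + c(-1, 1) * z * se_log)
  if (degenerate) {
    or <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  tibble::tibble(a = a, b = b, c = cc, d = d,
                 odds_ratio = or, lower = ci[1], upper = ci[2],
                 p_value = p, haldane = haldane, degenerate = degenerate)
}

#' Odds of severe evolution above a score threshold
#'
#' Dichotomizes the score at `cutoff` (inclusive) against the severe
#' cluster, builds the 2x2 table (rows: score at or above the cutoff vs
#' below; columns: severe cluster vs not) and delegates to
#' [fisher_exact_2x2()].
#'
#' @param data A data frame.
#' @param score Numeric score column (unquoted).
#' @param truth Outcome column (unquoted).
#' @param cutoff Score threshold; at or above means exposed. Default 10.
#' @param positive Positive-class label for non-numeric outcomes.
#' @return As [fisher_exact_2x2()], with an extra `cutoff` column.
#' @export
odds_at_threshold <- function(data, score, truth, cutoff = 10,
                              positive = "B") {
  s <- dplyr::pull(data, {{ score }})
  y <- as_binary_truth(dplyr::pull(data, {{ truth }}), positive)
  exposed <- s >= cutoff
  out <- fisher_exact_2x2(c(
    sum(exposed & y == 1), sum(exposed & y == 0),
    sum(!exposed & y == 1), sum(!exposed & y == 0)
  ))
  dplyr::mutate(out, cutoff = cutoff, .before = 1)
}
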