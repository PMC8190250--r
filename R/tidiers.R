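#' Tidy a ROC analysis into its curve coordinates
#'
#' @param x A [roc_analysis()] object.
#' @param ... Unused.
#' @return A tibble with `threshold`, `sensitivity`, `specificity`.
#' @exportS3Method generics::tidy
tidy.roc_analysis <- function(x, ...) {
  x$curve
}

#' One-row summary of a ROC analysis
#'
#' @param x A [roc_analysis()] object.
#' @param ... Unused.
#' @return A one-row tibble: `score`, `auc`, `cutpoint`, the operating
#'   metrics at the cutpoint, and the class counts.
#' @exportS3Method generics::glance
glance.roc_analysis <- function(x, ...) {
  tibble::tibble(
    score = x$score_name,
    auc = x$auc,
    cutpoint = x$cutpoint$cutpoint,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    ppv = x$metrics$ppv,
    npv = x$metrics$npv,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Tidy a logistic severity fit
#'
#' @param x A [fit_logistic()] object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (log-odds scale).
#' @exportS3Method generics::tidy
tidy.cvid_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$score_name),
    estimate = c(x$beta_0, x$beta_1),
    std.error = c(NA_real_, x$se_1),
    p.value = c(NA_real_, x$p_wald)
  )
}

#' One-row summary of a logistic severity fit
#'
#' @param x A [fit_logistic()] object.
#' @param ... Unused.
#' @return A one-row tibble with the per-point odds ratio, its Wald
#'   interval and p-value, and fit diagnostics.
#' @exportS3Method generics::glance
glance.cvid_logit <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio,
    conf.low = x$ci[1],
    conf.high = x$ci[2],
    p.value = x$p_wald,
    n = x$n,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Tidy Kaplan-Meier progression curves
#'
#' @param x A [km_progression()] object.
#' @param ... Unused.
#' @return The per-group step-function tibble.
#' @exportS3Method generics::tidy
tidy.km_progression <- function(x, ...) {
  x$curves
}

#' One-row summary of a Kaplan-Meier progression analysis
#'
#' @param x A [km_progression()] object.
#' @param ... Unused.
#' @return A one-row tibble with sample and event counts, per-group median
#'   times and, when two groups were compared, the log-rank statistic.
#' @exportS3Method generics::glance
glance.km_progression <- function(x, ...) {
  med <- setNames(as.list(x$medians$median_time),
                  paste0("median_", x$medians$group))
  out <- tibble::tibble(n = x$n, n_events = x$n_events)
  out <- dplyr::bind_cols(out, tibble::as_tibble(med))
  if (!is.null(x$logrank)) {
    out$logrank_chi_square <- x$logrank$chi_square
    out$logrank_p <- x$logrank$p_value
  }
  out
}
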