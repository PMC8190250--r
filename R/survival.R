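#' Kaplan-Meier progression analysis
#'
#' Product-limit estimate of the cumulative probability of progression to
#' the severe cluster as a function of age (the study's time axis), overall
#' or stratified by a risk group such as VISUAL at/above vs below the
#' cut-off. Ties between events and censorings at the same time are
#' resolved events-before-censoring, the product-limit convention. When a
#' grouping column is given, the Mantel-Cox log-rank test compares the two
#' groups; with no events the test is undefined and flagged rather than
#' computed.
#'
#' Estimation goes through [survival::survfit()] /
#' [survival::survdiff()].
#'
#' @param data A data frame with one row per patient.
#' @param time Column (unquoted) with the age at progression or censoring;
#'   must be positive.
#' @param event Column (unquoted), 1/TRUE = progressed, 0/FALSE = censored.
#' @param group Optional column (unquoted) with exactly two non-empty
#'   groups.
#' @return An object of class `km_progression` with `curves` (tibble:
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `cum_progression`), `medians` (tibble: smallest time with survival at
#'   or below one half, `NA` if never reached), and `logrank` (one-row
#'   tibble with `chi_square`, `df`, `p_value`, `no_events`, or `NULL`
#'   without grouping). Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(age = c(30, 35, 40, 50), prog = c(1, 1, 0, 1),
#'                     grp = c("high", "high", "low", "low"))
#' km_progression(d, age, prog, grp)
#' @export
km_progression <- function(data, time, event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g_q <- enquo(group)
  g <- if (rlang::quo_is_null(g_q)) NULL else dplyr::pull(data, !!g_q)
  if (length(t) == 0) abort("Empty sample: nothing to estimate.")
  if (anyNA(t) || anyNA(e)) abort("Times and events must be complete.")
  if (any(t <= 0)) abort("Times must be positive.")
  e <- as.integer(e)
  if (!all(e %in% c(0L, 1L))) abort("Events must be coded 0/1.")

  df <- data.frame(t = t, e = e,
                   g = if (is.null(g)) "all" else as.character(g))
  if (!is.null(g)) {
    tab <- table(df$g)
    if (length(tab) != 2) abort("Exactly two groups are required.")
    if (any(tab == 0)) abort("Both groups must be non-empty.")
  }
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  strata_names <- if (is.null(fit$strata)) {
    unique(df$g)
  } else {
    sub("^g=", "", names(fit$strata))
  }
  reps <- if (is.null(fit$strata)) length(fit$time) else fit$strata
  curves <- tibble::tibble(
    group = rep(strata_names, reps),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  curves$cum_progression <- 1 - curves$survival
  medians <- dplyr::summarise(
    dplyr::group_by(curves, .data$group),
    median_time = {
      hit <- .data$time[.data$survival <= 0.5]
      if (length(hit) == 0) NA_real_ else min(hit)
    },
    .groups = "drop"
  )

  logrank <- NULL
  if (!is.null(g)) {
    if (sum(e) == 0) {
      logrank <- tibble::tibble(chi_square = NA_real_, df = 1L,
                                p_value = NA_real_, no_events = TRUE)
    } else {
      sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
      logrank <- tibble::tibble(
        chi_square = sd$chisq, df = 1L,
        p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
        no_events = FALSE
      )
    }
  }
  structure(list(curves = curves, medians = medians, logrank = logrank,
                 n = nrow(df), n_events = sum(e)),
            class = "km_progression")
}

#' Mantel-Cox log-rank test between two groups
#'
#' Convenience wrapper returning just the log-rank comparison from
#' [km_progression()].
#'
#' @inheritParams km_progression
#' @param group Grouping column (unquoted), required here.
#' @return A one-row tibble with `chi_square`, `df`, `p_value`, `no_events`.
#' @export
logrank_test <- function(data, time, event, group) {
  km <- km_progression(data, {{ time }}, {{ event }}, {{ group }})
  km$logrank
}

#' @export
print.km_progression <- function(x, ...) {
  cat("Kaplan-Meier progression estimate: ", x$n, " patients, ",
      x$n_events, " events\n", sep = "")
  print(x$medians)
  if (!is.null(x$logrank)) {
    if (isTRUE(x$logrank$no_events)) {
      cat("  log-rank: undefined (no events)\n")
    } else {
      cat(sprintf("  log-rank chi-square %.3f (df 1), p = %.4g\n",
                  x$logrank$chi_square, x$logrank$p_value))
    }
  }
  invisible(x)
}
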