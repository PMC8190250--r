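test_that("product-limit estimate matches hand computation with censoring", {
  # events at 2 and 4, censoring at 3: S(2) = 2/3, S(4) = 0
  d <- tibble::tibble(time = c(2, 3, 4), event = c(1, 0, 1))
  km <- km_progression(d, time, event)
  ev <- km$curves[km$curves$n_event > 0, ]
  expect_equal(ev$time, c(2, 4))
  expect_equal(ev$survival, c(2 / 3, 0), tolerance = 1e-12)
})

test_that("without censoring 1 - S equals the empirical CDF exactly", {
  set.seed(41)
  t <- sample(seq(1, 60, by = 0.5), 40, replace = TRUE)
  d <- tibble::tibble(time = t, event = 1)
  km <- km_progression(d, time, event)
  ecdf_t <- stats::ecdf(t)
  expect_equal(km$curves$cum_progression, ecdf_t(km$curves$time),
               tolerance = 1e-12)
  # oracle product-limit agrees too
  hand <- oracle_km(t, rep(1, 40))
  expect_equal(km$curves$survival[km$curves$n_event > 0], hand$surv,
               tolerance = 1e-12)
})

test_that("S is a non-increasing step function starting at 1", {
  set.seed(42)
  d <- tibble::tibble(time = stats::rexp(30, 0.1) + 1,
                      event = rbinom(30, 1, 0.7))
  km <- km_progression(d, time, event)
  expect_true(all(diff(km$curves$survival) <= 1e-12))
  expect_true(all(km$curves$survival <= 1))
})

test_that("all-censored samples keep S at 1 with no median", {
  d <- tibble::tibble(time = c(10, 20, 30), event = 0)
  km <- km_progression(d, time, event)
  expect_true(all(km$curves$survival == 1))
  expect_true(is.na(km$medians$median_time))
})

test_that("the median is the smallest time with survival at or below one half", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1)
  km <- km_progression(d, time, event)
  expect_equal(km$medians$median_time, 2)  # S(2) = 0.5
})

test_that("log-rank: identical groups give statistic 0 and p = 1", {
  d <- tibble::tibble(
    time = rep(c(2, 4, 6, 8), 2),
    event = rep(c(1, 1, 0, 1), 2),
    group = rep(c("x", "y"), each = 4)
  )
  lr <- logrank_test(d, time, event, group)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank matches the hand O-E computation on a single event", {
  # one event at t = 1 in group a, group b censored at 2:
  # E_a = 1/2, V = 1/4, chi-square = (1 - 1/2)^2 / (1/4) = 1
  d <- tibble::tibble(time = c(1, 2), event = c(1, 0),
                      group = c("a", "b"))
  lr <- logrank_test(d, time, event, group)
  expect_equal(lr$chi_square, 1, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("log-rank is invariant to swapping group labels", {
  set.seed(43)
  d <- tibble::tibble(
    time = stats::rexp(40, 0.05) + 1,
    event = rbinom(40, 1, 0.8),
    group = rep(c("g1", "g2"), 20)
  )
  lr1 <- logrank_test(d, time, event, group)
  d$group <- ifelse(d$group == "g1", "g2", "g1")
  lr2 <- logrank_test(d, time, event, group)
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-12)
  expect_equal(lr1$p_value, lr2$p_value, tolerance = 1e-12)
})

test_that("chi-square p is sane against the permutation distribution", {
  set.seed(44)
  d <- tibble::tibble(
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = rep(1, 8),
    group = rep(c("a", "b"), each = 4)
  )
  obs <- logrank_test(d, time, event, group)
  perms <- combn(8, 4)
  stats_perm <- apply(perms, 2, function(idx) {
    g <- rep("b", 8)
    g[idx] <- "a"
    d2 <- d
    d2$group <- g
    logrank_test(d2, time, event, group)$chi_square
  })
  p_perm <- mean(stats_perm >= obs$chi_square - 1e-12)
  # order-of-magnitude agreement between asymptotic and exact p
  expect_true(obs$p_value > p_perm / 10 && obs$p_value < p_perm * 10 + 0.1)
})

test_that("degenerate survival inputs are rejected or flagged", {
  expect_error(km_progression(tibble::tibble(time = numeric(),
                                             event = integer()),
                              time, event),
               "Empty sample")
  expect_error(
    km_progression(tibble::tibble(time = c(-1, 2), event = c(1, 1)),
                   time, event),
    "positive")
  no_ev <- logrank_test(tibble::tibble(time = c(1, 2), event = c(0, 0),
                                       group = c("a", "b")),
                        time, event, group)
  expect_true(no_ev$no_events)
  expect_true(is.na(no_ev$p_value))
  expect_error(
    km_progression(tibble::tibble(time = 1:3, event = c(1, 1, 1),
                                  group = c("a", "b", "c")),
                   time, event, group),
    "Exactly two groups")
})

test_that("log-rank evidence grows with cohort size under a real hazard ratio", {
  mean_p <- function(n) {
    ps <- vapply(1:8, function(s) {
      co <- generate_cohort(cohort_config(n = n, seed = 600 + s),
                            complications = FALSE)
      d <- dplyr::inner_join(co$followup,
                             co$truth[, c("patient_id", "risk_class")],
                             by = "patient_id")
      logrank_test(d, age_progression_or_censor, event,
                   risk_class)$p_value
    }, numeric(1))
    mean(ps)
  }
  expect_lt(mean_p(500), mean_p(50))
})
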