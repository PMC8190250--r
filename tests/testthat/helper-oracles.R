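# Independent oracles used across the suite. Each recomputes a quantity by
# brute force / closed form, never through the package's own code path.

# Mann-Whitney AUC: fraction of (positive, negative) pairs in which the
# positive outscores the negative, ties counted one half.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Exhaustive closest-to-(0,1) threshold search with the spec'd tie-breaks.
oracle_cutpoint <- function(scores, y) {
  best <- NULL
  for (t in sort(unique(scores))) {
    se <- sum(scores >= t & y == 1) / sum(y == 1)
    sp <- sum(scores < t & y == 0) / sum(y == 0)
    d <- sqrt((1 - se)^2 + (1 - sp)^2)
    if (is.null(best) || d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 && (se > best$se + 1e-12 ||
          (abs(se - best$se) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, se = se, sp = sp, d = d)
    }
  }
  best
}

# Minimum within-cluster sum of squares over ALL 2-partitions (n <= 12).
oracle_best_partition_wss <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- x[sel]
    b <- x[!sel]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best <- min(best, wss)
  }
  best
}

# Two-sided Fisher p by explicit enumeration with binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- choose(c1, support) * choose(c2, r1 - support) / choose(n, r1)
  p_obs <- choose(c1, a) * choose(c2, r1 - a) / choose(n, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hand product-limit estimator (events before censorings at ties).
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = times, surv = out)
}

# Derivative-free logistic ML via Nelder-Mead on the log-likelihood.
oracle_logistic <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 20000))
  fit$par
}

# A minimal complete single-patient lab row, overridable per analyte.
make_labs <- function(..., patient_id = "p1") {
  base <- tibble::tibble(
    patient_id = patient_id,
    smb_pct = 10, iga_g_l = 1.5, igm_g_l = 1.0,
    poly_response = "adequate", protein_response = "adequate",
    cd4_per_ul = 900, age_at_diagnosis_years = 30
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
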