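# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (enumeration, hand formulas, grid search) and never
# calls the package function it checks.

# Exact two-sided rank-sum p by enumeration of all group-label assignments.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(pooled)
  m <- length(x)
  obs <- sum(r[seq_len(m)])
  mu <- m * (n + 1) / 2
  combs <- utils::combn(n, m)
  stats <- apply(combs, 2, function(i) sum(r[i]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  stats <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Hand O-E log-rank chi-square over the pooled distinct event times.
oracle_logrank_chi2 <- function(time, event, in_a) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & in_a)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Efron partial log-likelihood for a single covariate at scalar beta.
oracle_efron_loglik <- function(time, event, x, beta) {
  ll <- 0
  eta <- exp(beta * x)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    died <- event == 1 & time == t
    d <- sum(died)
    sum_risk <- sum(eta[risk])
    sum_died <- sum(eta[died])
    ll <- ll + beta * sum(x[died])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_died)
  }
  ll
}

# Two-stage grid maximizer of the Efron partial likelihood (resolution 1e-5).
oracle_grid_cox_beta <- function(time, event, x) {
  f <- function(b) oracle_efron_loglik(time, event, x, b)
  coarse <- seq(-5, 5, by = 0.001)
  b0 <- coarse[which.max(vapply(coarse, f, numeric(1)))]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  fine[which.max(vapply(fine, f, numeric(1)))]
}

# Brute-force maximally selected log-rank cutpoint, with survival::survdiff
# supplying the chi-square (independent of the package's log-rank code).
oracle_brute_cutpoint <- function(records, min_prop) {
  n <- nrow(records)
  best <- NULL
  for (c0 in sort(unique(records$covariate))) {
    hi <- records$covariate >= c0
    if (min(sum(hi), sum(!hi)) / n < min_prop ||
        sum(hi) == 0 || sum(!hi) == 0) next
    sd <- survival::survdiff(
      survival::Surv(records$time, records$event) ~ hi)
    if (is.null(best) || sd$chisq > best$chi2 + 1e-12)
      best <- list(cutoff = c0, chi2 = sd$chisq)
  }
  best
}

# Hand Benjamini-Hochberg step-up: sort, scale by m/i, enforce monotone
# from the largest down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Small survival-record fixture builder.
make_records <- function(time, event, covariate = seq_along(time)) {
  data.frame(sample_id = sprintf("s%02d", seq_along(time)),
             time = time, event = event, covariate = covariate,
             stringsAsFactors = FALSE)
}
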