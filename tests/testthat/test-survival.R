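test_that("follow-up filter keeps records at or above the threshold", {
  rec <- make_records(c(10, 30, 400), c(1, 0, 1))
  expect_equal(suppressMessages(filter_survival(rec, 30))$time, c(30, 400))
  expect_equal(nrow(filter_survival(rec, 0)), 3)
  expect_equal(nrow(filter_survival(rec[0, ], 30)), 0)
})

test_that("Kaplan-Meier estimate matches hand product-limit values", {
  # events at 1 and 2 with n = 2: S(1) = 0.5, S(2) = 0
  km <- km_estimate(make_records(c(1, 2), c(1, 1)))
  expect_equal(km$surv, c(0.5, 0))

  # events 1, 2 with a censor at 1.5: S(1) = (1 - 1/3) = 2/3; at t = 2 the
  # censored sample has left the risk set, so S(2) = 2/3 * (1 - 1/1) = 0
  km2 <- km_estimate(make_records(c(1, 1.5, 2), c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 2], 0)
  expect_equal(km2$n_risk[km2$time == 2], 1)

  # censor moved past the last event: S(1) = 2/3, S(2) = 2/3 * 1/2 = 1/3
  km2b <- km_estimate(make_records(c(1, 2.5, 2), c(1, 0, 1)))
  expect_equal(km2b$surv[km2b$time == 2], 1 / 3)

  # all censored: flat at 1
  km3 <- km_estimate(make_records(c(5, 9), c(0, 0)))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(make_records(numeric(), numeric())))
})

test_that("KM curve is non-increasing and starts at or below 1", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    km <- km_estimate(make_records(rexp(n, 0.01), rbinom(n, 1, 0.7)))
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_lte(km$surv[1], 1)
    expect_true(all(km$surv >= 0))
  }
})

test_that("log-rank chi-square matches the hand O-E oracle", {
  # frozen 4-record fixture: A events at 1,2; B events at 3,4 -> chi2 ~ 2.88
  a <- make_records(c(1, 2), c(1, 1))
  b <- make_records(c(3, 4), c(1, 1))
  lr <- logrank_test(a, b)
  expect_equal(lr$chi2, 2.882353, tolerance = 1e-6)
  expect_equal(lr$chi2,
               oracle_logrank_chi2(c(1, 2, 3, 4), rep(1, 4),
                                   c(TRUE, TRUE, FALSE, FALSE)),
               tolerance = 1e-12)

  # identical groups: no difference
  same <- make_records(c(1, 2, 3), c(1, 0, 1))
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)

  # label symmetry
  expect_equal(logrank_test(b, a)$chi2, lr$chi2)

  # zero events overall is degenerate
  cz <- make_records(c(1, 2), c(0, 0))
  expect_true(logrank_test(cz, cz)$degenerate)
})

test_that("log-rank agrees with survdiff and the Cox score test on random data", {
  set.seed(67)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    time <- if (i <= 4) sample(200, n) else sample(30, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    grp <- rbinom(n, 1, 0.5) == 1
    if (length(unique(grp)) < 2) grp[1:2] <- c(TRUE, FALSE)
    rec <- make_records(time, event)
    lr <- logrank_test(rec[grp, ], rec[!grp, ])
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-9)
    if (i <= 4) {  # tie-free: score test == log-rank
      cx <- cox_univariate(rec, grp)
      expect_equal(cx$score_chi2, lr$chi2, tolerance = 1e-6)
    }
  }
})

test_that("best_cutpoint equals brute-force maximization and honours min_prop", {
  set.seed(3)
  rec <- make_records(rexp(30, 0.01), rbinom(30, 1, 0.7), rlnorm(30, 8, 1))
  got <- best_cutpoint(rec, min_prop = 0.1)
  oracle <- oracle_brute_cutpoint(rec, 0.1)
  expect_equal(got$cutoff, oracle$cutoff)
  expect_equal(got$max_chi2, oracle$chi2, tolerance = 1e-9)

  # returned chi2 dominates every admissible candidate (exhaustiveness)
  for (c0 in sort(unique(rec$covariate))) {
    hi <- rec$covariate >= c0
    if (min(sum(hi), sum(!hi)) / 30 < 0.1 || !sum(hi) || !sum(!hi)) next
    expect_gte(got$max_chi2 + 1e-9,
               logrank_test(rec[hi, ], rec[!hi, ])$chi2)
  }

  # n = 50, min_prop = 0.1: no candidate may leave < 5 on a side
  set.seed(8)
  rec50 <- make_records(rexp(50, 0.01), rbinom(50, 1, 0.8), runif(50))
  got50 <- best_cutpoint(rec50, min_prop = 0.1)
  expect_gte(min(got50$n_low, got50$n_high), 5)

  expect_error(best_cutpoint(make_records(c(1, 2), c(1, 1), c(5, 5)),
                             min_prop = 0.4),
               "too small")
})

test_that("a planted expression cutpoint is recovered", {
  set.seed(5)
  n <- 200
  cov <- rlnorm(n, 8, 1)
  v <- stats::median(cov)
  hazard <- ifelse(cov >= v, 3 / 365, 1 / 365)
  time <- rexp(n, hazard)
  rec <- make_records(time, rep(1, n), cov)
  got <- best_cutpoint(rec, min_prop = 0.1)
  # recovered cutoff within the observed values adjacent to the plant
  srt <- sort(cov)
  idx <- which.min(abs(srt - v))
  window <- srt[max(1, idx - 5):min(n, idx + 5)]
  expect_true(got$cutoff >= min(window) && got$cutoff <= max(window))
})

test_that("Cox beta matches grid-search partial-likelihood maximization", {
  # 8-record fixture with tied event times so Efron weighting matters
  rec <- make_records(c(3, 3, 5, 7, 9, 9, 12, 15),
                      c(1, 1, 1, 0, 1, 1, 0, 1))
  grp <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  fit <- cox_univariate(rec, grp)
  oracle <- oracle_grid_cox_beta(rec$time, rec$event, as.integer(grp))
  expect_lt(abs(fit$beta - oracle), 1e-4)
  expect_equal(fit$hazard_ratio, exp(fit$beta))
  expect_true(fit$ci_low <= fit$hazard_ratio &&
                fit$hazard_ratio <= fit$ci_high)
})

test_that("planted group log-hazard ratio is recovered within 3 SE", {
  set.seed(42)
  n <- 500
  grp <- rbinom(n, 1, 0.5) == 1
  time <- rexp(n, (1 / 730) * exp(0.7 * grp))
  cens <- rexp(n, 1 / 2000)
  rec <- make_records(pmin(time, cens), as.integer(time <= cens))
  fit <- cox_univariate(rec, grp)
  expect_lt(abs(fit$beta - 0.7), 3 * fit$se)
})

test_that("null Cox fits stay within 3 SE in at least 93% of replicates", {
  inside <- 0L
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    n <- 400
    grp <- rep(c(TRUE, FALSE), n / 2)
    time <- rexp(n, 1 / 500)
    cens <- rexp(n, 1 / 1500)
    rec <- make_records(pmin(time, cens), as.integer(time <= cens))
    fit <- cox_univariate(rec, grp)
    if (abs(fit$beta) < 3 * fit$se) inside <- inside + 1L
  }
  expect_gte(inside / n_rep, 0.93)
})

test_that("Cox flags monotone likelihood and rejects constant groups", {
  rec <- make_records(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)  # all events in one group
  fit <- cox_univariate(rec, grp)
  expect_false(fit$converged)
  expect_true(is.infinite(fit$hazard_ratio) || fit$hazard_ratio == 0)
  expect_error(cox_univariate(rec, rep(TRUE, 6)), "constant")
  expect_error(cox_univariate(make_records(1:4, rep(0, 4)),
                              c(TRUE, TRUE, FALSE, FALSE)), "no events")
})

test_that("survival_scan labels directions and flags degenerate cells", {
  g <- data.frame(symbol = c("FGFR1", "FGFR3"),
                  base_log2_mean = c(10, 8), log2_sd = 1, log2fc = 0)
  d <- generate_cohort(cohort_spec("BLCA", 150, 0, genes = g,
                                   survival_link = list(gene = "FGFR1",
                                                        log_hr_per_sd = 0.9),
                                   seed = 9))
  sv <- survival_scan(d$expression, d$annotation, genes = c("FGFR1", "FGFR3"))
  hit <- sv[sv$gene == "FGFR1", ]
  expect_equal(hit$status, "ok")
  expect_equal(hit$direction, "adverse")
  expect_gt(hit$hazard_ratio, 1)
  expect_lt(hit$logrank_p, 0.05)
  expect_true(all(sv$cutpoint_selected))

  # constant covariate cell is flagged, not dropped
  m <- d$expression
  m["FGFR3", ] <- 1000
  sv2 <- survival_scan(m, d$annotation, genes = "FGFR3")
  expect_equal(sv2$status, "failed")
  expect_match(sv2$reason, "constant covariate")

  # zero-event cohort is flagged
  ann0 <- d$annotation
  ann0$os_event[!is.na(ann0$os_event)] <- 0L
  sv3 <- survival_scan(d$expression, ann0, genes = "FGFR1")
  expect_equal(sv3$status, "failed")
  expect_match(sv3$reason, "no events")
})

test_that("permutation-adjusted p is calibrated against selection inflation", {
  set.seed(99)
  rec <- make_records(rexp(60, 0.01), rbinom(60, 1, 0.8), rlnorm(60, 8, 1))
  naive <- {
    cp <- best_cutpoint(rec, 0.1)
    hi <- rec$covariate >= cp$cutoff
    logrank_test(rec[hi, ], rec[!hi, ])$p_value
  }
  perm <- cutpoint_perm_p(rec, min_prop = 0.1, n_perm = 99, seed = 2)
  # with a null covariate the selection-corrected p must exceed the naive one
  expect_gt(perm, naive)
  expect_gt(perm, 0.05)
})
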