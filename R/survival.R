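#' Build gene-wise survival records for one cohort
#'
#' Tumor samples only, keeping complete (time, event, expression) triples:
#' a patient enters the survival stage only when all three are observed.
#'
#' @param values Gene-by-sample expression matrix.
#' @param annot Sample annotation data.frame.
#' @param gene Gene symbol (covariate).
#' @param cohort Cohort code.
#' @return A data.frame with `sample_id`, `time`, `event` (1/0),
#'   `covariate` (linear expression).
#' @export
survival_records <- function(values, annot, gene, cohort) {
  values <- expression_matrix(values)
  annot <- sample_annotation(annot)
  if (!gene %in% rownames(values))
    stop("gene '", gene, "' absent from matrix")
  a <- annot[annot$cohort == cohort & annot$tissue == "tumor" &
               !is.na(annot$os_days) & annot$sample_id %in% colnames(values),
             , drop = FALSE]
  data.frame(sample_id = a$sample_id,
             time = a$os_days,
             event = a$os_event,
             covariate = as.numeric(values[gene, a$sample_id]),
             stringsAsFactors = FALSE)
}

#' Filter survival records on minimum follow-up
#'
#' Keeps records with `time >= min_days` regardless of event status
#' (the inclusion rule "at least `min_days` days of overall survival",
#' read inclusively); the dropped count is reported via `message()`.
#'
#' @param records Survival record data.frame (`time`, `event`, ...).
#' @param min_days Minimum follow-up in days (default 30).
#' @return Filtered records.
#' @export
filter_survival <- function(records, min_days = 30) {
  stopifnot(min_days >= 0)
  keep <- records$time >= min_days
  if (any(!keep))
    message(sum(!keep), " record(s) below ", min_days, " days dropped")
  records[keep, , drop = FALSE]
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Survival record data.frame with `time` and `event`
#'   (1 = event, 0 = censored); at least one record.
#' @return A data.frame of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop("no records for Kaplan-Meier estimate")
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of group-A events is
#' compared with its hypergeometric expectation given the pooled risk set;
#' the chi-square statistic is `(O - E)^2 / V` on 1 df with the
#' hypergeometric variance, tie-corrected. With zero events overall the
#' comparison is undefined and returned as degenerate with p = 1.
#'
#' @param group_a,group_b Survival record data.frames (`time`, `event`);
#'   both non-empty.
#' @return List with `chi2`, `p_value`, `observed` and `expected` group-A
#'   event counts, `degenerate`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b))
    stop("both groups must be non-empty")
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0L)
    return(list(chi2 = 0, p_value = 1, observed = 0, expected = 0,
                degenerate = TRUE))
  etimes <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0)
    return(list(chi2 = 0, p_value = 1, observed = O, expected = E,
                degenerate = TRUE))
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = O, expected = E, degenerate = FALSE)
}

#' Optimal expression cutpoint by maximally selected log-rank statistic
#'
#' Evaluates every distinct observed covariate value as a threshold
#' (low: `< cutoff`, high: `>= cutoff`), keeps candidates leaving at least
#' a `min_prop` fraction of the records on each side, and returns the
#' cutoff maximizing the log-rank chi-square. Ties are broken toward the
#' smaller cutoff. The selected cutoff is always an observed expression
#' value, keeping the procedure distribution-free. Note the selection
#' inflates the naive log-rank p-value; see [cutpoint_perm_p()] for a
#' selection-aware permutation p.
#'
#' @param records Survival record data.frame with `time`, `event`,
#'   `covariate`.
#' @param min_prop Minimum group-size fraction on each side (default 0.1).
#' @return List of class `cutpoint_result`: `cutoff`, `max_chi2`, `n_low`,
#'   `n_high`, `candidates_evaluated`.
#' @export
best_cutpoint <- function(records, min_prop = 0.1) {
  stopifnot(min_prop >= 0, min_prop < 0.5 + 1e-12)
  n <- nrow(records)
  cand <- sort(unique(records$covariate))
  best <- NULL
  evaluated <- 0L
  for (c0 in cand) {
    lo <- records$covariate < c0
    n_lo <- sum(lo); n_hi <- n - n_lo
    if (min(n_lo, n_hi) / n < min_prop || n_lo == 0L || n_hi == 0L) next
    evaluated <- evaluated + 1L
    lr <- logrank_test(records[lo, , drop = FALSE],
                       records[!lo, , drop = FALSE])
    if (is.null(best) || lr$chi2 > best$max_chi2 + 1e-12) {
      best <- list(cutoff = c0, max_chi2 = lr$chi2,
                   n_low = n_lo, n_high = n_hi)
    }
  }
  if (is.null(best))
    stop("cohort too small for cutpoint search (no admissible candidate)")
  best$candidates_evaluated <- evaluated
  class(best) <- "cutpoint_result"
  best
}

#' Permutation-adjusted p-value for the selected cutpoint
#'
#' Recomputes the maximally selected log-rank chi-square on permutations of
#' the covariate (survival kept fixed) and returns the fraction of
#' permuted maxima at least as large as the observed one (with the +1
#' correction), correcting the selection effect that makes the naive
#' cutpoint log-rank p anticonservative.
#'
#' @param records Survival record data.frame.
#' @param min_prop Cutpoint admissibility fraction (default 0.1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
cutpoint_perm_p <- function(records, min_prop = 0.1, n_perm = 1000,
                            seed = 1L) {
  obs <- best_cutpoint(records, min_prop)$max_chi2
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- records
    perm$covariate <- sample(records$covariate)
    chi2 <- tryCatch(best_cutpoint(perm, min_prop)$max_chi2,
                     error = function(e) 0)
    if (chi2 >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Univariate Cox proportional-hazards fit for a two-group split
#'
#' Partial-likelihood maximization (Newton-Raphson, Efron tie handling) of
#' the high-vs-low group indicator; hazard ratio `exp(beta)` with a 95%
#' Wald confidence interval. When all events fall on one side the partial
#' likelihood is monotone and the fit is flagged non-convergent with a
#' signed infinite hazard-ratio sentinel.
#'
#' @param records Survival record data.frame (`time`, `event`).
#' @param group Logical vector, `TRUE` = high group; must not be constant.
#' @return List with `beta`, `se`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value` (Wald), `score_chi2`, `converged`, `n_high`, `n_low`.
#' @export
cox_univariate <- function(records, group) {
  stopifnot(nrow(records) == length(group))
  if (length(unique(group)) < 2L)
    stop("constant group assignment")
  if (sum(records$event) == 0L)
    stop("no events: Cox model undefined")
  grp <- as.integer(group)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$time, records$event) ~ grp,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (monotone || abs(beta) > 15) {
    return(list(beta = sign(beta) * Inf, se = Inf,
                hazard_ratio = if (beta > 0) Inf else 0,
                ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, score_chi2 = unname(fit$score),
                converged = FALSE,
                n_high = sum(group), n_low = sum(!group)))
  }
  z <- beta / se
  list(beta = beta, se = se,
       hazard_ratio = exp(beta),
       ci_low = exp(beta - 1.959963984540054 * se),
       ci_high = exp(beta + 1.959963984540054 * se),
       p_value = 2 * stats::pnorm(-abs(z)),
       score_chi2 = unname(fit$score),
       converged = TRUE,
       n_high = sum(group), n_low = sum(!group))
}

#' Gene-wise overall-survival scan across cohorts
#'
#' Per (gene, cohort): build records, apply the follow-up filter, find the
#' optimal expression cutpoint, and run the log-rank test and univariate
#' Cox fit on the high (`>= cutoff`) vs low split. Degenerate cells
#' (constant covariate, no events, too few records) are reported with a
#' reason code, never silently dropped. `logrank_p` is cutpoint-selected
#' and therefore anticonservative; an optional seeded permutation-adjusted
#' p (`perm_p`) is emitted when `n_perm > 0`.
#'
#' @param values Gene-by-sample expression matrix.
#' @param annot Sample annotation data.frame.
#' @param genes Gene symbols to scan.
#' @param min_days Follow-up filter in days (default 30).
#' @param min_prop Cutpoint admissibility fraction (default 0.1).
#' @param n_perm Permutations for the selection-adjusted p (default 0 =
#'   off; column emitted as NA).
#' @param seed Seed for the permutation p.
#' @return A data.frame of class `fgfr_surv` with one row per (gene,
#'   cohort): cutoff, group sizes, hazard ratio with CI, Cox and log-rank
#'   p-values, `cutpoint_selected` flag, `perm_p`, `direction`
#'   (`adverse` when HR > 1, else `favorable`), `status`/`reason`.
#' @export
survival_scan <- function(values, annot, genes = paste0("FGFR", 1:4),
                          min_days = 30, min_prop = 0.1,
                          n_perm = 0, seed = 1L) {
  values <- expression_matrix(values)
  annot <- sample_annotation(annot)
  missing <- setdiff(genes, rownames(values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  cohorts <- sort(unique(annot$cohort[annot$tissue == "tumor" &
                                        !is.na(annot$os_days)]))
  rows <- list()
  for (co in cohorts) {
    for (gene in genes) {
      rec <- survival_records(values, annot, gene, co)
      rec <- suppressMessages(filter_survival(rec, min_days))
      row <- data.frame(gene = gene, cohort = co, n = nrow(rec),
                        cutoff = NA_real_, n_low = NA_integer_,
                        n_high = NA_integer_, hazard_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        cox_p = NA_real_, logrank_chi2 = NA_real_,
                        logrank_p = NA_real_, cutpoint_selected = TRUE,
                        perm_p = NA_real_, direction = NA_character_,
                        status = "ok", reason = NA_character_,
                        stringsAsFactors = FALSE)
      if (nrow(rec) < 4L) {
        row$status <- "failed"; row$reason <- "too few records"
        rows[[length(rows) + 1L]] <- row; next
      }
      if (length(unique(rec$covariate)) == 1L) {
        row$status <- "failed"; row$reason <- "constant covariate"
        rows[[length(rows) + 1L]] <- row; next
      }
      if (sum(rec$event) == 0L) {
        row$status <- "failed"; row$reason <- "no events"
        rows[[length(rows) + 1L]] <- row; next
      }
      cp <- tryCatch(best_cutpoint(rec, min_prop), error = function(e) e)
      if (inherits(cp, "error")) {
        row$status <- "failed"; row$reason <- conditionMessage(cp)
        rows[[length(rows) + 1L]] <- row; next
      }
      high <- rec$covariate >= cp$cutoff
      lr <- logrank_test(rec[!high, , drop = FALSE],
                         rec[high, , drop = FALSE])
      cox <- tryCatch(cox_univariate(rec, high), error = function(e) e)
      if (inherits(cox, "error")) {
        row$status <- "failed"; row$reason <- conditionMessage(cox)
        rows[[length(rows) + 1L]] <- row; next
      }
      row$cutoff <- cp$cutoff
      row$n_low <- cp$n_low; row$n_high <- cp$n_high
      row$hazard_ratio <- cox$hazard_ratio
      row$ci_low <- cox$ci_low; row$ci_high <- cox$ci_high
      row$cox_p <- cox$p_value
      row$logrank_chi2 <- lr$chi2; row$logrank_p <- lr$p_value
      row$direction <- if (is.finite(cox$hazard_ratio) &&
                           cox$hazard_ratio > 1 ||
                           is.infinite(cox$hazard_ratio)) "adverse" else "favorable"
      if (!cox$converged) {
        row$status <- "non_convergent"; row$reason <- "monotone likelihood"
      }
      if (n_perm > 0)
        row$perm_p <- cutpoint_perm_p(rec, min_prop, n_perm,
                                      seed = seed + match(co, cohorts) * 131L +
                                        match(gene, genes))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fgfr_surv", "data.frame")
  out
}

#' @export
print.fgfr_surv <- function(x, ...) {
  ok <- x$status != "failed"
  cat(sprintf("Survival scan: %d gene x cohort cells (%d computed, %d flagged)\n",
              nrow(x), sum(ok), sum(!ok)))
  if (any(ok))
    cat(sprintf("adverse: %d, favorable: %d; log-rank P < 0.05 in %d cells\n",
                sum(x$direction == "adverse", na.rm = TRUE),
                sum(x$direction == "favorable", na.rm = TRUE),
                sum(x$logrank_p < 0.05, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
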