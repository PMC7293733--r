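#' Pearson correlation with t-based two-sided p
#'
#' @param x,y Paired numeric vectors, n >= 3, both with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Expression-vs-IC50 correlation scan over a cell-line panel
#'
#' For each gene: one pan-tissue Pearson correlation of log2(expression +
#' pseudocount) against log-IC50 over all lines, plus one correlation per
#' tissue with at least `min_lines` lines (smaller tissues are skipped and
#' listed in `attr(, "skipped")`). A negative r means higher expression,
#' lower IC50, i.e. greater drug sensitivity. Correlation p-values are
#' reported raw (no multiplicity adjustment).
#'
#' @param panel A [cell_line_panel()].
#' @param genes Gene symbols to scan.
#' @param min_lines Minimum per-tissue line count (default 10).
#' @param log_expr Log2-transform expression before correlating
#'   (default TRUE).
#' @param pseudocount Pseudocount for the log transform (default 1).
#' @return A data.frame of class `fgfr_corr`: `gene`, `tissue` (`"pan"` or
#'   a tissue label), `r`, `p_value`, `n`.
#' @export
expr_ic50_scan <- function(panel, genes = c("FGFR1", "FGFR3"),
                           min_lines = 10, log_expr = TRUE,
                           pseudocount = 1) {
  stopifnot(inherits(panel, "cell_line_panel"))
  missing <- setdiff(genes, rownames(panel$expression))
  if (length(missing))
    stop("gene(s) absent from panel: ", paste(missing, collapse = ", "))
  xform <- function(v) if (log_expr) log2(v + pseudocount) else v
  rows <- list()
  skipped <- list()
  tissues <- sort(unique(panel$tissue))
  for (gene in genes) {
    ex <- xform(panel$expression[gene, ])
    pan <- pearson_correlation(ex, panel$log_ic50)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, tissue = "pan", r = pan$r, p_value = pan$p_value,
      n = pan$n, stringsAsFactors = FALSE)
    for (tt in tissues) {
      sel <- panel$tissue == tt
      if (sum(sel) < min_lines) {
        skipped[[paste(gene, tt)]] <- data.frame(
          gene = gene, tissue = tt, n = sum(sel),
          reason = sprintf("fewer than %d lines", min_lines))
        next
      }
      res <- pearson_correlation(ex[sel], panel$log_ic50[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, tissue = tt, r = res$r, p_value = res$p_value,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(), tissue = character(), n = integer(),
               reason = character())
  class(out) <- c("fgfr_corr", "data.frame")
  out
}

#' @export
print.fgfr_corr <- function(x, ...) {
  cat(sprintf("Expression-IC50 correlation scan: %d results, %d skipped tissue cells\n",
              nrow(x), nrow(attr(x, "skipped"))))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted (q) values with enforced monotonicity, capped at 1, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values, each in \[0, 1\].
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Dual-threshold significance call
#'
#' Significant iff `p < p_threshold` and `q <= fdr_threshold`; the sign of
#' the effect then labels the association `sensitizing` (effect < 0, mutant
#' lines need less drug) or `resistance` (effect > 0).
#'
#' @param p Raw p-value.
#' @param q BH-adjusted p-value.
#' @param effect Mean log-IC50 difference, mutant minus wild-type.
#' @param p_threshold P gate (default 1e-3).
#' @param fdr_threshold FDR gate (default 0.25).
#' @return `"sensitizing"`, `"resistance"`, or `"ns"`.
#' @export
significance_call <- function(p, q, effect, p_threshold = 1e-3,
                              fdr_threshold = 0.25) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            fdr_threshold > 0, fdr_threshold <= 1)
  if (is.na(p) || is.na(q)) return("ns")
  if (p < p_threshold && q <= fdr_threshold)
    if (effect < 0) "sensitizing" else "resistance"
  else "ns"
}

#' One-way two-group ANOVA of log-IC50 on a mutation marker
#'
#' Classical single-factor ANOVA of log-IC50 between mutant and wild-type
#' lines (equivalent to the squared pooled-variance two-sample t); the
#' effect is the mutant-minus-wild-type mean difference. Groups with fewer
#' than 2 lines are flagged not-computable.
#'
#' @param panel A [cell_line_panel()] with the marker in its mutation grid.
#' @param marker Marker gene symbol.
#' @return List with `marker`, `effect`, `F`, `p_value`, `n_mut`, `n_wt`,
#'   `computable`, `reason`.
#' @export
mutation_anova <- function(panel, marker) {
  stopifnot(inherits(panel, "cell_line_panel"))
  if (!marker %in% rownames(panel$mutations))
    stop("marker '", marker, "' absent from mutation grid")
  mut <- panel$mutations[marker, ] == 1
  n_mut <- sum(mut); n_wt <- sum(!mut)
  if (min(n_mut, n_wt) < 2L)
    return(list(marker = marker, effect = NA_real_, F = NA_real_,
                p_value = NA_real_, n_mut = n_mut, n_wt = n_wt,
                computable = FALSE, reason = "group with fewer than 2 lines"))
  y <- panel$log_ic50
  tab <- stats::anova(stats::lm(y ~ factor(mut)))
  list(marker = marker,
       effect = mean(y[mut]) - mean(y[!mut]),
       F = tab[["F value"]][1],
       p_value = tab[["Pr(>F)"]][1],
       n_mut = n_mut, n_wt = n_wt,
       computable = TRUE, reason = NA_character_)
}

#' Mutation-marker association scan with BH calls
#'
#' Runs [mutation_anova()] for every marker (or a subset), BH-adjusts the
#' computable p-values within this family, and assigns the dual-threshold
#' significance call (`p < p_threshold` and BH q <= `fdr_threshold`;
#' defaults P < 1e-3 and FDR <= 25%).
#'
#' @param panel A [cell_line_panel()].
#' @param markers Marker genes (default: all in the panel).
#' @param p_threshold,fdr_threshold Call thresholds.
#' @return A data.frame of class `fgfr_markers`: `marker`, `effect`, `F`,
#'   `p_value`, `q_value`, `n_mut`, `n_wt`, `call`, `computable`, `reason`.
#' @export
marker_scan <- function(panel, markers = rownames(panel$mutations),
                        p_threshold = 1e-3, fdr_threshold = 0.25) {
  stopifnot(inherits(panel, "cell_line_panel"), length(markers) >= 1L)
  res <- lapply(markers, function(m) mutation_anova(panel, m))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(marker = r$marker, effect = r$effect, F = r$F,
               p_value = r$p_value, n_mut = r$n_mut, n_wt = r$n_wt,
               computable = r$computable, reason = r$reason,
               stringsAsFactors = FALSE)))
  out$q_value <- NA_real_
  comp <- out$computable
  if (any(comp)) out$q_value[comp] <- bh_adjust(out$p_value[comp])
  out$call <- vapply(seq_len(nrow(out)), function(i)
    significance_call(out$p_value[i], out$q_value[i], out$effect[i],
                      p_threshold, fdr_threshold), character(1))
  out <- out[, c("marker", "effect", "F", "p_value", "q_value",
                 "n_mut", "n_wt", "call", "computable", "reason")]
  rownames(out) <- NULL
  class(out) <- c("fgfr_markers", "data.frame")
  out
}
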