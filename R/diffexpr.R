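#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration when both group sizes are at most
#' `exact_max_n` and there are no ties, otherwise the normal approximation
#' with tie-corrected variance and continuity correction. A pooled sample
#' with all values identical carries no ordering information and is returned
#' as degenerate with p = 1.
#'
#' @param x,y Numeric vectors (tumor and normal values); both non-empty.
#' @param exact_max_n Largest per-group size for the exact branch
#'   (default 25).
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `degenerate`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                degenerate = TRUE, exact = FALSE))
  use_exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
    !any(duplicated(pooled))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = min(wt$p.value, 1),
       degenerate = FALSE,
       exact = use_exact)
}

#' Two-sided Wilcoxon signed-rank test on matched pairs
#'
#' Zero differences are dropped before ranking; exact when the effective
#' number of non-zero differences is at most `exact_max_n` and their
#' absolute values are tie-free, otherwise the normal approximation with
#' continuity correction.
#'
#' @param tumor,normal Paired numeric vectors of equal length (>= 1 pair).
#' @param exact_max_n Largest effective n for the exact branch (default 25).
#' @return List with `statistic` (signed-rank V), `p_value`, `degenerate`,
#'   `exact`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(tumor, normal, exact_max_n = 25) {
  if (!length(tumor) || length(tumor) != length(normal))
    stop("need >= 1 pair of equal-length vectors")
  d <- tumor - normal
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, p_value = 1, degenerate = TRUE,
                exact = FALSE, n_effective = 0L))
  use_exact <- length(d) <= exact_max_n && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = min(wt$p.value, 1),
       degenerate = FALSE,
       exact = use_exact,
       n_effective = length(d))
}

#' Log2 fold change of group means
#'
#' `log2((mean(x) + pseudocount) / (mean(y) + pseudocount))` on the linear
#' abundance scale. The pseudocount guards against zero means; swapping the
#' groups negates the value exactly.
#'
#' @param x,y Numeric vectors (tumor and normal); both non-empty.
#' @param pseudocount Positive stabilizer added to both means (default 1).
#' @return A single number (tumor over normal).
#' @export
log2_fold_change <- function(x, y, pseudocount = 1) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  stopifnot(pseudocount > 0)
  log2((mean(x) + pseudocount) / (mean(y) + pseudocount))
}

de_tier <- function(p) {
  ifelse(p < 0.001, "p_lt_001", ifelse(p < 0.05, "p_lt_05", "ns"))
}

#' Tumor-versus-normal differential expression scan
#'
#' One result per (gene, cohort) for every cohort with at least
#' `min_normals` normal samples; cohorts below the threshold are skipped
#' with a reason (mirroring the exclusion of cohorts that have no normal
#' tissue at all). Unpaired mode uses the rank-sum test over all tumor vs
#' all normal samples; paired mode uses the signed-rank test over matched
#' pairs only. Raw p-values are tiered (`ns`, `p_lt_05`, `p_lt_001`); a
#' BH-adjusted column is emitted alongside but never used for tiering.
#'
#' @param values Gene-by-sample expression matrix (linear scale).
#' @param annot Sample annotation data.frame.
#' @param genes Gene symbols to test (must be present in the matrix).
#' @param min_normals Minimum normal-sample count for a cohort to be tested
#'   (default 1).
#' @param mode `"unpaired"` (rank-sum) or `"paired"` (signed-rank on
#'   matched pairs).
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @param exact_max_n Exact-branch size threshold (default 25).
#' @return A data.frame of class `fgfr_de` with columns `gene`, `cohort`,
#'   `log2fc`, `p_value`, `p_adj`, `n_tumor`, `n_normal`, `tier`, `mode`,
#'   `degenerate`; skipped cohorts in `attr(, "skipped")`.
#' @export
de_scan <- function(values, annot, genes = paste0("FGFR", 1:4),
                    min_normals = 1, mode = c("unpaired", "paired"),
                    pseudocount = 1, exact_max_n = 25) {
  mode <- match.arg(mode)
  values <- expression_matrix(values)
  annot <- sample_annotation(annot)
  missing <- setdiff(genes, rownames(values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))

  cohorts <- sort(unique(annot$cohort))
  rows <- list()
  skipped <- list()
  for (co in cohorts) {
    a <- annot[annot$cohort == co, , drop = FALSE]
    tum <- a$sample_id[a$tissue == "tumor"]
    nor <- a$sample_id[a$tissue == "normal"]
    if (length(nor) == 0L) {
      skipped[[co]] <- data.frame(cohort = co, reason = "no normal tissues")
      next
    }
    if (length(nor) < min_normals) {
      skipped[[co]] <- data.frame(cohort = co,
                                  reason = sprintf("fewer than %d normal samples",
                                                   min_normals))
      next
    }
    if (mode == "paired") {
      pa <- a[!is.na(a$pair_id), , drop = FALSE]
      if (!nrow(pa)) {
        skipped[[co]] <- data.frame(cohort = co, reason = "no matched pairs")
        next
      }
      pt <- pa[pa$tissue == "tumor", c("sample_id", "pair_id")]
      pn <- pa[pa$tissue == "normal", c("sample_id", "pair_id")]
      m <- merge(pt, pn, by = "pair_id", suffixes = c("_t", "_n"))
      tum_p <- m$sample_id_t
      nor_p <- m$sample_id_n
    }
    for (gene in genes) {
      xt <- values[gene, tum]
      xn <- values[gene, nor]
      if (mode == "unpaired") {
        tst <- wilcoxon_rank_sum(xt, xn, exact_max_n = exact_max_n)
        fc <- log2_fold_change(xt, xn, pseudocount)
        nt <- length(tum); nn <- length(nor)
      } else {
        vt <- values[gene, tum_p]
        vn <- values[gene, nor_p]
        tst <- wilcoxon_signed_rank(vt, vn, exact_max_n = exact_max_n)
        fc <- log2_fold_change(vt, vn, pseudocount)
        nt <- length(tum_p); nn <- length(nor_p)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, cohort = co, log2fc = fc, p_value = tst$p_value,
        n_tumor = nt, n_normal = nn, mode = mode,
        degenerate = tst$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), cohort = character(), log2fc = numeric(),
               p_value = numeric(), n_tumor = integer(), n_normal = integer(),
               mode = character(), degenerate = logical())
  out$p_adj <- if (nrow(out)) bh_adjust(out$p_value) else numeric()
  out$tier <- de_tier(out$p_value)
  out <- out[, c("gene", "cohort", "log2fc", "p_value", "p_adj",
                 "n_tumor", "n_normal", "tier", "mode", "degenerate")]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cohort = character(), reason = character())
  class(out) <- c("fgfr_de", "data.frame")
  out
}

#' @export
print.fgfr_de <- function(x, ...) {
  cat(sprintf("Differential expression scan: %d gene x cohort cells (%s)\n",
              nrow(x), if (nrow(x)) x$mode[1] else "empty"))
  sk <- attr(x, "skipped")
  if (nrow(sk))
    cat("Skipped cohorts:",
        paste(sprintf("%s (%s)", sk$cohort, sk$reason), collapse = "; "), "\n")
  cat(sprintf("P < 0.001 in %d cells, P < 0.05 in %d of %d\n",
              sum(x$tier == "p_lt_001"), sum(x$p_value < 0.05), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
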