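#' Default simulated gene panel
#'
#' The 22 human FGF ligand genes (FGF1-14, FGF16-23) plus the four receptor
#' genes FGFR1-4, with staggered baseline log2 abundances so that linear-scale
#' values span the range where expression cutoffs in the thousands are
#' meaningful. Planted fold changes default to zero (pure null).
#'
#' @param log2_sd Per-gene log2-scale standard deviation (default 1.5).
#' @return A data.frame with columns `symbol`, `base_log2_mean`, `log2_sd`,
#'   `log2fc`.
#' @export
default_gene_table <- function(log2_sd = 1.5) {
  symbols <- c(paste0("FGF", c(1:14, 16:23)), paste0("FGFR", 1:4))
  data.frame(symbol = symbols,
             base_log2_mean = seq(6, 12, length.out = length(symbols)),
             log2_sd = log2_sd,
             log2fc = 0,
             stringsAsFactors = FALSE)
}

#' Specify one synthetic tumor cohort
#'
#' Describes a TCGA-like cohort: per-gene log2-normal expression with a
#' planted tumor/normal fold change, overall survival under proportional
#' hazards optionally linked to one gene, independent exponential censoring,
#' and optional matched tumor/normal pairs sharing a latent intercept.
#'
#' @param cohort Cohort code (e.g. `"BLCA"`).
#' @param n_tumor,n_normal Sample counts (>= 0).
#' @param genes Gene table as from [default_gene_table()]: columns `symbol`,
#'   `base_log2_mean`, `log2_sd`, `log2fc`.
#' @param survival_link Optional `list(gene = , log_hr_per_sd = )`: the log
#'   hazard ratio per standard deviation of that gene's log2 expression.
#' @param baseline_hazard Baseline event rate in events/day (default 1/730,
#'   i.e. median survival around two years).
#' @param censor_rate Target fraction of tumors censored (default 0.3).
#' @param matched_fraction Fraction of normals paired to tumors (default 0).
#' @param pair_sd SD of the shared latent per-pair intercept on the log2
#'   scale (default 0.5), giving the paired test real correlation to exploit.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(cohort, n_tumor, n_normal,
                        genes = default_gene_table(),
                        survival_link = NULL,
                        baseline_hazard = 1 / 730,
                        censor_rate = 0.3,
                        matched_fraction = 0,
                        pair_sd = 0.5,
                        seed = 1L) {
  stopifnot(is.character(cohort), length(cohort) == 1L,
            n_tumor >= 0, n_normal >= 0,
            is.data.frame(genes),
            all(c("symbol", "base_log2_mean", "log2_sd", "log2fc") %in%
                  names(genes)),
            all(genes$log2_sd > 0),
            baseline_hazard > 0,
            censor_rate >= 0, censor_rate <= 1,
            matched_fraction >= 0, matched_fraction <= 1,
            pair_sd >= 0)
  if (!is.null(survival_link)) {
    stopifnot(is.list(survival_link),
              all(c("gene", "log_hr_per_sd") %in% names(survival_link)))
    if (!survival_link$gene %in% genes$symbol)
      stop("survival_link gene '", survival_link$gene,
           "' not in the gene list")
  }
  structure(list(cohort = cohort, n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), genes = genes,
                 survival_link = survival_link,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 matched_fraction = matched_fraction,
                 pair_sd = pair_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Censoring rate c solving mean(c / (c + hazard_i)) = target; independent
# exponential censoring keeps the Cox model's non-informative assumption.
solve_censor_rate <- function(hazards, target) {
  if (target <= 0) return(0)
  if (target >= 1) return(Inf)
  f <- function(lc) mean(exp(lc) / (exp(lc) + hazards)) - target
  r <- stats::uniroot(f, lower = log(min(hazards)) - 20,
                      upper = log(max(hazards)) + 20, tol = 1e-12)
  exp(r$root)
}

#' Generate one synthetic cohort
#'
#' Tumor expression for gene g is log2-normal with mean
#' `base_log2_mean + log2fc`; normals sit at `base_log2_mean`. Values are
#' exponentiated to the linear scale (all analyses consume linear
#' abundance). Overall survival times for tumors are exponential with hazard
#' `baseline_hazard * exp(log_hr_per_sd * z)` where z is the standardized
#' log2 expression of the linked gene (constant hazard when no link is
#' given); censoring is an independent exponential whose rate is solved
#' numerically to hit `censor_rate` on average. Matched pairs share a latent
#' per-pair intercept added to both members' log2 values.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `expression` (gene-by-sample matrix, linear scale)
#'   and `annotation` (sample annotation data.frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$genes
  nt <- spec$n_tumor
  nn <- spec$n_normal
  tumor_ids <- if (nt) sprintf("%s-T%04d", spec$cohort, seq_len(nt)) else character()
  normal_ids <- if (nn) sprintf("%s-N%04d", spec$cohort, seq_len(nn)) else character()

  log2t <- matrix(stats::rnorm(nrow(g) * nt,
                               mean = rep(g$base_log2_mean + g$log2fc, nt),
                               sd = rep(g$log2_sd, nt)),
                  nrow = nrow(g), ncol = nt,
                  dimnames = list(g$symbol, tumor_ids))
  log2n <- matrix(stats::rnorm(nrow(g) * nn,
                               mean = rep(g$base_log2_mean, nn),
                               sd = rep(g$log2_sd, nn)),
                  nrow = nrow(g), ncol = nn,
                  dimnames = list(g$symbol, normal_ids))

  n_pairs <- min(round(spec$matched_fraction * nn), nn, nt)
  pair_id <- rep(NA_character_, nt + nn)
  if (n_pairs > 0) {
    b <- stats::rnorm(n_pairs, 0, spec$pair_sd)
    for (k in seq_len(n_pairs)) {
      log2t[, k] <- log2t[, k] + b[k]
      log2n[, k] <- log2n[, k] + b[k]
    }
    ids <- sprintf("%s-P%04d", spec$cohort, seq_len(n_pairs))
    pair_id[seq_len(n_pairs)] <- ids            # first tumors
    pair_id[nt + seq_len(n_pairs)] <- ids       # first normals
  }

  values <- 2^cbind(log2t, log2n)

  os_days <- rep(NA_real_, nt + nn)
  os_event <- rep(NA_integer_, nt + nn)
  if (nt > 0) {
    if (!is.null(spec$survival_link)) {
      lx <- log2t[spec$survival_link$gene, ]
      z <- if (stats::sd(lx) > 0) (lx - mean(lx)) / stats::sd(lx) else lx * 0
      hazard <- spec$baseline_hazard * exp(spec$survival_link$log_hr_per_sd * z)
    } else {
      hazard <- rep(spec$baseline_hazard, nt)
    }
    t_event <- stats::rexp(nt, rate = hazard)
    crate <- solve_censor_rate(hazard, spec$censor_rate)
    t_cens <- if (crate > 0) stats::rexp(nt, rate = crate) else rep(Inf, nt)
    os_days[seq_len(nt)] <- pmax(1, round(pmin(t_event, t_cens)))
    os_event[seq_len(nt)] <- as.integer(t_event <= t_cens)
  }

  annot <- data.frame(sample_id = c(tumor_ids, normal_ids),
                      cohort = spec$cohort,
                      tissue = c(rep("tumor", nt), rep("normal", nn)),
                      pair_id = pair_id,
                      os_days = os_days,
                      os_event = os_event,
                      stringsAsFactors = FALSE)
  list(expression = expression_matrix(values),
       annotation = sample_annotation(annot))
}

#' Generate a merged pan-cancer dataset from several cohort specs
#'
#' Column-wise concatenation over cohorts (codes must be unique; all specs
#' must share one gene panel), emulating a multi-cohort atlas layout in
#' which some cohorts may have no normal tissue at all.
#'
#' @param specs List of [cohort_spec()] objects.
#' @return A list with merged `expression` and `annotation`.
#' @export
generate_pancancer <- function(specs) {
  stopifnot(length(specs) >= 1L)
  codes <- vapply(specs, function(s) s$cohort, character(1))
  dup <- unique(codes[duplicated(codes)])
  if (length(dup))
    stop("duplicate cohort code(s): ", paste(dup, collapse = ", "))
  parts <- lapply(specs, generate_cohort)
  genes0 <- rownames(parts[[1]]$expression)
  for (p in parts)
    if (!identical(rownames(p$expression), genes0))
      stop("all cohort specs must share the same gene panel")
  list(expression = expression_matrix(
         do.call(cbind, lapply(parts, `[[`, "expression"))),
       annotation = sample_annotation(
         do.call(rbind, lapply(parts, `[[`, "annotation"))))
}

#' Specify a synthetic cell-line panel
#'
#' Describes a GDSC-like panel: log2-normal expression over a gene table,
#' per-line natural-log IC50 linearly linked to the standardized log2
#' expression of one gene, additive effects of binary mutation markers, and
#' Gaussian noise.
#'
#' @param n_lines Number of cell lines (>= 0).
#' @param tissue_mix Named numeric vector of tissue fractions summing to 1.
#' @param genes Gene table as from [default_gene_table()].
#' @param response_link `list(gene = , beta = , alpha = , noise_sd = )`:
#'   log-IC50 slope per SD of log2 expression, intercept, and noise SD.
#' @param markers Optional data.frame with columns `gene`, `prevalence`,
#'   `delta` (additive log-IC50 shift in mutant lines).
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_lines,
                       tissue_mix = c(PAN = 1),
                       genes = default_gene_table(),
                       response_link = list(gene = "FGFR1", beta = -0.8,
                                            alpha = 3, noise_sd = 1),
                       markers = NULL,
                       seed = 1L) {
  stopifnot(n_lines >= 0,
            is.numeric(tissue_mix), !is.null(names(tissue_mix)),
            abs(sum(tissue_mix) - 1) < 1e-9,
            is.list(response_link),
            all(c("gene", "beta", "alpha", "noise_sd") %in%
                  names(response_link)),
            response_link$noise_sd > 0)
  if (!response_link$gene %in% genes$symbol)
    stop("response_link gene '", response_link$gene,
         "' not in the gene list")
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers),
              all(c("gene", "prevalence", "delta") %in% names(markers)),
              all(markers$prevalence >= 0 & markers$prevalence <= 1))
  }
  structure(list(n_lines = as.integer(n_lines), tissue_mix = tissue_mix,
                 genes = genes, response_link = response_link,
                 markers = markers, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Validate a cell-line panel
#'
#' @param expression Gene-by-line expression matrix (linear scale).
#' @param log_ic50 Named numeric vector of natural-log IC50, one per line.
#' @param tissue Named character vector of tissue labels, one per line.
#' @param mutations Binary marker-gene-by-line matrix (may have 0 rows).
#' @return A `cell_line_panel` list.
#' @export
cell_line_panel <- function(expression, log_ic50, tissue, mutations) {
  expression <- expression_matrix(expression)
  lines <- colnames(expression)
  same_ids <- function(a) identical(sort(as.character(a)),
                                    sort(as.character(lines)))
  if (!same_ids(names(log_ic50)))
    stop("log_ic50 names must match expression samples")
  if (!all(is.finite(log_ic50)))
    stop("log_ic50 must be finite")
  if (!same_ids(names(tissue)))
    stop("tissue names must match expression samples")
  stopifnot(is.matrix(mutations))
  if (ncol(mutations) != length(lines) || !same_ids(colnames(mutations)))
    stop("mutation columns must match expression samples")
  if (nrow(mutations) && !all(mutations %in% c(0, 1)))
    stop("mutation markers must be strictly binary")
  structure(list(expression = expression,
                 log_ic50 = log_ic50[lines],
                 tissue = tissue[lines],
                 mutations = mutations[, lines, drop = FALSE]),
            class = "cell_line_panel")
}

#' @export
print.cell_line_panel <- function(x, ...) {
  cat(sprintf("<cell_line_panel> %d lines, %d genes, %d mutation markers, %d tissues\n",
              ncol(x$expression), nrow(x$expression), nrow(x$mutations),
              length(unique(x$tissue))))
  invisible(x)
}

#' Generate a synthetic cell-line panel
#'
#' `log_ic50 = alpha + beta * z(log2 expr of linked gene) +
#' sum(delta_m * marker_m) + N(0, noise_sd)`; markers are Bernoulli with the
#' specified prevalences. Tissue labels are assigned deterministically by
#' largest-remainder apportionment of the mix fractions. An empty panel
#' (`n_lines = 0`) is valid and carried with an `empty` attribute.
#'
#' @param spec A [panel_spec()].
#' @return A `cell_line_panel`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_lines
  g <- spec$genes
  ids <- if (n) sprintf("CL%04d", seq_len(n)) else character()

  log2e <- matrix(stats::rnorm(nrow(g) * n,
                               mean = rep(g$base_log2_mean, n),
                               sd = rep(g$log2_sd, n)),
                  nrow = nrow(g), ncol = n,
                  dimnames = list(g$symbol, ids))

  mk <- spec$markers
  n_mk <- if (is.null(mk)) 0L else nrow(mk)
  mut <- matrix(0, nrow = n_mk, ncol = n,
                dimnames = list(if (n_mk) mk$gene else NULL, ids))
  if (n_mk && n)
    for (i in seq_len(n_mk))
      mut[i, ] <- stats::rbinom(n, 1L, mk$prevalence[i])

  # deterministic tissue apportionment (largest remainder)
  counts <- integer(length(spec$tissue_mix))
  if (n) {
    raw <- spec$tissue_mix * n
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
  }
  tissue <- rep(names(spec$tissue_mix), counts)
  names(tissue) <- ids

  if (n) {
    lx <- log2e[spec$response_link$gene, ]
    z <- if (n > 1 && stats::sd(lx) > 0) (lx - mean(lx)) / stats::sd(lx) else lx * 0
    ic <- spec$response_link$alpha + spec$response_link$beta * z +
      stats::rnorm(n, 0, spec$response_link$noise_sd)
    if (n_mk) ic <- ic + as.numeric(crossprod(mut, mk$delta))
  } else ic <- numeric()
  names(ic) <- ids

  panel <- cell_line_panel(2^log2e, ic, tissue, mut)
  attr(panel, "empty") <- n == 0L
  panel
}
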