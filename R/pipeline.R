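#' Derive a stage-specific child seed from a global seed
#'
#' Deterministic fan-out of one global seed into independent per-stage
#' seeds via a polynomial hash of the stage name, so adding a stage never
#' shifts another stage's random stream. Result is always in \[1, 2^31 - 2\].
#'
#' @param seed Global integer seed.
#' @param stage Stage name, e.g. `"diffexpr"`.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 7919 + h) %%
               2147483645 + 1)
}

#' Assemble a full pipeline run configuration
#'
#' Collects input paths, gene lists, every stage threshold and the global
#' seed. Thresholds default to the study constants: 30-day follow-up
#' filter, 0.1 minimum cutpoint group fraction, P < 1e-3 and FDR <= 25%
#' marker calls, 42% target prevalence, pseudocount 1. The configuration
#' round-trips through JSON unchanged.
#'
#' @param matrix_path,annot_path Expression / annotation TSV paths.
#' @param panel_expr_path,ic50_path,mutations_path Optional cell-line panel
#'   TSVs (expression, two-column `sample_id`/`log_ic50`, binary marker
#'   matrix).
#' @param genes Genes for the DE and survival scans.
#' @param corr_genes Genes for the expression-IC50 scan.
#' @param min_normals,min_days,min_prop,p_threshold,fdr_threshold,target_prevalence,pseudocount
#'   Stage thresholds (see the stage functions).
#' @param gene_set,reference_cohort,report_genes Positivity settings.
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(matrix_path, annot_path,
                       panel_expr_path = NULL, ic50_path = NULL,
                       mutations_path = NULL,
                       genes = c(paste0("FGF", c(1:14, 16:23)),
                                 paste0("FGFR", 1:4)),
                       corr_genes = c("FGFR1", "FGFR3"),
                       min_normals = 1, min_days = 30, min_prop = 0.1,
                       p_threshold = 1e-3, fdr_threshold = 0.25,
                       target_prevalence = 0.42, pseudocount = 1,
                       gene_set = c("FGFR1", "FGFR3"),
                       reference_cohort = "BLCA",
                       report_genes = paste0("FGFR", 1:4),
                       seed = 1L, out_dir = ".") {
  stopifnot(min_days >= 0, min_prop >= 0, min_prop < 0.5,
            p_threshold > 0, p_threshold <= 1,
            fdr_threshold > 0, fdr_threshold <= 1,
            target_prevalence > 0, target_prevalence < 1,
            pseudocount > 0)
  structure(list(matrix_path = matrix_path, annot_path = annot_path,
                 panel_expr_path = panel_expr_path, ic50_path = ic50_path,
                 mutations_path = mutations_path,
                 genes = genes, corr_genes = corr_genes,
                 min_normals = min_normals, min_days = min_days,
                 min_prop = min_prop, p_threshold = p_threshold,
                 fdr_threshold = fdr_threshold,
                 target_prevalence = target_prevalence,
                 pseudocount = pseudocount, gene_set = gene_set,
                 reference_cohort = reference_cohort,
                 report_genes = report_genes,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

read_panel_inputs <- function(config) {
  expr <- read_expression_matrix(config$panel_expr_path)
  ic <- utils::read.delim(config$ic50_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "log_ic50") %in% names(ic)))
    stop("IC50 table needs columns sample_id, log_ic50")
  log_ic50 <- ic$log_ic50
  names(log_ic50) <- ic$sample_id
  tissue <- if ("tissue_type" %in% names(ic)) {
    tt <- ic$tissue_type; names(tt) <- ic$sample_id; tt
  } else {
    tt <- rep("PAN", nrow(ic)); names(tt) <- ic$sample_id; tt
  }
  mut <- if (!is.null(config$mutations_path)) {
    m <- read_expression_matrix(config$mutations_path)
    storage.mode(m) <- "double"
    m
  } else matrix(0, 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  cell_line_panel(expr, log_ic50, tissue, mut)
}

#' Run the full biomarker pipeline
#'
#' Stages run in order: differential expression, survival, drug
#' sensitivity (only when a cell-line panel is configured), positivity.
#' Each stage writes a TSV plus a JSON sidecar echoing its parameters; a
#' manifest lists every output with its MD5 digest, so identical
#' config + seed yields identical digests. A stage failure halts the run
#' with the failing stage named and a `FAILED` marker file preserved next
#' to any partial outputs.
#'
#' @param config A [run_config()].
#' @return The manifest list (`stages`: name, path, digest; `config` echo),
#'   invisibly; also written to `manifest.json` in `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  values <- read_expression_matrix(config$matrix_path)
  annot <- read_sample_annotation(config$annot_path)
  input_digests <- tools::md5sum(c(config$matrix_path, config$annot_path))

  stages <- list()
  emit <- function(stage, rows, extra = list()) {
    path <- file.path(config$out_dir, paste0(stage, ".tsv"))
    write_result_table(rows, path, metadata = c(list(
      stage = stage, seed = config$seed,
      stage_seed = derive_seed(config$seed, stage),
      input_digests = as.list(input_digests)), extra))
    stages[[stage]] <<- list(stage = stage, path = path,
                             digest = unname(tools::md5sum(path)))
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(paste0("stage ", stage, ": ", conditionMessage(res)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline halted at stage '", stage, "': ",
           conditionMessage(res), call. = FALSE)
    }
    res
  }

  de <- run_stage("diffexpr", function()
    de_scan(values, annot, genes = config$genes,
            min_normals = config$min_normals,
            pseudocount = config$pseudocount))
  emit("diffexpr", as.data.frame(de),
       list(skipped = attr(de, "skipped"),
            min_normals = config$min_normals))

  sv <- run_stage("survival", function()
    survival_scan(values, annot, genes = config$genes,
                  min_days = config$min_days, min_prop = config$min_prop,
                  seed = derive_seed(config$seed, "survival")))
  emit("survival", as.data.frame(sv),
       list(min_days = config$min_days, min_prop = config$min_prop))

  if (!is.null(config$panel_expr_path)) {
    panel <- run_stage("drugsens", function() read_panel_inputs(config))
    corr <- run_stage("drugsens", function()
      expr_ic50_scan(panel, genes = config$corr_genes))
    emit("drugsens_correlation", as.data.frame(corr),
         list(skipped = attr(corr, "skipped")))
    if (nrow(panel$mutations)) {
      mk <- run_stage("drugsens", function()
        marker_scan(panel, p_threshold = config$p_threshold,
                    fdr_threshold = config$fdr_threshold))
      emit("drugsens_markers", as.data.frame(mk),
           list(p_threshold = config$p_threshold,
                fdr_threshold = config$fdr_threshold))
    }
  } else {
    message("no cell-line panel configured; drug-sensitivity stage skipped")
  }

  pos_cfg <- positivity_config(gene_set = config$gene_set,
                               reference_cohort = config$reference_cohort,
                               target_prevalence = config$target_prevalence,
                               report_genes = config$report_genes)
  pos <- run_stage("positivity", function()
    positivity_scan(values, annot, pos_cfg,
                    seed = derive_seed(config$seed, "positivity")))
  emit("positivity", pos$table,
       list(cutoff = pos$cutoff,
            achieved_reference_ratio = pos$achieved_reference_ratio,
            target_prevalence = config$target_prevalence,
            reference_cohort = config$reference_cohort,
            gene_set = config$gene_set,
            note = "report genes reuse the single calibrated cutoff"))

  manifest <- list(stages = unname(stages), config = unclass(config))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
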