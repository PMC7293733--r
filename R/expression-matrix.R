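#' Validate a gene-by-sample expression matrix
#'
#' The package exchanges expression as a plain numeric matrix with genes in
#' rows and samples in columns, on the linear (RSEM-like) normalized
#' abundance scale. Log transforms are applied per analysis stage, never at
#' I/O, because the positivity cutoff lives on the linear scale.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @return The validated matrix, invisibly unchanged.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("FGFR1", "FGFR3"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  # R normalizes empty dimnames to NULL; zero-extent dimensions are legal
  if ((is.null(genes) && nrow(values) > 0L) ||
      (is.null(samples) && ncol(values) > 0L))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (is.null(genes)) genes <- character()
  if (is.null(samples)) samples <- character()
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicate gene symbol(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "expression values must be finite and non-negative; first offender at gene '%s', sample '%s'",
      genes[bad[1, 1]], samples[bad[1, 2]]))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a single header line; the first column holds row labels
#' (gene symbols for `genes_in_rows`, sample IDs for `samples_in_rows`).
#' The matrix is normalized to genes-in-rows internally.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A validated gene-by-sample numeric matrix.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression file: ", path)
  labels <- raw[[1]]
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate row label(s) in ", path, ": ", paste(dup, collapse = ", "))
  cols <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(cols),
                 dimnames = list(labels, cols))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf(
        "non-numeric or negative cell in %s at row '%s', column '%s' (value '%s')",
        path, labels[bad[1]], cols[j], raw[[j + 1L]][bad[1]]))
    vals[, j] <- v
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals)
}

#' Write an expression matrix to TSV
#'
#' Genes-in-rows dialect: `gene_symbol<TAB>s1<TAB>s2...`, UTF-8, "." decimal
#' separator. Values round-trip exactly for decimal representations up to
#' (at least) 6 significant digits.
#'
#' @param values Gene-by-sample numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(values, path) {
  values <- expression_matrix(values)
  df <- data.frame(gene_symbol = rownames(values),
                   values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sample annotation table
#'
#' Required columns: `sample_id`, `cohort`, `tissue` (`"tumor"` or
#' `"normal"`). Optional: `pair_id` (links exactly one tumor and one normal
#' sample), `os_days` (non-negative days of overall survival) and `os_event`
#' (1 = death observed, 0 = censored); the two survival fields must be
#' present or absent together on each row. Extra columns are preserved.
#'
#' @param annot A data.frame.
#' @return The validated data.frame (tissue as character, os_event integer).
#' @export
sample_annotation <- function(annot) {
  if (!is.data.frame(annot)) stop("annotation must be a data.frame")
  req <- c("sample_id", "cohort", "tissue")
  miss <- setdiff(req, names(annot))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  annot$sample_id <- as.character(annot$sample_id)
  annot$cohort <- as.character(annot$cohort)
  annot$tissue <- as.character(annot$tissue)
  dup <- unique(annot$sample_id[duplicated(annot$sample_id)])
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  bad_tissue <- setdiff(unique(annot$tissue), c("tumor", "normal"))
  if (length(bad_tissue))
    stop("tissue must be 'tumor' or 'normal'; found: ",
         paste(bad_tissue, collapse = ", "))
  if (is.null(annot$pair_id)) annot$pair_id <- NA_character_
  annot$pair_id <- as.character(annot$pair_id)
  annot$pair_id[!is.na(annot$pair_id) & annot$pair_id == ""] <- NA_character_
  if (is.null(annot$os_days)) annot$os_days <- NA_real_
  if (is.null(annot$os_event)) annot$os_event <- NA_integer_
  annot$os_days <- suppressWarnings(as.numeric(annot$os_days))
  annot$os_event <- suppressWarnings(as.integer(annot$os_event))
  mism <- is.na(annot$os_days) != is.na(annot$os_event)
  if (any(mism))
    stop("os_days and os_event must be present together; offending sample(s): ",
         paste(annot$sample_id[mism], collapse = ", "))
  if (any(annot$os_days < 0, na.rm = TRUE))
    stop("os_days must be non-negative")
  if (!all(annot$os_event %in% c(0L, 1L, NA_integer_)))
    stop("os_event must be 1 (event) or 0 (censored)")
  pid <- annot$pair_id[!is.na(annot$pair_id)]
  for (p in unique(pid)) {
    members <- annot$tissue[!is.na(annot$pair_id) & annot$pair_id == p]
    if (!(length(members) == 2L && all(sort(members) == c("normal", "tumor"))))
      stop("pair_id '", p,
           "' must link exactly one tumor and one normal sample")
  }
  annot
}

#' Read a sample annotation TSV
#'
#' Columns `sample_id`, `cohort`, `tissue` and optional `pair_id`,
#' `os_days`, `os_event` (encoded 1 = event, 0 = censored on disk).
#'
#' @param path Path to a TSV file.
#' @return A validated annotation data.frame.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sample_annotation(raw)
}

#' Write a sample annotation TSV
#' @param annot Annotation data.frame (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annot, path) {
  annot <- sample_annotation(annot)
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a matrix and its annotations to one cohort
#'
#' Matrix samples without an annotation row are dropped (with a message
#' giving the count); every annotated sample must be present in the matrix.
#'
#' @param values Gene-by-sample expression matrix.
#' @param annot Sample annotation data.frame.
#' @param cohort Cohort code, e.g. `"BLCA"`.
#' @return A list with elements `expression` (matrix subset, columns are the
#'   cohort's samples) and `annotation` (matching rows), class `cohort_view`.
#' @export
join_cohort <- function(values, annot, cohort) {
  values <- expression_matrix(values)
  annot <- sample_annotation(annot)
  missing_in_matrix <- setdiff(annot$sample_id, colnames(values))
  if (length(missing_in_matrix))
    stop("annotated sample(s) absent from matrix: ",
         paste(utils::head(missing_in_matrix, 5), collapse = ", "))
  unannotated <- setdiff(colnames(values), annot$sample_id)
  if (length(unannotated))
    message(length(unannotated), " matrix sample(s) without annotation dropped")
  if (!cohort %in% annot$cohort)
    stop("cohort '", cohort, "' not found; available: ",
         paste(sort(unique(annot$cohort)), collapse = ", "))
  sub <- annot[annot$cohort == cohort, , drop = FALSE]
  out <- list(expression = values[, sub$sample_id, drop = FALSE],
              annotation = sub,
              cohort = cohort)
  class(out) <- "cohort_view"
  out
}

#' @export
print.cohort_view <- function(x, ...) {
  cat(sprintf("<cohort_view> %s: %d genes x %d samples (%d tumor, %d normal)\n",
              x$cohort, nrow(x$expression), ncol(x$expression),
              sum(x$annotation$tissue == "tumor"),
              sum(x$annotation$tissue == "normal")))
  invisible(x)
}

#' Write a result table with a JSON metadata sidecar
#'
#' Results are one record per row in TSV; a `<path>.json` sidecar echoes the
#' run configuration (seeds, thresholds, input digests) so every output is
#' self-describing.
#'
#' @param rows A data.frame of results.
#' @param path Output TSV path.
#' @param metadata Named list echoed into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path, metadata = list()) {
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, logical(1))
  for (j in which(num)) {
    # NA marks a flagged not-computable cell and +/-Inf a documented
    # sentinel (monotone-likelihood hazard ratios); NaN is always a bug.
    if (any(is.nan(rows[[j]])))
      stop("NaN value in result column '", names(rows)[j], "'")
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(metadata, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
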