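#' Expression matrix with sample annotations
#'
#' `expr_mat` is the carrier object for gene expression throughout the
#' pipeline: a numeric gene x sample matrix together with per-sample cohort
#' and tissue annotations and a processing-stage tag. The stage tag records
#' the unit of the values (`"raw"` FPKM or RMA-like intensities, `"log"`
#' log2-transformed, `"harmonized"` batch-corrected, `"zscored"` per-gene
#' standardized) so downstream operations can check their preconditions.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with one row per column of `values`, columns
#'   `sample_id`, `cohort` (one of `"preclinical"`, `"clinical"`) and
#'   `tissue`. Row order must match the column order of `values`.
#' @param stage Processing stage, one of `"raw"`, `"log"`, `"harmonized"`,
#'   `"zscored"`.
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, samples, stage = "raw") {
  values <- as.matrix(values)
  samples <- tibble::as_tibble(samples)
  obj <- structure(
    list(values = values, samples = samples, stage = stage),
    class = "expr_mat"
  )
  validate_expr_mat(obj)
}

expr_stages <- c("raw", "log", "harmonized", "zscored")
cohort_levels <- c("preclinical", "clinical")

validate_expr_mat <- function(x) {
  stopifnot(inherits(x, "expr_mat"), is.matrix(x$values))
  gid <- rownames(x$values)
  sid <- colnames(x$values)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s) > 0) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  req <- c("sample_id", "cohort", "tissue")
  miss <- setdiff(req, names(x$samples))
  if (length(miss) > 0) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(x$samples$sample_id), sid)) {
    stop("sample metadata rows must match matrix columns (same ids, same order)",
         call. = FALSE)
  }
  bad_cohort <- setdiff(unique(x$samples$cohort), cohort_levels)
  if (length(bad_cohort) > 0) {
    stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "),
         call. = FALSE)
  }
  if (!x$stage %in% expr_stages) {
    stop("unknown stage: ", x$stage, call. = FALSE)
  }
  if (x$stage != "raw" && anyNA(x$values)) {
    stop("missing values are only allowed at stage 'raw'", call. = FALSE)
  }
  x
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d genes x %d samples, stage = %s\n",
    nrow(x$values), ncol(x$values), x$stage
  ))
  tab <- table(x$samples$cohort)
  cat("cohorts:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("tissues:", paste(sort(unique(x$samples$tissue)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of gene ids in row order.
#' @export
genes <- function(x) rownames(x$values)

#' Long-format view of an expression matrix
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `cohort`, `tissue`,
#'   `value` (one row per matrix cell).
#' @export
as_tibble.expr_mat <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Subset an expression matrix
#'
#' @param x An `expr_mat`.
#' @param genes Optional character vector of gene ids to keep (in the given
#'   order).
#' @param samples Optional character vector of sample ids to keep.
#' @return An `expr_mat` restricted to the requested rows/columns.
#' @export
expr_subset <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  s <- x$samples
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(v))
    if (length(missing_g) > 0) {
      stop("gene(s) not present: ", paste(utils::head(missing_g, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(v))
    if (length(missing_s) > 0) {
      stop("sample(s) not present: ", paste(utils::head(missing_s, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[, samples, drop = FALSE]
    s <- s[match(samples, s$sample_id), , drop = FALSE]
  }
  expr_mat(v, s, stage = x$stage)
}

#' Combine two expression matrices over a shared gene set
#'
#' Column-binds two cohorts that have already been restricted to an identical
#' ordered gene set (see [harmonize_gene_space()]). Used to pool cohorts
#' before batch correction.
#'
#' @param a,b `expr_mat` objects with identical gene ids in identical order
#'   and disjoint sample ids.
#' @return A pooled `expr_mat`; the stage must agree between inputs.
#' @export
bind_expr <- function(a, b) {
  if (!identical(rownames(a$values), rownames(b$values))) {
    stop("gene sets differ; run harmonize_gene_space() first", call. = FALSE)
  }
  if (!identical(a$stage, b$stage)) {
    stop("stages differ: ", a$stage, " vs ", b$stage, call. = FALSE)
  }
  expr_mat(cbind(a$values, b$values),
           dplyr::bind_rows(a$samples, b$samples),
           stage = a$stage)
}

#' Split a pooled expression matrix by cohort
#'
#' @param x A pooled `expr_mat`.
#' @return Named list with elements `preclinical` and `clinical` (only the
#'   cohorts present).
#' @export
split_by_cohort <- function(x) {
  out <- lapply(split(x$samples$sample_id, x$samples$cohort), function(ids) {
    expr_subset(x, samples = ids)
  })
  out
}

#' Read a delimited expression table with sample metadata
#'
#' Expression files have gene ids in the first column and one column per
#' sample; the metadata file has one row per sample with columns
#' `sample_id`, `cohort`, `tissue`. Tab- and comma-delimited files are both
#' accepted (delimiter sniffed from the header line).
#'
#' @param path Path to the expression table.
#' @param metadata_path Path to the sample metadata table.
#' @param stage Stage tag to record on the result (default `"raw"`).
#' @return An `expr_mat`.
#' @export
read_expression_table <- function(path, metadata_path, stage = "raw") {
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene id column plus samples", call. = FALSE)
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "" & toupper(cells) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric value '%s' at gene row %d ('%s'), sample column %d ('%s')",
                 cells[i, j], i, gene_ids[i], j, colnames(cells)[j]), call. = FALSE)
  }
  rownames(num) <- gene_ids

  md_delim <- sniff_delim(metadata_path)
  meta <- readr::read_delim(metadata_path, delim = md_delim, show_col_types = FALSE,
                            progress = FALSE)
  missing_meta <- setdiff(colnames(num), meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("sample(s) missing from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(colnames(num), meta$sample_id), , drop = FALSE]
  expr_mat(num, meta, stage = stage)
}

#' Write an expression matrix and its metadata as delimited text
#'
#' @param x An `expr_mat`.
#' @param path Output path for the expression table (tab-delimited).
#' @param metadata_path Optional output path for the sample metadata.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, path, metadata_path = NULL) {
  df <- tibble::as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_tsv(x$samples, metadata_path, progress = FALSE)
  }
  invisible(x)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
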