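#' Filter and log-transform a tumor FPKM matrix
#'
#' Mirrors the standard RNA-seq preprocessing used for the clinical cohort:
#' genes with any missing value are dropped, genes that are not expressed
#' (FPKM below `not_expressed_threshold`) in strictly more than
#' `max_unexpressed_fraction` of samples are dropped, and the surviving
#' values are transformed to `log2(value + pseudo)`. The boundary is strict:
#' a gene unexpressed in exactly 90% of samples is retained under the
#' defaults.
#'
#' The preclinical (RMA-like microarray) cohort does not pass through this
#' step: its intensities are already continuous on a log-like scale and are
#' required to be complete.
#'
#' @param mat An `expr_mat` at stage `"raw"` holding non-negative FPKM values.
#' @param not_expressed_threshold FPKM value below which a gene counts as not
#'   expressed in a sample (default 1).
#' @param max_unexpressed_fraction Fraction of samples above which (strictly)
#'   an unexpressed gene is dropped (default 0.9).
#' @param pseudo Offset added before the log2 transform (default 0.1).
#' @return An `expr_mat` at stage `"log"`.
#' @export
preprocess_tumor_fpkm <- function(mat, not_expressed_threshold = 1,
                                  max_unexpressed_fraction = 0.9,
                                  pseudo = 0.1) {
  stopifnot(inherits(mat, "expr_mat"))
  if (mat$stage != "raw") {
    stop("preprocess_tumor_fpkm() expects stage 'raw', got '", mat$stage, "'",
         call. = FALSE)
  }
  v <- mat$values
  if (any(v < 0, na.rm = TRUE)) stop("FPKM values must be non-negative", call. = FALSE)
  keep <- !apply(v, 1, anyNA)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) > 0) {
    frac_unexpressed <- rowMeans(v < not_expressed_threshold)
    v <- v[frac_unexpressed <= max_unexpressed_fraction, , drop = FALSE]
  }
  if (nrow(v) == 0) {
    stop("no genes survive the expression filter", call. = FALSE)
  }
  expr_mat(log2(v + pseudo), mat$samples, stage = "log")
}

#' Restrict two cohorts to shared, variable genes
#'
#' Both matrices are restricted to the identical ordered intersection of
#' their gene sets (order taken from `a`), then genes whose standard
#' deviation across the pooled samples of both cohorts is below `sd_min`
#' are removed. Standard deviations are population-style (divide by n) so
#' that the downstream z-scoring postcondition is exact.
#'
#' @param a,b `expr_mat` objects on a continuous (log or RMA-like) scale.
#' @param sd_min Minimum pooled standard deviation to keep a gene
#'   (default 0.1).
#' @return A list with elements `a` and `b`, both restricted to the same
#'   ordered gene set.
#' @export
harmonize_gene_space <- function(a, b, sd_min = 0.1) {
  stopifnot(inherits(a, "expr_mat"), inherits(b, "expr_mat"))
  shared <- intersect(rownames(a$values), rownames(b$values))
  if (length(shared) == 0) stop("no shared genes between cohorts", call. = FALSE)
  va <- a$values[shared, , drop = FALSE]
  vb <- b$values[shared, , drop = FALSE]
  pooled_sd <- row_sds_pop(cbind(va, vb))
  keep <- shared[pooled_sd >= sd_min]
  if (length(keep) == 0) stop("no genes survive the variability filter", call. = FALSE)
  list(
    a = expr_mat(va[keep, , drop = FALSE], a$samples, stage = a$stage),
    b = expr_mat(vb[keep, , drop = FALSE], b$samples, stage = b$stage)
  )
}

#' Z-score each gene across all samples
#'
#' Centers and scales each gene row to mean 0 and (population) standard
#' deviation 1. Genes with zero variance are an error: they should already
#' have been removed by [harmonize_gene_space()].
#'
#' @param mat An `expr_mat`.
#' @return An `expr_mat` at stage `"zscored"`.
#' @export
zscore_normalize <- function(mat) {
  stopifnot(inherits(mat, "expr_mat"))
  v <- mat$values
  mu <- rowMeans(v)
  sdv <- row_sds_pop(v)
  zero <- rownames(v)[sdv == 0]
  if (length(zero) > 0) {
    stop("zero-variance gene(s): ", paste(utils::head(zero, 5), collapse = ", "),
         call. = FALSE)
  }
  z <- (v - mu) / sdv
  expr_mat(z, mat$samples, stage = "zscored")
}

# population (divide-by-n) row standard deviations
row_sds_pop <- function(m) {
  sqrt(pmax(rowMeans(m * m) - rowMeans(m)^2, 0))
}
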