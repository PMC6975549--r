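#' Remove the cohort batch effect from a pooled expression matrix
#'
#' Applies parametric empirical-Bayes batch correction (the ComBat
#' algorithm, via \pkg{sva}) to a pooled preclinical + clinical matrix,
#' treating the cohort as the sole batch factor with no covariates. The
#' correction is transductive: it sees the pooled train and test expression
#' at once, but never any response label. `method = "none"` is an identity
#' backend used for the no-homogenization ablation; it only re-tags the
#' stage.
#'
#' @param pooled An `expr_mat` containing both cohorts on a shared gene set
#'   (see [bind_expr()]). Every gene must have nonzero pooled variance.
#' @param method `"combat"` (default) or `"none"`.
#' @return An `expr_mat` at stage `"harmonized"` with identical shape and
#'   ordering.
#' @export
combat_correct <- function(pooled, method = c("combat", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(pooled, "expr_mat"))
  batch <- pooled$samples$cohort
  tab <- table(batch)
  if (length(tab) < 2) {
    stop("batch correction needs both cohorts; found only: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  if (any(tab < 2)) {
    stop("each cohort needs at least 2 samples for batch correction", call. = FALSE)
  }
  if (method == "none") {
    return(expr_mat(pooled$values, pooled$samples, stage = "harmonized"))
  }
  sds <- row_sds_pop(pooled$values)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) must be removed before batch correction: ",
         paste(utils::head(rownames(pooled$values)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  corrected <- suppressMessages(
    sva::ComBat(dat = pooled$values, batch = factor(batch), mod = NULL,
                par.prior = TRUE, prior.plots = FALSE)
  )
  dimnames(corrected) <- dimnames(pooled$values)
  expr_mat(corrected, pooled$samples, stage = "harmonized")
}
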