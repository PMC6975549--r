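# Small in-code fixtures shared across test files.

make_expr <- function(values, cohort = "clinical", tissue = NULL, stage = "raw") {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(tissue)) tissue <- rep("lung", n)
  expr_mat(values,
           tibble::tibble(sample_id = colnames(values),
                          cohort = rep_len(cohort, n),
                          tissue = rep_len(tissue, n)),
           stage = stage)
}

# paired cohorts with a planted batch shift, for harmonization tests
make_batch_pair <- function(n_genes = 30, n_per = 50, shift = 0, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_genes * n_per, 5, 1), n_genes,
              dimnames = list(paste0("g", 1:n_genes), paste0("a", 1:n_per)))
  b <- matrix(rnorm(n_genes * n_per, 5 + shift, 1), n_genes,
              dimnames = list(paste0("g", 1:n_genes), paste0("b", 1:n_per)))
  pooled <- cbind(a, b)
  expr_mat(pooled,
           tibble::tibble(
             sample_id = colnames(pooled),
             cohort = rep(c("preclinical", "clinical"), each = n_per),
             tissue = "lung"
           ),
           stage = "log")
}

small_sim <- function(seed = 1, n_ccl = 20, n_tumor = 10, ...) {
  sim_config(n_genes = 200, tissues = paste0("t", 1:3), n_ccl = n_ccl,
             n_tumor = n_tumor, signature_sizes = c(5, 10, 25), n_drugs = 2,
             private_tissues = 1, seed = seed, ...)
}

new_lasso_model_for_test <- function(coefs) {
  structure(list(coefficients = coefs, intercept = 0, alpha = 0.1,
                 n_train = 10L),
            class = "lasso_model")
}

# run the harmonization front half of the pipeline on a synthetic bundle
zscore_cohorts <- function(bundle, method = "combat") {
  tl <- preprocess_tumor_fpkm(bundle$tumor)
  sh <- harmonize_gene_space(bundle$ccl, tl)
  pooled <- combat_correct(bind_expr(sh$a, sh$b), method = method)
  split_by_cohort(zscore_normalize(pooled))
}
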