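#' Tissue-guided selection of the LASSO penalty
#'
#' Implements the core of TG-LASSO's hyperparameter tuning for one target
#' tissue: all training cell lines of tissue `tissue` are held out as the
#' validation set, a LASSO path is fitted on the cell lines of every other
#' tissue, and the penalty minimizing the mean squared error on the held-out
#' tissue is returned. Ties prefer the larger (sparser) penalty.
#'
#' Returns `NA` to signal that the fallback model is needed: when no cell
#' line carries the tissue label, or fewer than 2 cell lines remain in the
#' training complement.
#'
#' @param X Cell-line feature matrix (samples x genes).
#' @param y Cell-line log IC50 vector.
#' @param tissues Per-row tissue labels for `X`.
#' @param tissue Target tissue whose cell lines form the validation set.
#' @param grid Decreasing penalty grid (see [make_alpha_grid()]).
#' @return Selected penalty, or `NA_real_` when the fallback is required.
#' @export
tissue_guided_alpha <- function(X, y, tissues, tissue, grid) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(tissues) == length(y))
  hold <- tissues == tissue
  if (!any(hold) || sum(!hold) < 2) return(NA_real_)
  preds <- path_predict(X[!hold, , drop = FALSE], y[!hold], grid,
                        X[hold, , drop = FALSE])
  mse <- colMeans((preds - y[hold])^2)
  grid[which.min(mse)]
}

#' Fit TG-LASSO for one drug and predict tumor log IC50
#'
#' For each tissue present in the tumor cohort, the penalty is selected by
#' [tissue_guided_alpha()] (holding out that tissue's cell lines as
#' validation), then a single model is refitted on *all* eligible cell
#' lines with that penalty and used to predict the tumors of that tissue.
#' Tumor tissues with no matching cell lines (or with a degenerate hold-out
#' split) are predicted by a fallback model whose penalty comes from plain
#' cross-validation on all cell lines. Cell lines missing a log IC50 for
#' the drug are dropped before anything else.
#'
#' @param ccl_expr Preclinical `expr_mat` (stage `"zscored"` in the standard
#'   pipeline).
#' @param ccl_response Long tibble `sample_id`, `drug_id`, `log_ic50`.
#' @param tumor_expr Clinical `expr_mat` on the same gene space.
#' @param drug Drug id to model.
#' @param grid Optional penalty grid; defaults to
#'   `make_alpha_grid(X, y)` on the eligible cell lines.
#' @param folds CV folds for the fallback penalty (default 5).
#' @param seed Seed for CV fold assignment (default 0).
#' @return A `tg_lasso_fit`: list with `drug`, `method`, `predictions`
#'   (tibble `sample_id`, `tissue`, `predicted`, `fallback`), `models`
#'   (named list of `tissue_model`), `n_train`.
#' @export
tg_lasso_fit_predict <- function(ccl_expr, ccl_response, tumor_expr, drug,
                                 grid = NULL, folds = 5, seed = 0) {
  tr <- prep_training(ccl_expr, ccl_response, drug)
  X <- tr$X; y <- tr$y; ccl_tissues <- tr$tissues
  if (is.null(grid)) grid <- make_alpha_grid(X, y)
  fallback_env <- new.env()
  get_fallback <- function() {
    if (is.null(fallback_env$model)) {
      a <- cv_select_alpha(X, y, grid, folds = folds, seed = seed)
      fallback_env$alpha <- a
      fallback_env$model <- fit_lasso(X, y, a)
    }
    fallback_env
  }
  predict_by_tissue(
    tumor_expr, drug, method = "tglasso", n_train = length(y),
    fit_for_tissue = function(t) {
      a_t <- tissue_guided_alpha(X, y, ccl_tissues, t, grid)
      if (is.na(a_t)) {
        fb <- get_fallback()
        list(model = fb$model, alpha = fb$alpha, fallback = TRUE)
      } else {
        list(model = fit_lasso(X, y, a_t), alpha = a_t, fallback = FALSE)
      }
    }
  )
}

#' Tissue-naive LASSO baseline for one drug
#'
#' A single model for all tumors: penalty by k-fold cross-validation on all
#' eligible cell lines, fit on all cell lines.
#'
#' @inheritParams tg_lasso_fit_predict
#' @return A `tg_lasso_fit` with one model labeled `"(all)"`.
#' @export
lasso_fit_predict <- function(ccl_expr, ccl_response, tumor_expr, drug,
                              grid = NULL, folds = 5, seed = 0) {
  tr <- prep_training(ccl_expr, ccl_response, drug)
  if (is.null(grid)) grid <- make_alpha_grid(tr$X, tr$y)
  a <- cv_select_alpha(tr$X, tr$y, grid, folds = folds, seed = seed)
  model <- fit_lasso(tr$X, tr$y, a)
  shared <- list(model = model, alpha = a, fallback = FALSE)
  predict_by_tissue(tumor_expr, drug, method = "lasso", n_train = length(tr$y),
                    fit_for_tissue = function(t) shared, single_model = TRUE)
}

#' Append one-hot tissue indicator columns to a feature matrix
#'
#' Each sample gains `length(vocabulary)` binary columns; its own tissue is
#' 1 and the rest 0. Samples whose tissue is outside the vocabulary get an
#' all-zero block. Appended columns are named `tissue:<label>` and are
#' penalized like any gene.
#'
#' @param X Feature matrix (samples x genes).
#' @param tissues Per-row tissue labels.
#' @param vocabulary Ordered tissue vocabulary defining the appended columns.
#' @return Matrix with `ncol(X) + length(vocabulary)` columns.
#' @export
method1_augment <- function(X, tissues, vocabulary) {
  X <- as.matrix(X)
  stopifnot(length(tissues) == nrow(X), !anyDuplicated(vocabulary))
  block <- matrix(0, nrow(X), length(vocabulary),
                  dimnames = list(rownames(X), paste0("tissue:", vocabulary)))
  hit <- match(tissues, vocabulary)
  ok <- !is.na(hit)
  block[cbind(which(ok), hit[ok])] <- 1
  cbind(X, block)
}

#' Tissue-as-binary-features LASSO baseline (method 1)
#'
#' Augments both cohorts' expression with one-hot tissue indicators drawn
#' from the cell-line tissue vocabulary, then fits a single
#' cross-validated LASSO.
#'
#' @inheritParams tg_lasso_fit_predict
#' @return A `tg_lasso_fit` with one model labeled `"(all)"`.
#' @export
method1_fit_predict <- function(ccl_expr, ccl_response, tumor_expr, drug,
                                grid = NULL, folds = 5, seed = 0) {
  tr <- prep_training(ccl_expr, ccl_response, drug)
  vocab <- sort(unique(tr$tissues))
  Xa <- method1_augment(tr$X, tr$tissues, vocab)
  if (is.null(grid)) grid <- make_alpha_grid(Xa, tr$y)
  a <- cv_select_alpha(Xa, tr$y, grid, folds = folds, seed = seed)
  model <- fit_lasso(Xa, tr$y, a)
  shared <- list(model = model, alpha = a, fallback = FALSE)
  predict_by_tissue(
    tumor_expr, drug, method = "tissue-features", n_train = length(tr$y),
    fit_for_tissue = function(t) shared, single_model = TRUE,
    test_features = function(Xtest, tissues) method1_augment(Xtest, tissues, vocab)
  )
}

#' Tissue-restricted LASSO baseline (method 2)
#'
#' For each tumor tissue, a model is trained only on the cell lines of that
#' tissue (penalty by cross-validation within the subset, folds shrunk to
#' `min(folds, n_t)`). Tissues with no matching cell lines, or fewer than 3
#' (too few for cross-validation), fall back to the all-cell-line model.
#'
#' @inheritParams tg_lasso_fit_predict
#' @param min_tissue_n Minimum cell lines required to train a
#'   tissue-restricted model (default 3).
#' @return A `tg_lasso_fit`.
#' @export
method2_fit_predict <- function(ccl_expr, ccl_response, tumor_expr, drug,
                                grid = NULL, folds = 5, seed = 0,
                                min_tissue_n = 3) {
  tr <- prep_training(ccl_expr, ccl_response, drug)
  X <- tr$X; y <- tr$y; ccl_tissues <- tr$tissues
  if (is.null(grid)) grid <- make_alpha_grid(X, y)
  fallback_env <- new.env()
  get_fallback <- function() {
    if (is.null(fallback_env$model)) {
      a <- cv_select_alpha(X, y, grid, folds = folds, seed = seed)
      fallback_env$alpha <- a
      fallback_env$model <- fit_lasso(X, y, a)
    }
    fallback_env
  }
  predict_by_tissue(
    tumor_expr, drug, method = "tissue-restricted", n_train = length(y),
    fit_for_tissue = function(t) {
      idx <- ccl_tissues == t
      n_t <- sum(idx)
      if (n_t < min_tissue_n || stats::sd(y[idx]) == 0) {
        fb <- get_fallback()
        return(list(model = fb$model, alpha = fb$alpha, fallback = TRUE))
      }
      Xt <- X[idx, , drop = FALSE]
      grid_t <- make_alpha_grid(Xt, y[idx], size = length(grid))
      a_t <- cv_select_alpha(Xt, y[idx], grid_t, folds = min(folds, n_t), seed = seed)
      list(model = fit_lasso(Xt, y[idx], a_t), alpha = a_t, fallback = FALSE)
    }
  )
}

#' Genes selected by a fitted model
#'
#' Genes with a nonzero coefficient, ordered by decreasing absolute
#' coefficient, ties broken by gene id.
#'
#' @param model A `tissue_model` or `lasso_model`.
#' @return Character vector of gene ids (possibly empty).
#' @export
extract_selected_genes <- function(model) {
  if (inherits(model, "tissue_model")) model <- model$model
  stopifnot(inherits(model, "lasso_model"))
  w <- model$coefficients
  nz <- w[w != 0]
  names(nz)[order(-abs(nz), names(nz))]
}

# ---- internal machinery -----------------------------------------------------

# align the cell-line expression and drug response for one drug
prep_training <- function(ccl_expr, ccl_response, drug) {
  stopifnot(inherits(ccl_expr, "expr_mat"))
  resp <- tibble::as_tibble(ccl_response)
  resp <- resp[resp$drug_id == drug & !is.na(resp$log_ic50), , drop = FALSE]
  if (nrow(resp) == 0) stop("no cell lines with measured response for drug ", drug,
                            call. = FALSE)
  missing_expr <- setdiff(resp$sample_id, colnames(ccl_expr$values))
  if (length(missing_expr) > 0) {
    stop("cell line(s) in response table without expression: ",
         paste(utils::head(missing_expr, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(ccl_expr$values)) {
    stop("cell-line expression must be complete (no missing values)", call. = FALSE)
  }
  ids <- resp$sample_id
  if (length(ids) < 2) stop("need at least 2 cell lines with response for drug ",
                            drug, call. = FALSE)
  X <- t(ccl_expr$values[, ids, drop = FALSE])
  meta <- ccl_expr$samples[match(ids, ccl_expr$samples$sample_id), ]
  list(X = X, y = resp$log_ic50, tissues = meta$tissue, sample_ids = ids)
}

new_tissue_model <- function(drug, tissue, alpha, model, fallback) {
  structure(
    list(drug = drug, tissue = tissue, alpha = alpha, model = model,
         selected_genes = extract_selected_genes(model), fallback = fallback),
    class = "tissue_model"
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> drug %s / tissue %s: alpha = %.4g, %d genes%s\n",
              x$drug, x$tissue, x$alpha, length(x$selected_genes),
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

# shared prediction loop over the tumor tissues; fit_for_tissue returns
# list(model, alpha, fallback) for each tissue
predict_by_tissue <- function(tumor_expr, drug, method, n_train, fit_for_tissue,
                              single_model = FALSE, test_features = NULL) {
  stopifnot(inherits(tumor_expr, "expr_mat"))
  tumor_tissues <- tumor_expr$samples$tissue
  Xtest <- t(tumor_expr$values)
  if (!is.null(test_features)) Xtest <- test_features(Xtest, tumor_tissues)
  models <- list()
  pred_rows <- vector("list", 0)
  for (t in sort(unique(tumor_tissues))) {
    ft <- fit_for_tissue(t)
    key <- if (single_model) "(all)" else t
    if (is.null(models[[key]])) {
      models[[key]] <- new_tissue_model(drug, key, ft$alpha, ft$model, ft$fallback)
    }
    idx <- tumor_tissues == t
    pred_rows[[t]] <- tibble::tibble(
      sample_id = tumor_expr$samples$sample_id[idx],
      tissue = t,
      predicted = unname(predict(ft$model, Xtest[idx, , drop = FALSE])),
      fallback = ft$fallback
    )
  }
  predictions <- dplyr::bind_rows(pred_rows)
  predictions <- predictions[match(tumor_expr$samples$sample_id,
                                   predictions$sample_id), ]
  structure(
    list(drug = drug, method = method, predictions = predictions,
         models = models, n_train = n_train),
    class = "tg_lasso_fit"
  )
}

#' @export
print.tg_lasso_fit <- function(x, ...) {
  cat(sprintf("<tg_lasso_fit> drug %s, method %s: %d tumors, %d model(s), n_train = %d\n",
              x$drug, x$method, nrow(x$predictions), length(x$models), x$n_train))
  invisible(x)
}

#' Tidy the nonzero coefficients of a fitted drug model
#'
#' @param x A `tg_lasso_fit` (or `lasso_model`).
#' @param ... Unused.
#' @return For `tg_lasso_fit`: tibble `drug_id`, `tissue`, `alpha`,
#'   `fallback`, `gene_id`, `coefficient` (nonzero entries only, ordered by
#'   decreasing absolute coefficient within tissue). For `lasso_model`:
#'   `gene_id`, `coefficient`.
#' @export
tidy.tg_lasso_fit <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    td <- tidy(m$model)
    if (nrow(td) == 0) {
      td <- tibble::tibble(gene_id = character(), coefficient = numeric())
    }
    tibble::tibble(drug_id = m$drug, tissue = m$tissue, alpha = m$alpha,
                   fallback = m$fallback, gene_id = td$gene_id,
                   coefficient = td$coefficient)
  })
}

#' One-row summary of a fitted drug model
#'
#' @param x A `tg_lasso_fit`.
#' @param ... Unused.
#' @return Tibble with drug, method, training size, tissue counts and the
#'   median number of selected genes across tissues.
#' @export
glance.tg_lasso_fit <- function(x, ...) {
  n_sel <- vapply(x$models, function(m) length(m$selected_genes), integer(1))
  tibble::tibble(
    drug_id = x$drug, method = x$method, n_train = x$n_train,
    n_tumors = nrow(x$predictions), n_tissue_models = length(x$models),
    n_fallback = sum(vapply(x$models, function(m) m$fallback, logical(1))),
    median_genes_selected = stats::median(n_sel)
  )
}

#' Serialize fitted models to a delimited text file
#'
#' Writes one row per nonzero coefficient (`drug_id`, `tissue`, `alpha`,
#' `fallback`, `gene_id`, `coefficient`); intercepts are written as rows
#' with `gene_id = "(Intercept)"`.
#'
#' @param fit A `tg_lasso_fit` or list of them.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_models <- function(fit, path) {
  fits <- if (inherits(fit, "tg_lasso_fit")) list(fit) else fit
  rows <- purrr::map_dfr(fits, function(f) {
    coefs <- tidy(f)
    intercepts <- purrr::map_dfr(f$models, function(m) {
      tibble::tibble(drug_id = m$drug, tissue = m$tissue, alpha = m$alpha,
                     fallback = m$fallback, gene_id = "(Intercept)",
                     coefficient = m$model$intercept)
    })
    dplyr::bind_rows(intercepts, coefs)
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
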