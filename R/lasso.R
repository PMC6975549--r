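#' Fit a LASSO model at a fixed penalty
#'
#' Minimizes `(1/2n) * ||y - Xw - b||_2^2 + alpha * ||w||_1` with an
#' unpenalized intercept `b`. Features are expected to be z-scored upstream;
#' no re-standardization is performed. The fit is delegated to
#' \pkg{glmnet} along a short warm-start path ending at `alpha`, which
#' solves this exact objective for the Gaussian family.
#'
#' @param X Numeric feature matrix, samples in rows, genes in columns
#'   (colnames used as gene ids).
#' @param y Numeric response vector (log IC50), length `nrow(X)`.
#' @param alpha Non-negative L1 penalty weight.
#' @return A `lasso_model`: list with `coefficients` (named vector over the
#'   columns of `X`), `intercept`, `alpha`, `n_train`.
#' @export
fit_lasso <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  null_model <- function() {
    new_lasso_model(stats::setNames(numeric(ncol(X)), colnames(X)),
                    mean(y), alpha, nrow(X))
  }
  if (stats::sd(y) == 0) return(null_model())
  amax <- alpha_max(X, y)
  if (alpha >= amax) return(null_model())

  # short geometric path from alpha_max down to the requested penalty gives
  # glmnet warm starts; lambda = 0 is appended only when explicitly requested
  if (alpha > 0) {
    path <- exp(seq(log(amax), log(alpha), length.out = 20L))
    path[length(path)] <- alpha
  } else {
    path <- c(exp(seq(log(amax), log(amax * 1e-4), length.out = 20L)), 0)
  }
  Xg <- X
  pad <- ncol(Xg) < 2
  if (pad) Xg <- cbind(Xg, .pad. = 0)
  fit <- glmnet::glmnet(Xg, y, family = "gaussian", lambda = path,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e7)
  beta <- as.numeric(fit$beta[, length(path)])
  b0 <- fit$a0[[length(path)]]
  if (pad) beta <- beta[1]
  new_lasso_model(stats::setNames(beta, colnames(X)), b0, alpha, nrow(X))
}

new_lasso_model <- function(coefficients, intercept, alpha, n_train) {
  structure(
    list(coefficients = coefficients, intercept = unname(intercept),
         alpha = alpha, n_train = n_train),
    class = "lasso_model"
  )
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("<lasso_model> alpha = %.4g, %d/%d nonzero coefficients, n = %d\n",
              x$alpha, sum(x$coefficients != 0), length(x$coefficients), x$n_train))
  invisible(x)
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_mat")) newdata <- t(newdata$values)
  newdata <- as.matrix(newdata)
  feats <- names(object$coefficients)
  missing_f <- setdiff(feats, colnames(newdata))
  if (length(missing_f) > 0) {
    stop("newdata lacks feature(s): ", paste(utils::head(missing_f, 5), collapse = ", "),
         call. = FALSE)
  }
  drop(newdata[, feats, drop = FALSE] %*% object$coefficients) + object$intercept
}

#' @rdname tidy.tg_lasso_fit
#' @export
tidy.lasso_model <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  ord <- order(-abs(nz), names(nz))
  tibble::tibble(gene_id = names(nz)[ord], coefficient = unname(nz)[ord])
}

#' LASSO objective value
#'
#' `(1/2n)||y - Xw - b||^2 + alpha ||w||_1`; exposed for solver diagnostics.
#'
#' @param model A `lasso_model`.
#' @param X,y Training data the model was fitted on.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(model, X, y) {
  r <- y - predict(model, X)
  sum(r^2) / (2 * length(y)) + model$alpha * sum(abs(model$coefficients))
}

# smallest penalty at which the LASSO solution (with intercept) is w = 0
alpha_max <- function(X, y) {
  n <- length(y)
  max(abs(crossprod(X, y - mean(y)))) / n
}

#' Log-spaced penalty grid anchored at the null-model boundary
#'
#' The grid starts at the data-derived `alpha_max` (the smallest penalty at
#' which all coefficients are zero) and decreases geometrically to
#' `eps * alpha_max`.
#'
#' @param X,y Training data (see [fit_lasso()]).
#' @param size Number of grid points (default 100).
#' @param eps Ratio of smallest to largest penalty (default 1e-3).
#' @return Strictly decreasing numeric vector of penalties.
#' @export
make_alpha_grid <- function(X, y, size = 100, eps = 1e-3) {
  X <- as.matrix(X)
  stopifnot(size >= 1, eps > 0, eps <= 1)
  if (stats::sd(y) == 0) stop("constant response: no usable penalty grid", call. = FALSE)
  amax <- alpha_max(X, y)
  if (amax == 0) stop("all features orthogonal to response", call. = FALSE)
  if (size == 1) return(amax)
  exp(seq(log(amax), log(eps * amax), length.out = size))
}

#' Select the penalty by k-fold cross-validation
#'
#' Folds are assigned by a seeded random permutation; the mean held-out
#' squared error is computed per grid point and the minimizer returned.
#' On ties the larger (sparser) penalty wins.
#'
#' @param X,y Training data.
#' @param grid Decreasing penalty grid from [make_alpha_grid()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment (default 0).
#' @return The selected penalty (a member of `grid`).
#' @export
cv_select_alpha <- function(X, y, grid, folds = 5, seed = 0) {
  X <- as.matrix(X)
  n <- length(y)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  fold_id <- local({
    set.seed(seed)
    sample(rep(seq_len(folds), length.out = n))
  })
  sq_err <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    preds <- path_predict(X[!hold, , drop = FALSE], y[!hold], grid,
                          X[hold, , drop = FALSE])
    sq_err[hold, ] <- (preds - y[hold])^2
  }
  mse <- colMeans(sq_err)
  grid[which.min(mse)] # grid decreasing: first minimum = largest alpha
}

# fit a full glmnet path at the given penalties and predict new samples;
# returns a matrix n_new x length(grid)
path_predict <- function(X_train, y_train, grid, X_new) {
  if (stats::sd(y_train) == 0) {
    return(matrix(mean(y_train), nrow(X_new), length(grid)))
  }
  pad <- ncol(X_train) < 2
  Xt <- if (pad) cbind(X_train, .pad. = 0) else X_train
  Xn <- if (pad) cbind(X_new, .pad. = 0) else X_new
  fit <- glmnet::glmnet(Xt, y_train, family = "gaussian",
                        lambda = sort(grid, decreasing = TRUE),
                        standardize = FALSE, thresh = 1e-9, maxit = 1e6)
  preds <- stats::predict(fit, newx = Xn, s = grid)
  matrix(preds, nrow = nrow(X_new), ncol = length(grid))
}
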