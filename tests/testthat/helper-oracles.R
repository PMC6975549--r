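# Independent reference implementations used to check the package's
# statistics and solver. These deliberately share no code with the package.

# Exhaustive Mann-Whitney: p = Pr(U >= u_obs) over all label assignments of
# the pooled values (distinct values assumed).
mwu_enum_oracle <- function(resistant, sensitive) {
  vals <- c(resistant, sensitive)
  n1 <- length(resistant)
  u_obs <- sum(outer(resistant, sensitive, ">"))
  idx <- utils::combn(length(vals), n1)
  us <- apply(idx, 2, function(i) {
    sum(outer(vals[i], vals[-i], ">"))
  })
  mean(us >= u_obs)
}

# Proximal-gradient (ISTA) reference for the LASSO objective
# (1/2n)||y - Xw - b||^2 + alpha ||w||_1 with unpenalized intercept.
lasso_prox_reference <- function(X, y, alpha, iters = 50000, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- numeric(ncol(X))
  b <- mean(y)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / max(L, 1e-12)
  obj <- function(w, b) sum((y - X %*% w - b)^2) / (2 * n) + alpha * sum(abs(w))
  last <- obj(w, b)
  for (k in seq_len(iters)) {
    r <- y - X %*% w - b
    w <- w - step * (-crossprod(X, r) / n)
    w <- sign(w) * pmax(abs(w) - step * alpha, 0)
    b <- mean(y - X %*% w)
    if (k %% 200 == 0) {
      cur <- obj(w, b)
      if (last - cur < tol) break
      last <- cur
    }
  }
  list(w = as.numeric(w), intercept = b, objective = obj(w, b))
}

# Brute-force odds-ratio threshold scan (Haldane-corrected ranking only when
# a zero cell is present), kept structurally independent of the package.
threshold_scan_oracle <- function(preds, labels) {
  u <- sort(unique(preds))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (thr in cand) {
    a <- sum(preds > thr & labels == "resistant")
    b <- sum(preds <= thr & labels == "resistant")
    cc <- sum(preds > thr & labels == "sensitive")
    d <- sum(preds <= thr & labels == "sensitive")
    score <- if (min(a, b, cc, d) == 0) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5))
    } else {
      a * d / (b * cc)
    }
    if (is.null(best) || score > best$score) {
      best <- list(score = score, threshold = thr,
                   table = matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))
    }
  }
  best
}

# closed-form Fisher combinations for k = 1 and k = 2
fisher_df2_oracle <- function(p) exp(-(-2 * log(p)) / 2)
fisher_df4_oracle <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}
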