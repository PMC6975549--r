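#' One-sided Mann-Whitney test for resistant/sensitive separation
#'
#' Tests whether predicted log IC50 values of resistant patients are
#' stochastically larger than those of sensitive patients (H1: resistant >
#' sensitive). The exact null distribution is used when both groups have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections is used.
#'
#' @param resistant_preds Predicted values for the resistant group.
#' @param sensitive_preds Predicted values for the sensitive group.
#' @param exact_max Largest group size for the exact path (default 8).
#' @return One-sided p-value in (0, 1].
#' @export
mwu_one_sided <- function(resistant_preds, sensitive_preds, exact_max = 8) {
  if (length(resistant_preds) == 0 || length(sensitive_preds) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(resistant_preds, sensitive_preds)) > 0
  use_exact <- !ties && length(resistant_preds) <= exact_max &&
    length(sensitive_preds) <= exact_max
  suppressWarnings(
    stats::wilcox.test(resistant_preds, sensitive_preds,
                       alternative = "greater", exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Combine independent p-values by Fisher's method
#'
#' `-2 * sum(log(p))` is referred to a chi-square distribution with
#' `2 * length(pvals)` degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Precision at the k-th percentile tails
#'
#' The k-th and (100-k)-th percentiles of the *training* (cell-line) log
#' IC50 values define a sensitive and a resistant calling threshold.
#' Precision@k% is the fraction of correct calls among tumors whose
#' predicted log IC50 falls strictly outside those thresholds:
#' `(R_hi + S_lo) / (N_hi + N_lo)`, where `R_hi` counts resistant tumors
#' predicted above the upper threshold, `S_lo` sensitive tumors predicted
#' below the lower one, and `N_hi`/`N_lo` all tumors beyond each threshold.
#' When no tumor falls outside either threshold the measure is undefined.
#' Percentiles use linear interpolation between closest ranks.
#'
#' @param train_ic50 Training (cell-line) log IC50 values for the drug.
#' @param preds Predicted tumor log IC50 values.
#' @param labels True binary labels (`"resistant"`/`"sensitive"`) aligned
#'   with `preds`.
#' @param k Percentage, at most 50.
#' @return One-row tibble: `k`, `t_low`, `t_high`, `r_high`, `s_low`,
#'   `n_high`, `n_low`, `defined`, `value` (`NA` when undefined).
#' @export
precision_at_k <- function(train_ic50, preds, labels, k = 20) {
  if (k > 50) stop("k must be at most 50", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (length(train_ic50) == 0) stop("empty training IC50 vector", call. = FALSE)
  stopifnot(length(preds) == length(labels))
  qs <- stats::quantile(train_ic50, c(k, 100 - k) / 100, names = FALSE, type = 7)
  t_low <- qs[1]; t_high <- qs[2]
  hi <- preds > t_high
  lo <- preds < t_low
  r_high <- sum(hi & labels == "resistant")
  s_low <- sum(lo & labels == "sensitive")
  n_high <- sum(hi); n_low <- sum(lo)
  defined <- (n_high + n_low) > 0
  tibble::tibble(
    k = k, t_low = t_low, t_high = t_high,
    r_high = r_high, s_low = s_low, n_high = n_high, n_low = n_low,
    defined = defined,
    value = if (defined) (r_high + s_low) / (n_high + n_low) else NA_real_
  )
}

#' Summary statistics of a 2x2 prediction contingency table
#'
#' Rows are the true classes (resistant, sensitive), columns the predicted
#' classes (resistant, sensitive). Returns the uncorrected cross-product
#' odds ratio (infinite when a zero cell makes it so), the resistant-class
#' recall, precision and specificity, and one- and two-sided Fisher exact
#' p-values.
#'
#' @param tab 2x2 numeric matrix: `tab[1,1]` true-resistant predicted-
#'   resistant, `tab[1,2]` true-resistant predicted-sensitive, `tab[2,1]`
#'   true-sensitive predicted-resistant, `tab[2,2]` true-sensitive
#'   predicted-sensitive.
#' @return One-row tibble: `odds_ratio`, `recall`, `precision`,
#'   `specificity`, `p_one_sided`, `p_two_sided`.
#' @export
contingency_stats <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  tibble::tibble(
    odds_ratio = or,
    recall = a / (a + b),
    precision = a / (a + c),
    specificity = d / (c + d),
    p_one_sided = stats::fisher.test(tab, alternative = "greater")$p.value,
    p_two_sided = stats::fisher.test(tab)$p.value
  )
}

#' Find the classification threshold maximizing the odds ratio
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' predictions; a tumor is called resistant when its prediction is strictly
#' greater than the threshold. Tables are ranked by odds ratio, with the
#' Haldane correction (+0.5 on every cell) applied only when a table
#' contains a zero cell; the winning table is reported with its
#' *uncorrected* odds ratio (possibly infinite) and Fisher exact p-values.
#' On ties the smallest threshold wins.
#'
#' @param preds Predicted log IC50 values.
#' @param labels True binary labels aligned with `preds`; both classes must
#'   be present.
#' @return A `contingency_scan`: list with `table` (2x2 matrix), `threshold`,
#'   `stats` (from [contingency_stats()]), `n_thresholds`.
#' @export
threshold_scan_contingency <- function(preds, labels) {
  stopifnot(length(preds) == length(labels))
  if (!all(c("resistant", "sensitive") %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  u <- sort(unique(preds))
  if (length(u) < 2) stop("predictions are constant; no threshold exists", call. = FALSE)
  thresholds <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  best_score <- -Inf
  for (thr in thresholds) {
    pred_r <- preds > thr
    tab <- matrix(c(
      sum(pred_r & labels == "resistant"), sum(!pred_r & labels == "resistant"),
      sum(pred_r & labels == "sensitive"), sum(!pred_r & labels == "sensitive")
    ), 2, 2, byrow = TRUE,
    dimnames = list(c("true_resistant", "true_sensitive"),
                    c("pred_resistant", "pred_sensitive")))
    score <- if (any(tab == 0)) {
      ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) / ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    } else {
      (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    }
    if (score > best_score) {
      best_score <- score
      best <- list(table = tab, threshold = thr)
    }
  }
  structure(
    list(table = best$table, threshold = best$threshold,
         stats = contingency_stats(best$table),
         n_thresholds = length(thresholds)),
    class = "contingency_scan"
  )
}

#' @export
print.contingency_scan <- function(x, ...) {
  cat(sprintf("<contingency_scan> threshold = %.4g, odds ratio = %.3g, one-sided Fisher p = %.3g\n",
              x$threshold, x$stats$odds_ratio, x$stats$p_one_sided))
  print(x$table)
  invisible(x)
}

#' Evaluate predictions for a panel of drugs
#'
#' Joins per-patient predictions with binary response labels, keeps drugs
#' passing the eligibility filter, and computes per drug: the one-sided
#' Mann-Whitney separation p-value, class counts, Precision@k% for each
#' requested `k` (when training IC50 values are supplied), and the
#' odds-ratio-maximizing contingency summary. The per-drug p-values of the
#' whole panel (significant or not) are combined by Fisher's method.
#'
#' @param predictions Tibble with columns `sample_id` (patient), `drug_id`,
#'   `predicted`.
#' @param response Binary response tibble (`patient_id`, `drug_id`,
#'   `label`), e.g. from [map_cdr_labels()].
#' @param k Percentages for Precision@k% (default `c(10, 20, 30, 40, 50)`).
#' @param train_ic50 Optional tibble `drug_id`, `log_ic50` with the
#'   training cell-line values used for the Precision@k% thresholds.
#' @param patients Optional patient subset: either a character vector of
#'   patient ids, or a tibble `patient_id`, `drug_id` restricting each
#'   drug's evaluation (used for the drug-combination subanalysis).
#' @param min_per_class,min_total Eligibility thresholds passed to
#'   [filter_eligible_drugs()].
#' @return A `drug_panel_eval`: list with `drugs` (per-drug tibble),
#'   `precision` (per drug x k tibble), `combined_p`, `n_significant`,
#'   `data` (the joined evaluation records).
#' @export
evaluate_drug_panel <- function(predictions, response, k = c(10, 20, 30, 40, 50),
                                train_ic50 = NULL, patients = NULL,
                                min_per_class = 2, min_total = 8) {
  predictions <- tibble::as_tibble(predictions)
  response <- tibble::as_tibble(response)
  stopifnot(all(c("sample_id", "drug_id", "predicted") %in% names(predictions)),
            all(c("patient_id", "drug_id", "label") %in% names(response)))
  dat <- dplyr::inner_join(
    dplyr::rename(predictions, patient_id = "sample_id"),
    response, by = c("patient_id", "drug_id")
  )
  if (!is.null(patients)) {
    if (is.data.frame(patients)) {
      dat <- dplyr::semi_join(dat, patients, by = c("patient_id", "drug_id"))
    } else {
      dat <- dat[dat$patient_id %in% patients, , drop = FALSE]
    }
  }
  eligible <- filter_eligible_drugs(dat, min_per_class = min_per_class,
                                    min_total = min_total)
  dat <- dat[dat$drug_id %in% eligible, , drop = FALSE]
  if (nrow(dat) == 0) stop("no eligible drugs in the panel", call. = FALSE)

  per_drug <- lapply(eligible, function(d) {
    dd <- dat[dat$drug_id == d, ]
    res <- dd$predicted[dd$label == "resistant"]
    sen <- dd$predicted[dd$label == "sensitive"]
    p <- mwu_one_sided(res, sen)
    scan <- tryCatch(threshold_scan_contingency(dd$predicted, dd$label),
                     error = function(e) NULL)
    tibble::tibble(
      drug_id = d, p_value = p,
      n_resistant = length(res), n_sensitive = length(sen),
      best_odds_ratio = if (is.null(scan)) NA_real_ else scan$stats$odds_ratio,
      best_threshold = if (is.null(scan)) NA_real_ else scan$threshold,
      or_p_one_sided = if (is.null(scan)) NA_real_ else scan$stats$p_one_sided
    )
  })
  drugs <- dplyr::bind_rows(per_drug)

  precision <- NULL
  if (!is.null(train_ic50)) {
    train_ic50 <- tibble::as_tibble(train_ic50)
    stopifnot(all(c("drug_id", "log_ic50") %in% names(train_ic50)))
    precision <- purrr::map_dfr(eligible, function(d) {
      dd <- dat[dat$drug_id == d, ]
      tr <- train_ic50$log_ic50[train_ic50$drug_id == d & !is.na(train_ic50$log_ic50)]
      if (length(tr) == 0) return(NULL)
      purrr::map_dfr(k, function(kk) {
        dplyr::bind_cols(tibble::tibble(drug_id = d),
                         precision_at_k(tr, dd$predicted, dd$label, kk))
      })
    })
  }

  structure(
    list(drugs = drugs,
         precision = precision,
         combined_p = fisher_combine(drugs$p_value),
         n_significant = sum(drugs$p_value < 0.05),
         data = dat),
    class = "drug_panel_eval"
  )
}

#' @export
print.drug_panel_eval <- function(x, ...) {
  cat(sprintf("<drug_panel_eval> %d drugs, %d with p < 0.05, combined p = %.3g\n",
              nrow(x$drugs), x$n_significant, x$combined_p))
  print(x$drugs)
  invisible(x)
}

#' @rdname evaluate_drug_panel
#' @param x A `drug_panel_eval`.
#' @param ... Unused.
#' @export
tidy.drug_panel_eval <- function(x, ...) x$drugs

#' @rdname evaluate_drug_panel
#' @export
glance.drug_panel_eval <- function(x, ...) {
  tibble::tibble(n_drugs = nrow(x$drugs), n_significant = x$n_significant,
                 combined_p = x$combined_p)
}

#' Box plots of predicted log IC50 by response class
#'
#' One facet per drug, with the per-drug one-sided Mann-Whitney p-value in
#' the strip label.
#'
#' @param object A `drug_panel_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drug_panel_eval <- function(object, ...) {
  lab <- stats::setNames(
    sprintf("%s (p = %.2g)", object$drugs$drug_id, object$drugs$p_value),
    object$drugs$drug_id
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$label, y = .data$predicted,
                               fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~drug_id, scales = "free_y",
                        labeller = ggplot2::labeller(drug_id = lab)) +
    ggplot2::labs(x = NULL, y = "predicted log(IC50)") +
    ggplot2::theme_bw()
}

#' Precision@k% curves per drug
#'
#' @param eval A `drug_panel_eval` computed with `train_ic50` supplied.
#' @return A ggplot object (value vs k, one line per drug; undefined points
#'   are dropped).
#' @export
plot_precision_curves <- function(eval) {
  stopifnot(inherits(eval, "drug_panel_eval"))
  if (is.null(eval$precision)) {
    stop("evaluation was run without training IC50 values", call. = FALSE)
  }
  dd <- eval$precision[eval$precision$defined, ]
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$drug_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "k (%)", y = "Precision@k%", colour = "drug") +
    ggplot2::theme_bw()
}
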