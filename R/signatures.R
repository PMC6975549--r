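#' Count how often each gene is selected across tissues and drugs
#'
#' Takes the tissue models produced by TG-LASSO fits over a drug x tissue
#' grid (gaps allowed) and tabulates, for every gene, the number of tissues
#' selecting it per drug and the number of drugs selecting it per tissue.
#' Duplicate (drug, tissue) models are an error.
#'
#' @param models A list of `tissue_model` objects, or a list of
#'   `tg_lasso_fit` objects (flattened automatically).
#' @return A `selection_counts`: list with `selections` (tibble `drug_id`,
#'   `tissue`, `gene_id`), `by_drug` (tibble `drug_id`, `gene_id`,
#'   `n_tissues`), `by_tissue` (tibble `tissue`, `gene_id`, `n_drugs`).
#' @export
aggregate_gene_selections <- function(models) {
  if (inherits(models, "tg_lasso_fit")) models <- list(models)
  flat <- list()
  for (m in models) {
    if (inherits(m, "tg_lasso_fit")) flat <- c(flat, unname(m$models))
    else if (inherits(m, "tissue_model")) flat <- c(flat, list(m))
    else stop("models must be tissue_model or tg_lasso_fit objects", call. = FALSE)
  }
  keys <- vapply(flat, function(m) paste(m$drug, m$tissue, sep = "\r"), character(1))
  if (anyDuplicated(keys)) {
    dup <- strsplit(keys[duplicated(keys)][1], "\r")[[1]]
    stop("duplicate model for drug ", dup[1], " / tissue ", dup[2], call. = FALSE)
  }
  selections <- purrr::map_dfr(flat, function(m) {
    if (length(m$selected_genes) == 0) return(NULL)
    tibble::tibble(drug_id = m$drug, tissue = m$tissue, gene_id = m$selected_genes)
  })
  if (nrow(selections) == 0) {
    selections <- tibble::tibble(drug_id = character(), tissue = character(),
                                 gene_id = character())
  }
  by_drug <- selections |>
    dplyr::distinct(.data$drug_id, .data$tissue, .data$gene_id) |>
    dplyr::count(.data$drug_id, .data$gene_id, name = "n_tissues")
  by_tissue <- selections |>
    dplyr::distinct(.data$tissue, .data$drug_id, .data$gene_id) |>
    dplyr::count(.data$tissue, .data$gene_id, name = "n_drugs")
  structure(
    list(selections = selections, by_drug = by_drug, by_tissue = by_tissue),
    class = "selection_counts"
  )
}

#' @export
print.selection_counts <- function(x, ...) {
  cat(sprintf("<selection_counts> %d selections over %d drug(s) x %d tissue(s)\n",
              nrow(x$selections), length(unique(x$selections$drug_id)),
              length(unique(x$selections$tissue))))
  invisible(x)
}

#' Recurrently selected genes of one tissue
#'
#' Genes selected for strictly more than `min_drugs` different drugs in the
#' given tissue — the per-tissue signature used for survival stratification.
#'
#' @param counts A `selection_counts` from [aggregate_gene_selections()].
#' @param tissue Tissue label.
#' @param min_drugs Strict lower bound on the number of drugs (default 5:
#'   a gene must be selected for 6 or more drugs).
#' @return Character vector of gene ids ordered by decreasing drug count,
#'   ties by gene id (possibly empty).
#' @export
tissue_signature <- function(counts, tissue, min_drugs = 5) {
  stopifnot(inherits(counts, "selection_counts"))
  bt <- counts$by_tissue
  hits <- bt[bt$tissue == tissue & bt$n_drugs > min_drugs, , drop = FALSE]
  hits <- hits[order(-hits$n_drugs, hits$gene_id), ]
  hits$gene_id
}

#' Cluster patients on signature-gene expression
#'
#' Agglomerative hierarchical clustering with cosine distance and average
#' linkage, cut into two clusters. Expression is taken as given (z-scored
#' upstream in the standard pipeline) restricted to the signature genes.
#'
#' @param expr An `expr_mat` restricted to the signature genes (at least 2
#'   genes, at least 2 patients), or a gene x patient matrix.
#' @return Named integer vector of cluster labels (1 or 2) per patient.
#' @export
cluster_by_signature <- function(expr) {
  m <- if (inherits(expr, "expr_mat")) expr$values else as.matrix(expr)
  if (nrow(m) < 2) stop("need at least 2 signature genes", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 patients", call. = FALSE)
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    stop("zero-norm expression vector for patient(s): ",
         paste(utils::head(colnames(m)[norms == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  xn <- sweep(m, 2, norms, "/")
  cos_sim <- crossprod(xn)
  d <- stats::as.dist(1 - cos_sim)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = 2)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom comparing the
#' survival curves of two patient clusters.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param cluster Two-level group labels.
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`,
#'   `n`, `n_events`.
#' @export
logrank_test <- function(time, event, cluster) {
  stopifnot(length(time) == length(event), length(time) == length(cluster))
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (length(unique(cluster)) != 2) {
    stop("exactly two non-empty clusters are required", call. = FALSE)
  }
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ cluster)
  tibble::tibble(
    statistic = sd_fit$chisq, df = 1L,
    p_value = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
    n = length(time), n_events = sum(event)
  )
}

#' Signature-driven survival stratification for one tissue
#'
#' Extracts the tissue's recurrent-gene signature, clusters its patients on
#' signature expression, and tests the two clusters for a survival
#' difference with the log-rank test.
#'
#' @param counts A `selection_counts`.
#' @param expr Clinical `expr_mat` (z-scored in the standard pipeline).
#' @param survival_df Tibble `patient_id`, `time`, `event`.
#' @param tissue Tissue label to analyze; patients are taken from the
#'   expression metadata for that tissue.
#' @param min_drugs Signature threshold, see [tissue_signature()].
#' @return A `signature_survival`: list with `tissue`, `genes`, `clusters`
#'   (named vector), `test` (tibble from [logrank_test()]), `data`
#'   (per-patient tibble with time, event and cluster).
#' @export
signature_survival <- function(counts, expr, survival_df, tissue, min_drugs = 5) {
  stopifnot(inherits(expr, "expr_mat"))
  survival_df <- tibble::as_tibble(survival_df)
  stopifnot(all(c("patient_id", "time", "event") %in% names(survival_df)))
  genes_sig <- tissue_signature(counts, tissue, min_drugs = min_drugs)
  if (length(genes_sig) < 2) {
    stop("signature for tissue ", tissue, " has fewer than 2 genes", call. = FALSE)
  }
  patients <- expr$samples$sample_id[expr$samples$tissue == tissue]
  patients <- intersect(patients, survival_df$patient_id)
  if (length(patients) < 2) {
    stop("fewer than 2 patients with survival data in tissue ", tissue, call. = FALSE)
  }
  sub <- expr_subset(expr, genes = intersect(genes_sig, genes(expr)),
                     samples = patients)
  cl <- cluster_by_signature(sub)
  sv <- survival_df[match(patients, survival_df$patient_id), ]
  test <- logrank_test(sv$time, sv$event, cl)
  structure(
    list(tissue = tissue, genes = genes_sig, clusters = cl, test = test,
         data = tibble::tibble(patient_id = patients, time = sv$time,
                               event = sv$event, cluster = factor(cl))),
    class = "signature_survival"
  )
}

#' @export
print.signature_survival <- function(x, ...) {
  cat(sprintf("<signature_survival> tissue %s: %d genes, chi-square = %.3g, p = %.3g\n",
              x$tissue, length(x$genes), x$test$statistic, x$test$p_value))
  invisible(x)
}

#' Kaplan-Meier curves for a signature-survival stratification
#'
#' @param object A `signature_survival`.
#' @param ... Unused.
#' @return A ggplot object with one step curve per cluster and the log-rank
#'   p-value in the subtitle.
#' @export
autoplot.signature_survival <- function(object, ...) {
  fit <- survival::survfit(survival::Surv(time, event) ~ cluster, data = object$data)
  strata <- rep(names(fit$strata), fit$strata)
  km <- tibble::tibble(
    time = fit$time, surv = fit$surv, cluster = sub("^cluster=", "", strata)
  )
  km0 <- tibble::tibble(time = 0, surv = 1,
                        cluster = unique(km$cluster))
  ggplot2::ggplot(dplyr::bind_rows(km0, km),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "time (days)", y = "survival probability", colour = "cluster",
      subtitle = sprintf("log-rank p = %.3g (tissue %s, %d signature genes)",
                         object$test$p_value, object$tissue, length(object$genes))
    ) +
    ggplot2::theme_bw()
}
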