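#' Run the full preclinical-to-clinical prediction workflow
#'
#' Executes the pipeline end to end on in-memory inputs: tumor FPKM
#' preprocessing, gene-space harmonization, batch correction, pooled
#' z-scoring, per-drug model fitting and tumor prediction with the chosen
#' tissue strategy, and panel evaluation. When a survival table is supplied
#' and the method produces per-tissue models, the signature/survival
#' analysis is run for every tissue with an adequate signature.
#'
#' The clinical response table is read only by the evaluation stage; model
#' fitting never sees it.
#'
#' @param ccl Preclinical `expr_mat` on a continuous log-like scale
#'   (stage `"log"`).
#' @param ccl_response Tibble `sample_id`, `drug_id`, `log_ic50`.
#' @param tumor Clinical `expr_mat` at stage `"raw"` (FPKM) or `"log"`.
#' @param cdr Tibble `patient_id`, `drug_id`, `category`.
#' @param survival_df Optional tibble `patient_id`, `time`, `event`.
#' @param method Tissue strategy: `"tglasso"` (default), `"lasso"`,
#'   `"tissue-features"`, `"tissue-restricted"`.
#' @param harmonization `"combat"` (default) or `"none"`.
#' @param k Percentages for Precision@k%.
#' @param min_per_class,min_total Drug eligibility thresholds.
#' @param sd_min Pooled standard-deviation filter for shared genes.
#' @param min_drugs Signature threshold for the survival analysis.
#' @param grid_size,grid_eps Penalty-grid shape (see [make_alpha_grid()]).
#' @param folds Cross-validation folds for fallback/baseline penalties.
#' @param seed Root seed for all stochastic steps (CV fold assignment).
#' @param patients Optional patient subset for the evaluation stage (see
#'   [evaluate_drug_panel()]).
#' @param out_dir Optional directory; when given, report tables are written
#'   there as delimited text.
#' @return A `tg_run`: list with `method`, `harmonization`, `seed`,
#'   `eligible_drugs`, `fits` (named list of `tg_lasso_fit`),
#'   `predictions` (long tibble), `evaluation` (`drug_panel_eval`),
#'   `signatures` (list of `signature_survival`, possibly empty),
#'   `expression` (list with the z-scored cohorts).
#' @export
run_experiment <- function(ccl, ccl_response, tumor, cdr, survival_df = NULL,
                           method = c("tglasso", "lasso", "tissue-features",
                                      "tissue-restricted"),
                           harmonization = c("combat", "none"),
                           k = c(10, 20, 30, 40, 50),
                           min_per_class = 2, min_total = 8,
                           sd_min = 0.1, min_drugs = 5,
                           grid_size = 100, grid_eps = 1e-3,
                           folds = 5, seed = 0,
                           patients = NULL, out_dir = NULL) {
  method <- match.arg(method)
  harmonization <- match.arg(harmonization)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  tumor_log <- with_stage("preprocess", {
    if (tumor$stage == "raw") preprocess_tumor_fpkm(tumor) else tumor
  })
  shared <- with_stage("harmonize_genes",
                       harmonize_gene_space(ccl, tumor_log, sd_min = sd_min))
  pooled <- with_stage("batch_correct", {
    combat_correct(bind_expr(shared$a, shared$b), method = harmonization)
  })
  zpooled <- with_stage("zscore", zscore_normalize(pooled))
  cohorts <- split_by_cohort(zpooled)
  ccl_z <- cohorts$preclinical
  tumor_z <- cohorts$clinical

  labels <- with_stage("map_labels", map_cdr_labels(cdr))
  eligible <- filter_eligible_drugs(labels, min_per_class = min_per_class,
                                    min_total = min_total)
  measured <- unique(ccl_response$drug_id[!is.na(ccl_response$log_ic50)])
  eligible <- intersect(eligible, measured)
  if (length(eligible) == 0) stop("stage 'train' failed: no eligible drugs",
                                  call. = FALSE)

  fit_fun <- switch(method,
    tglasso = tg_lasso_fit_predict,
    lasso = lasso_fit_predict,
    "tissue-features" = method1_fit_predict,
    "tissue-restricted" = method2_fit_predict
  )
  fits <- with_stage("train", {
    out <- lapply(eligible, function(d) {
      tr <- prep_training(ccl_z, ccl_response, d)
      grid <- make_alpha_grid(tr$X, tr$y, size = grid_size, eps = grid_eps)
      fit_fun(ccl_z, ccl_response, tumor_z, d, grid = grid, folds = folds,
              seed = seed)
    })
    stats::setNames(out, eligible)
  })
  predictions <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(f$predictions, drug_id = f$drug, .before = 1)
  })

  evaluation <- with_stage("evaluate", {
    evaluate_drug_panel(
      dplyr::select(predictions, "sample_id", "drug_id", "predicted"),
      labels, k = k,
      train_ic50 = dplyr::select(ccl_response, "drug_id", "log_ic50"),
      patients = patients,
      min_per_class = min_per_class, min_total = min_total
    )
  })

  signatures <- list()
  if (!is.null(survival_df) && method %in% c("tglasso", "tissue-restricted")) {
    signatures <- with_stage("signature_survival", {
      counts <- aggregate_gene_selections(fits)
      out <- list()
      for (t in sort(unique(tumor_z$samples$tissue))) {
        res <- tryCatch(
          signature_survival(counts, tumor_z, survival_df, t, min_drugs = min_drugs),
          error = function(e) NULL
        )
        if (!is.null(res)) out[[t]] <- res
      }
      out
    })
  }

  run <- structure(
    list(method = method, harmonization = harmonization, seed = seed,
         eligible_drugs = eligible, fits = fits, predictions = predictions,
         evaluation = evaluation, signatures = signatures,
         expression = list(ccl = ccl_z, tumor = tumor_z)),
    class = "tg_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.tg_run <- function(x, ...) {
  cat(sprintf("<tg_run> method = %s, harmonization = %s, seed = %d\n",
              x$method, x$harmonization, x$seed))
  print(x$evaluation)
  if (length(x$signatures) > 0) {
    for (s in x$signatures) print(s)
  }
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits `predictions.tsv`, `evaluation.tsv`, `precision.tsv` (when
#' computed), `models.tsv` and `summary.json` into `dir`.
#'
#' @param run A `tg_run`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "tg_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    predictions = file.path(dir, "predictions.tsv"),
    evaluation = file.path(dir, "evaluation.tsv"),
    models = file.path(dir, "models.tsv"),
    summary = file.path(dir, "summary.json")
  )
  readr::write_tsv(run$predictions, paths["predictions"], progress = FALSE)
  readr::write_tsv(run$evaluation$drugs, paths["evaluation"], progress = FALSE)
  if (!is.null(run$evaluation$precision)) {
    paths["precision"] <- file.path(dir, "precision.tsv")
    readr::write_tsv(run$evaluation$precision, paths["precision"], progress = FALSE)
  }
  write_models(run$fits, paths["models"])
  summary <- list(
    method = run$method, harmonization = run$harmonization, seed = run$seed,
    n_drugs = nrow(run$evaluation$drugs),
    n_significant = run$evaluation$n_significant,
    combined_p = run$evaluation$combined_p,
    survival = lapply(run$signatures, function(s) {
      list(tissue = s$tissue, n_genes = length(s$genes),
           chisq = s$test$statistic, p_value = s$test$p_value)
    })
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
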