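#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the study conditions emulated by [generate_cohorts()]: a
#' preclinical (microarray-like, log-scale) and a clinical (RNA-seq FPKM)
#' cohort sharing tissue structure, with a per-gene additive/multiplicative
#' batch effect between them; sparse linear log IC50 signals whose active
#' gene set size varies by tissue (tissue signatures are nested within a
#' per-drug master signature, so tissues share a signal core but differ in
#' how many genes carry signal); clinical response categories derived by a
#' median split of the latent sensitivity with label noise; and survival
#' times whose hazard is linked to signature expression.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tissues Tissue labels (default 5 tissues).
#' @param n_ccl,n_tumor Per-tissue cell-line and tumor counts (recycled to
#'   `length(tissues)`; defaults 60 and 30, matching the per-tissue scale of
#'   the large public preclinical and clinical panels).
#' @param signature_sizes Per-tissue active-set sizes (default
#'   `c(5, 10, 20, 40, 80)`).
#' @param n_drugs Number of drugs (default 3).
#' @param private_tissues Number of tissues (taken from the start of
#'   `tissues`) whose signature genes are private to that tissue rather
#'   than drawn from the shared master signature — emulating lineages with
#'   idiosyncratic response biology, e.g. hormone-driven cancers
#'   (default 1).
#' @param coef_scale Overall scale of the effect sizes; the j-th master
#'   gene has coefficient magnitude `coef_scale * U(0.5, 1.5) / sqrt(j)`
#'   (default 1.5).
#' @param response_noise_sd Noise sd added to log IC50 and to the tumors'
#'   latent response (default 0.5).
#' @param expr_noise_sd Per-sample expression noise sd on the log2 scale
#'   (default 1).
#' @param tissue_effect_sd Sd of per-gene tissue mean offsets (default 0.5).
#' @param base_mean_range Range of per-gene baseline log2 expression
#'   (default `c(2, 10)`).
#' @param batch_shift_sd Sd of the per-gene additive batch shift applied to
#'   the clinical cohort on the log2 scale (default 1).
#' @param batch_scale_range Range of the per-gene multiplicative batch
#'   scale on residuals (default `c(0.8, 1.25)`; use `c(1, 1)` for no
#'   scale effect).
#' @param missing_rate Fraction of cell-line log IC50 entries set missing
#'   (default 0.05).
#' @param label_noise Probability of flipping a derived binary response
#'   label (default 0.05; must be below 0.5).
#' @param censor_rate Approximate fraction of censored survival records
#'   (default 0.3).
#' @param survival_link Log-hazard slope on the mean signature expression
#'   (default 0.8).
#' @param base_hazard Baseline exponential hazard per day (default 1/1500).
#' @param seed Integer seed; the whole bundle is reproducible from it
#'   (default 0).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = paste0("tissue", 1:5),
                       n_ccl = 60, n_tumor = 30,
                       signature_sizes = c(5, 10, 20, 40, 80),
                       n_drugs = 3,
                       private_tissues = 1,
                       coef_scale = 1.5,
                       response_noise_sd = 0.5,
                       expr_noise_sd = 1,
                       tissue_effect_sd = 0.5,
                       base_mean_range = c(2, 10),
                       batch_shift_sd = 1,
                       batch_scale_range = c(0.8, 1.25),
                       missing_rate = 0.05,
                       label_noise = 0.05,
                       censor_rate = 0.3,
                       survival_link = 0.8,
                       base_hazard = 1 / 1500,
                       seed = 0) {
  nt <- length(tissues)
  cfg <- list(
    n_genes = n_genes, tissues = tissues,
    n_ccl = rep_len(n_ccl, nt), n_tumor = rep_len(n_tumor, nt),
    signature_sizes = rep_len(signature_sizes, nt), n_drugs = n_drugs,
    private_tissues = private_tissues,
    coef_scale = coef_scale, response_noise_sd = response_noise_sd,
    expr_noise_sd = expr_noise_sd, tissue_effect_sd = tissue_effect_sd,
    base_mean_range = base_mean_range,
    batch_shift_sd = batch_shift_sd, batch_scale_range = batch_scale_range,
    missing_rate = missing_rate, label_noise = label_noise,
    censor_rate = censor_rate, survival_link = survival_link,
    base_hazard = base_hazard, seed = as.integer(seed)
  )
  problems <- character()
  if (n_genes < 1) problems <- c(problems, "n_genes must be positive")
  if (nt < 1) problems <- c(problems, "at least one tissue is required")
  if (anyDuplicated(tissues)) problems <- c(problems, "tissue labels must be unique")
  if (any(cfg$n_ccl < 1) || any(cfg$n_tumor < 1)) {
    problems <- c(problems, "per-tissue sample counts must be positive")
  }
  if (any(cfg$signature_sizes < 1) || any(cfg$signature_sizes > n_genes)) {
    problems <- c(problems, "signature sizes must lie in [1, n_genes]")
  }
  if (n_drugs < 1) problems <- c(problems, "n_drugs must be positive")
  if (private_tissues < 0 || private_tissues > nt) {
    problems <- c(problems, "private_tissues must lie in [0, number of tissues]")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    problems <- c(problems, "label_noise must lie in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    problems <- c(problems, "missing_rate must lie in [0, 1)")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    problems <- c(problems, "censor_rate must lie in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate paired preclinical/clinical cohorts with ground truth
#'
#' Draws a complete synthetic bundle under a [sim_config()]: a preclinical
#' expression matrix (log2 scale, microarray-like) with per-drug log IC50
#' values, a clinical FPKM matrix distorted by a per-gene batch effect, a
#' 4-category clinical response table derived from the tumors' latent
#' sensitivity, a survival table linked to signature expression, and the
#' generator's ground truth for recovery tests. Everything is reproducible
#' from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `tg_cohorts` list: `ccl` (`expr_mat`, stage `"log"`),
#'   `ccl_response` (tibble `sample_id`, `drug_id`, `log_ic50`), `tumor`
#'   (`expr_mat`, stage `"raw"` FPKM), `cdr` (tibble `patient_id`,
#'   `drug_id`, `category`, `start_day`, `end_day`), `survival` (tibble
#'   `patient_id`, `time`, `event`), `truth`, `config`.
#' @export
generate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  nt <- length(cfg$tissues)
  drugs <- paste0("drug", seq_len(cfg$n_drugs))

  base_mean <- stats::runif(ng, cfg$base_mean_range[1], cfg$base_mean_range[2])
  tissue_offset <- matrix(stats::rnorm(ng * nt, 0, cfg$tissue_effect_sd), ng, nt,
                          dimnames = list(gene_ids, cfg$tissues))

  ccl_tissue <- rep(cfg$tissues, cfg$n_ccl)
  tumor_tissue <- rep(cfg$tissues, cfg$n_tumor)
  ccl_ids <- sprintf("ccl%03d", seq_along(ccl_tissue))
  tumor_ids <- sprintf("pt%03d", seq_along(tumor_tissue))

  draw_log_expr <- function(tissue_labels, ids) {
    mu <- base_mean + tissue_offset[, match(tissue_labels, cfg$tissues), drop = FALSE]
    noise <- matrix(stats::rnorm(ng * length(ids), 0, cfg$expr_noise_sd),
                    ng, length(ids))
    m <- mu + noise
    dimnames(m) <- list(gene_ids, ids)
    m
  }

  ccl_log <- draw_log_expr(ccl_tissue, ccl_ids)
  tumor_true_log <- draw_log_expr(tumor_tissue, tumor_ids)

  # microarray-vs-RNA-seq style batch effect, ComBat's L/S model: per-gene
  # additive shift plus multiplicative scaling of residuals on the log scale
  batch_shift <- stats::rnorm(ng, 0, cfg$batch_shift_sd)
  batch_scale <- stats::runif(ng, cfg$batch_scale_range[1], cfg$batch_scale_range[2])
  tumor_obs_log <- base_mean + batch_scale * (tumor_true_log - base_mean) + batch_shift
  tumor_fpkm <- pmax(2^tumor_obs_log - 0.1, 0)

  # nested per-tissue signatures within a per-drug master signature
  smax <- max(cfg$signature_sizes)
  ccl_centered <- ccl_log - base_mean
  tumor_centered <- tumor_true_log - base_mean
  master_genes <- list(); master_coefs <- list(); tissue_coefs <- list()
  active_sets <- list(); resp_rows <- list(); latent_rows <- list(); cdr_rows <- list()
  for (d in drugs) {
    # shared tissue signatures are nested in a master gene order whose
    # effect sizes decay with depth (few strong pharmacogenes, many weak
    # modifiers): a tissue with a small signature responds only through the
    # strong core, one with a large signature also recruits the weak tail.
    # The first `private_tissues` tissues instead use signature genes
    # private to that tissue, with the same decaying-magnitude profile.
    n_private_genes <- sum(utils::head(cfg$signature_sizes, cfg$private_tissues))
    picked <- sample(gene_ids, smax + n_private_genes)
    mg <- picked[seq_len(smax)]
    mc <- stats::setNames(
      sample(c(-1, 1), smax, replace = TRUE) * stats::runif(smax, 0.5, 1.5) /
        sqrt(seq_len(smax)),
      mg
    )
    master_genes[[d]] <- mg
    master_coefs[[d]] <- mc
    offset <- smax
    active_sets[[d]] <- list(); tissue_coefs[[d]] <- list()
    for (i in seq_len(nt)) {
      s_i <- cfg$signature_sizes[i]
      if (i <= cfg$private_tissues) {
        act <- picked[offset + seq_len(s_i)]
        offset <- offset + s_i
        beta <- stats::setNames(
          cfg$coef_scale *
            sample(c(-1, 1), s_i, replace = TRUE) * stats::runif(s_i, 0.5, 1.5) /
            sqrt(seq_len(s_i)),
          act
        )
      } else {
        act <- mg[seq_len(s_i)]
        beta <- cfg$coef_scale * mc[act]
      }
      active_sets[[d]][[cfg$tissues[i]]] <- act
      tissue_coefs[[d]][[cfg$tissues[i]]] <- beta
    }

    signal_for <- function(centered, tissue_labels) {
      vapply(seq_along(tissue_labels), function(i) {
        beta <- tissue_coefs[[d]][[tissue_labels[i]]]
        sum(beta * centered[names(beta), i])
      }, numeric(1))
    }
    y_ccl <- signal_for(ccl_centered, ccl_tissue) +
      stats::rnorm(length(ccl_ids), 0, cfg$response_noise_sd)
    if (cfg$missing_rate > 0) {
      y_ccl[stats::runif(length(y_ccl)) < cfg$missing_rate] <- NA_real_
    }
    resp_rows[[d]] <- tibble::tibble(sample_id = ccl_ids, drug_id = d,
                                     log_ic50 = y_ccl)

    latent <- signal_for(tumor_centered, tumor_tissue) +
      stats::rnorm(length(tumor_ids), 0, cfg$response_noise_sd)
    latent_rows[[d]] <- tibble::tibble(sample_id = tumor_ids, drug_id = d,
                                       latent = latent)
    sensitive <- latent < stats::median(latent)
    flip <- stats::runif(length(latent)) < cfg$label_noise
    sensitive <- xor(sensitive, flip)
    category <- ifelse(
      sensitive,
      sample(c("complete response", "partial response"), length(latent), TRUE),
      sample(c("stable disease", "clinical progressive disease"), length(latent), TRUE)
    )
    start_day <- sample(0:180, length(latent), replace = TRUE)
    cdr_rows[[d]] <- tibble::tibble(
      patient_id = tumor_ids, drug_id = d, category = category,
      start_day = start_day,
      end_day = start_day + sample(20:60, length(latent), replace = TRUE)
    )
  }

  # survival: hazard linked to mean expression over the first drug's
  # tissue-specific signature
  surv_score <- vapply(seq_along(tumor_ids), function(i) {
    act <- active_sets[[drugs[1]]][[tumor_tissue[i]]]
    mean(tumor_centered[act, i])
  }, numeric(1))
  rate <- cfg$base_hazard * exp(cfg$survival_link * surv_score)
  t_event <- stats::rexp(length(tumor_ids), rate)
  cens_rate <- cfg$base_hazard * cfg$censor_rate / max(1 - cfg$censor_rate, 1e-9)
  t_cens <- if (cfg$censor_rate > 0) {
    stats::rexp(length(tumor_ids), cens_rate)
  } else {
    rep(Inf, length(tumor_ids))
  }
  survival_tbl <- tibble::tibble(
    patient_id = tumor_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )

  ccl <- expr_mat(
    ccl_log,
    tibble::tibble(sample_id = ccl_ids, cohort = "preclinical", tissue = ccl_tissue),
    stage = "log"
  )
  tumor <- expr_mat(
    tumor_fpkm,
    tibble::tibble(sample_id = tumor_ids, cohort = "clinical", tissue = tumor_tissue),
    stage = "raw"
  )

  truth <- list(
    master_genes = master_genes,
    master_coefficients = master_coefs,
    active_sets = active_sets,
    tissue_coefficients = tissue_coefs,
    batch = list(shift = stats::setNames(batch_shift, gene_ids),
                 scale = stats::setNames(batch_scale, gene_ids)),
    latent = dplyr::bind_rows(latent_rows),
    survival_score = stats::setNames(surv_score, tumor_ids)
  )

  structure(
    list(ccl = ccl, ccl_response = dplyr::bind_rows(resp_rows),
         tumor = tumor, cdr = dplyr::bind_rows(cdr_rows),
         survival = survival_tbl, truth = truth, config = cfg),
    class = "tg_cohorts"
  )
}

#' @export
print.tg_cohorts <- function(x, ...) {
  cat(sprintf(
    "<tg_cohorts> %d genes, %d cell lines, %d tumors, %d drugs, %d tissues (seed %d)\n",
    x$config$n_genes, ncol(x$ccl$values), ncol(x$tumor$values),
    x$config$n_drugs, length(x$config$tissues), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic bundle as delimited-text fixture files
#'
#' Writes the expression matrices with their metadata, the response tables
#' and the survival table as tab-delimited text, plus the ground truth and
#' config as JSON. The expression files round-trip losslessly through
#' [read_expression_table()].
#'
#' @param bundle A `tg_cohorts`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tg_cohorts"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  }
  paths <- c(
    ccl_expression = file.path(dir, "ccl_expression.tsv"),
    ccl_metadata = file.path(dir, "ccl_metadata.tsv"),
    tumor_expression = file.path(dir, "tumor_expression.tsv"),
    tumor_metadata = file.path(dir, "tumor_metadata.tsv"),
    ccl_response = file.path(dir, "ccl_response.tsv"),
    cdr = file.path(dir, "cdr.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  write_expression_table(bundle$ccl, paths["ccl_expression"], paths["ccl_metadata"])
  write_expression_table(bundle$tumor, paths["tumor_expression"], paths["tumor_metadata"])
  readr::write_tsv(bundle$ccl_response, paths["ccl_response"], progress = FALSE)
  readr::write_tsv(bundle$cdr, paths["cdr"], progress = FALSE)
  readr::write_tsv(bundle$survival, paths["survival"], progress = FALSE)
  truth_json <- bundle$truth
  truth_json$latent <- as.list(truth_json$latent)
  jsonlite::write_json(truth_json, paths["truth"], digits = NA, auto_unbox = FALSE)
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, paths["config"], digits = NA, auto_unbox = FALSE)
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Directory containing the fixture files.
#' @return A `tg_cohorts`-shaped list (truth and config parsed from JSON).
#' @export
read_fixture <- function(dir) {
  ccl <- read_expression_table(file.path(dir, "ccl_expression.tsv"),
                               file.path(dir, "ccl_metadata.tsv"), stage = "log")
  tumor <- read_expression_table(file.path(dir, "tumor_expression.tsv"),
                                 file.path(dir, "tumor_metadata.tsv"), stage = "raw")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$latent <- tibble::as_tibble(truth$latent)
  config <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  structure(
    list(ccl = ccl, ccl_response = read_ccl_response(file.path(dir, "ccl_response.tsv")),
         tumor = tumor, cdr = read_cdr_table(file.path(dir, "cdr.tsv")),
         survival = readr::read_tsv(file.path(dir, "survival.tsv"),
                                    show_col_types = FALSE, progress = FALSE),
         truth = truth, config = config),
    class = "tg_cohorts"
  )
}
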