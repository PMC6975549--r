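#' Clinical drug response category vocabulary
#'
#' The four RECIST-style clinical drug response (CDR) categories and their
#' binary mapping: complete response and partial response count as
#' sensitive; stable disease and clinical progressive disease count as
#' resistant.
#'
#' @format Named character vector mapping category to binary label.
#' @export
cdr_category_map <- c(
  "complete response" = "sensitive",
  "partial response" = "sensitive",
  "stable disease" = "resistant",
  "clinical progressive disease" = "resistant"
)

#' Map 4-category clinical drug response to binary labels
#'
#' @param cdr Data frame with columns `patient_id`, `drug_id`, `category`.
#'   Categories must come from the 4-value vocabulary of
#'   [cdr_category_map]; `(patient_id, drug_id)` pairs must be unique.
#' @return A tibble with columns `patient_id`, `drug_id`, `label`
#'   (`"sensitive"` or `"resistant"`).
#' @export
map_cdr_labels <- function(cdr) {
  cdr <- tibble::as_tibble(cdr)
  stopifnot(all(c("patient_id", "drug_id", "category") %in% names(cdr)))
  unknown <- setdiff(unique(cdr$category), names(cdr_category_map))
  if (length(unknown) > 0) {
    stop("unknown CDR category: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- cdr |>
    dplyr::count(.data$patient_id, .data$drug_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (patient, drug) pairs in CDR table, e.g. ",
         dup$patient_id[1], " / ", dup$drug_id[1], call. = FALSE)
  }
  tibble::tibble(
    patient_id = cdr$patient_id,
    drug_id = cdr$drug_id,
    label = unname(cdr_category_map[cdr$category])
  )
}

#' Drugs with enough labeled patients for evaluation
#'
#' A drug is eligible when it has at least `min_per_class` patients in each
#' of the resistant and sensitive classes and at least `min_total` labeled
#' patients overall.
#'
#' @param resp Binary response tibble as returned by [map_cdr_labels()].
#' @param min_per_class Minimum patients per class (default 2).
#' @param min_total Minimum total labeled patients (default 8).
#' @return Sorted character vector of eligible drug ids (possibly empty).
#' @export
filter_eligible_drugs <- function(resp, min_per_class = 2, min_total = 8) {
  resp <- tibble::as_tibble(resp)
  stopifnot(all(c("drug_id", "label") %in% names(resp)))
  counts <- resp |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(
      n_resistant = sum(.data$label == "resistant"),
      n_sensitive = sum(.data$label == "sensitive"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  eligible <- counts |>
    dplyr::filter(
      .data$n_resistant >= min_per_class,
      .data$n_sensitive >= min_per_class,
      .data$n_total >= min_total
    )
  sort(eligible$drug_id)
}

#' Read a long-format cell-line drug response table
#'
#' @param path Delimited file with columns `sample_id`, `drug_id`,
#'   `log_ic50` (missing values allowed, encoded as empty or NA).
#' @return A tibble with those columns; `log_ic50` numeric.
#' @export
read_ccl_response <- function(path) {
  delim <- sniff_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "drug_id", "log_ic50") %in% names(out)))
  out$log_ic50 <- as.numeric(out$log_ic50)
  tibble::as_tibble(out)
}

#' Read a patient clinical drug response table
#'
#' @param path Delimited file with columns `patient_id`, `drug_id`,
#'   `category`, and optionally `start_day`, `end_day` (administration
#'   interval, used for the drug-combination subanalysis).
#' @return A tibble.
#' @export
read_cdr_table <- function(path) {
  delim <- sniff_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("patient_id", "drug_id", "category") %in% names(out)))
  tibble::as_tibble(out)
}

#' Patients whose drug administration overlapped another drug
#'
#' Identifies, per drug, the patients for whom that drug's administration
#' interval overlaps the interval of at least one other drug given to the
#' same patient — the patient subset used for the drug-combination
#' subanalysis. Intervals are closed; records without interval columns are
#' never flagged.
#'
#' @param cdr CDR tibble with columns `patient_id`, `drug_id`, `start_day`,
#'   `end_day`.
#' @return Tibble with columns `patient_id`, `drug_id` for overlapping
#'   administrations.
#' @export
overlapping_administration <- function(cdr) {
  cdr <- tibble::as_tibble(cdr)
  stopifnot(all(c("patient_id", "drug_id", "start_day", "end_day") %in% names(cdr)))
  pairs <- dplyr::inner_join(
    cdr, cdr,
    by = "patient_id", suffix = c("", ".other"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$drug_id != .data$drug_id.other,
      .data$start_day <= .data$end_day.other,
      .data$start_day.other <= .data$end_day
    ) |>
    dplyr::distinct(.data$patient_id, .data$drug_id)
  dplyr::arrange(pairs, .data$patient_id, .data$drug_id)
}
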