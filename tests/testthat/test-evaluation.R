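test_that("one-sided Mann-Whitney matches exact enumeration on small groups", {
  expect_equal(mwu_one_sided(c(3, 4), c(1, 2)), 1 / 6, tolerance = 1e-12)
  expect_equal(mwu_one_sided(c(1, 2), c(3, 4)), 1, tolerance = 1e-12)
  expect_error(mwu_one_sided(5, numeric(0)), "non-empty")

  # exhaustive agreement with the enumeration oracle over random
  # distinct-value inputs at every group-size combination up to 5
  set.seed(30)
  for (n1 in 1:5) {
    for (n2 in 1:5) {
      vals <- sample(seq_len(1000), n1 + n2) + stats::runif(n1 + n2, 0, 0.5)
      r <- vals[seq_len(n1)]; s <- vals[-seq_len(n1)]
      expect_equal(mwu_one_sided(r, s), mwu_enum_oracle(r, s),
                   tolerance = 1e-12,
                   label = sprintf("exact path at n1=%d n2=%d", n1, n2))
    }
  }

  # large groups switch to the corrected normal approximation
  set.seed(31)
  r <- rnorm(30, 1); s <- rnorm(40)
  expect_equal(
    mwu_one_sided(r, s),
    stats::wilcox.test(r, s, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  )
})

test_that("Fisher's method matches its closed forms and is monotone", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  for (p in c(0.9, 0.3, 0.05, 1e-4)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)        # df = 2
    expect_equal(fisher_combine(p), fisher_df2_oracle(p), tolerance = 1e-12)
  }
  expect_equal(fisher_combine(c(0.05, 0.05)), fisher_df4_oracle(0.05, 0.05),
               tolerance = 1e-10)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747, tolerance = 1e-3)
  # lowering any one p lowers the combination
  base <- c(0.2, 0.5, 0.8)
  for (i in 1:3) {
    lower <- base; lower[i] <- lower[i] / 2
    expect_lt(fisher_combine(lower), fisher_combine(base))
  }
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
})

test_that("Precision@k% reproduces hand-computed toys and the undefined case", {
  train <- 0:9 # t_20 = 1.8, t_80 = 7.2 under linear interpolation
  preds <- c(9, 1, 5)
  labels <- c("resistant", "sensitive", "resistant")
  out <- precision_at_k(train, preds, labels, k = 20)
  expect_equal(out$t_low, 1.8)
  expect_equal(out$t_high, 7.2)
  expect_equal(out$value, 1)

  flipped <- c("sensitive", "resistant", "resistant")
  expect_equal(precision_at_k(train, preds, flipped, k = 20)$value, 0)

  mid <- precision_at_k(train, c(5, 5.5, 4), labels, k = 20)
  expect_false(mid$defined)
  expect_true(is.na(mid$value))

  expect_error(precision_at_k(train, preds, labels, k = 60), "at most 50")
})

test_that("Precision@k% is invariant under joint monotone transforms", {
  set.seed(32)
  train <- rnorm(50); preds <- rnorm(20)
  labels <- sample(c("resistant", "sensitive"), 20, TRUE)
  f <- function(x) exp(x / 2) + x^3 / 10 # strictly increasing
  for (k in c(10, 25, 50)) {
    a <- precision_at_k(train, preds, labels, k)
    b <- precision_at_k(f(train), f(preds), labels, k)
    expect_equal(a$value, b$value, label = paste("k =", k))
    expect_equal(a$n_high + a$n_low, b$n_high + b$n_low)
  }
})

test_that("threshold scan maximizes the odds ratio over every cut", {
  # perfectly separable toy: best cut isolates both classes
  out <- threshold_scan_contingency(c(1, 2, 3, 4),
                                    c("sensitive", "sensitive", "resistant",
                                      "resistant"))
  expect_true(out$threshold > 2 && out$threshold < 3)
  expect_equal(unname(out$table), matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(out$stats$odds_ratio, Inf)

  # agreement with the brute-force oracle on random instances up to n = 50
  set.seed(33)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    preds <- rnorm(n)
    labels <- ifelse(preds + rnorm(n) > 0, "resistant", "sensitive")
    if (length(unique(labels)) < 2) next
    got <- threshold_scan_contingency(preds, labels)
    want <- threshold_scan_oracle(preds, labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(unname(got$table), unname(want$table))
  }

  expect_error(threshold_scan_contingency(c(1, 2), c("resistant", "resistant")),
               "both classes")
  expect_error(threshold_scan_contingency(c(1, 1), c("resistant", "sensitive")),
               "constant")
})

test_that("label-independent predictions give near-null odds ratios", {
  # maximizing over every cut inflates the raw odds ratio (the winning cut
  # often isolates a pure tail, making it infinite), so the null behavior
  # is checked on the Haldane-corrected odds ratio of the winning table
  set.seed(34)
  preds <- rnorm(60)
  labels <- rep(c("resistant", "sensitive"), 30)
  ors <- replicate(100, {
    tab <- threshold_scan_contingency(preds, sample(labels))$table + 0.5
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  })
  med <- stats::median(ors)
  expect_true(med >= 0.2 && med <= 8)
  # and the selected association is far weaker than a real one
  real <- threshold_scan_contingency(preds + 2 * (labels == "resistant"), labels)
  expect_gt(real$stats$odds_ratio, med)
})

test_that("contingency summaries recover published-style table statistics", {
  tab <- matrix(c(23, 2, 58, 53), 2, 2, byrow = TRUE)
  st <- contingency_stats(tab)
  expect_equal(st$odds_ratio, (23 * 53) / (2 * 58))
  expect_equal(st$recall, 23 / 25)
  expect_lt(st$p_one_sided, 0.001)
})

test_that("panel evaluation assembles per-drug tests and combines them", {
  set.seed(35)
  mk_drug <- function(drug, shift) {
    labels <- rep(c("resistant", "sensitive"), each = 12)
    tibble::tibble(
      patient_id = paste0(drug, "_p", 1:24), drug_id = drug,
      predicted = rnorm(24) + ifelse(labels == "resistant", shift, 0),
      label = labels
    )
  }
  dat <- dplyr::bind_rows(mk_drug("d1", 2), mk_drug("d2", 2.5), mk_drug("d3", 2))
  preds <- dplyr::select(dplyr::rename(dat, sample_id = patient_id),
                         "sample_id", "drug_id", "predicted")
  resp <- dplyr::select(dat, "patient_id", "drug_id", "label")
  ev <- evaluate_drug_panel(preds, resp)
  expect_equal(nrow(ev$drugs), 3)
  expect_true(all(ev$drugs$p_value < 0.05))
  expect_lt(ev$combined_p, min(ev$drugs$p_value))
  expect_equal(ev$n_significant, 3L)
  expect_equal(glance(ev)$combined_p, ev$combined_p)

  # single-drug panel: combined p is that drug's p
  ev1 <- evaluate_drug_panel(preds[preds$drug_id == "d1", ], resp)
  expect_equal(ev1$combined_p, ev1$drugs$p_value, tolerance = 1e-12)

  # ineligible drugs are excluded; empty panels error
  tiny <- mk_drug("d9", 0)[1:3, ]
  expect_error(
    evaluate_drug_panel(
      dplyr::select(dplyr::rename(tiny, sample_id = patient_id),
                    "sample_id", "drug_id", "predicted"),
      dplyr::select(tiny, "patient_id", "drug_id", "label")
    ),
    "no eligible"
  )

  # patient subsetting restricts the evaluation (combination subanalysis)
  sub <- evaluate_drug_panel(preds, resp,
                             patients = unique(dat$patient_id)[1:48])
  expect_lte(nrow(sub$data), 48)
})

test_that("precision curves are computed per drug when training IC50 is given", {
  set.seed(36)
  labels <- rep(c("resistant", "sensitive"), each = 10)
  preds <- tibble::tibble(
    sample_id = paste0("p", 1:20), drug_id = "d1",
    predicted = ifelse(labels == "resistant", rnorm(20, 3), rnorm(20, 0))
  )
  resp <- tibble::tibble(patient_id = paste0("p", 1:20), drug_id = "d1",
                         label = labels)
  train <- tibble::tibble(drug_id = "d1", log_ic50 = rnorm(100, 1.5, 2))
  ev <- evaluate_drug_panel(preds, resp, k = c(20, 50), train_ic50 = train)
  expect_equal(nrow(ev$precision), 2)
  expect_true(all(ev$precision$value[ev$precision$defined] >= 0))
  p <- plot_precision_curves(ev)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
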