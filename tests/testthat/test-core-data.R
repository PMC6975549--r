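test_that("expression tables round-trip through delimited text", {
  m <- matrix(c(1.5, 2, 0.25, 3, 4.125, 5), nrow = 3,
              dimnames = list(c("TP53", "EGFR", "BRCA1"), c("s1", "s2")))
  x <- make_expr(m, cohort = "clinical", tissue = c("lung", "breast"))
  dir <- withr::local_tempdir()
  write_expression_table(x, file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  y <- read_expression_table(file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  expect_equal(y$values, x$values)
  expect_equal(y$samples$tissue, x$samples$tissue)
  expect_equal(dim(y), c(3L, 2L))
})

test_that("malformed expression input is rejected with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id\ts1\ts2", "TP53\t1\t2", "TP53\t3\t4"),
             file.path(dir, "dup.tsv"))
  writeLines(c("sample_id\tcohort\ttissue", "s1\tclinical\tlung",
               "s2\tclinical\tlung"), file.path(dir, "meta.tsv"))
  expect_error(read_expression_table(file.path(dir, "dup.tsv"),
                                     file.path(dir, "meta.tsv")), "TP53")

  writeLines(c("gene_id\ts1\ts2", "TP53\t1\toops"), file.path(dir, "bad.tsv"))
  err <- expect_error(read_expression_table(file.path(dir, "bad.tsv"),
                                            file.path(dir, "meta.tsv")))
  expect_match(conditionMessage(err), "oops")
  expect_match(conditionMessage(err), "s2")

  writeLines(c("gene_id\ts1\ts2", "TP53\t1\t2"), file.path(dir, "ok.tsv"))
  writeLines(c("sample_id\tcohort\ttissue", "s1\tclinical\tlung"),
             file.path(dir, "meta1.tsv"))
  expect_error(read_expression_table(file.path(dir, "ok.tsv"),
                                     file.path(dir, "meta1.tsv")), "s2")
})

test_that("FPKM filter drops unexpressed and missing genes with a strict boundary", {
  v <- rbind(
    alllow = rep(0.5, 10),            # FPKM < 1 in 10/10 -> dropped
    boundary = c(rep(0.5, 9), 2),     # 9/10 = 0.9 is not > 0.9 -> kept
    hasna = c(NA, rep(5, 9)),         # missing value -> dropped
    expressed = rep(3, 10)
  )
  colnames(v) <- paste0("s", 1:10)
  x <- make_expr(v)
  out <- preprocess_tumor_fpkm(x)
  expect_setequal(genes(out), c("boundary", "expressed"))
  expect_equal(out$stage, "log")
  expect_equal(out$values["expressed", 1], log2(3.1))

  # a gene at FPKM 0.9 kept under a looser fraction maps to log2(1.0) = 0
  y <- make_expr(matrix(0.9, 1, 10, dimnames = list("g", paste0("s", 1:10))))
  out2 <- preprocess_tumor_fpkm(y, max_unexpressed_fraction = 1)
  expect_equal(unname(out2$values[1, ]), rep(0, 10))

  expect_error(preprocess_tumor_fpkm(make_expr(matrix(0.1, 2, 10))), "no genes")
})

test_that("gene-space harmonization intersects and filters by pooled sd", {
  a <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                        dimnames = list(c("g1", "g2", "g3"), c("a1", "a2"))),
                 cohort = "preclinical", stage = "log")
  bvals <- matrix(c(2, 30, 9, 2.04, 3.5, 9.5), 3, 2,
                  dimnames = list(c("g2", "g3", "g4"), c("b1", "b2")))
  b <- make_expr(bvals, stage = "log")
  out <- harmonize_gene_space(a, b, sd_min = 0)
  expect_equal(genes(out$a), c("g2", "g3"))
  expect_equal(genes(out$a), genes(out$b))

  # pooled sd of g2 (2, 5, 2, 2.04) ~ 1.28 falls below a 2.0 cutoff while
  # g3 (3, 6, 30, 3.5) survives it
  out2 <- harmonize_gene_space(a, b, sd_min = 2)
  expect_equal(genes(out2$a), "g3")

  # constant gene is always removed (sd 0 < 0.1)
  a2 <- make_expr(matrix(1, 1, 2, dimnames = list("g9", c("a1", "a2"))), stage = "log")
  b2 <- make_expr(matrix(1, 1, 2, dimnames = list("g9", c("b1", "b2"))), stage = "log")
  expect_error(harmonize_gene_space(a2, b2), "no genes")

  disjoint <- make_expr(matrix(1, 1, 2, dimnames = list("gX", c("c1", "c2"))),
                        stage = "log")
  expect_error(harmonize_gene_space(a, disjoint), "no shared genes")
})

test_that("z-scoring yields exact moments, is idempotent and affine-invariant", {
  x <- make_expr(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL)), stage = "log")
  z <- zscore_normalize(x)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)

  set.seed(42)
  m <- matrix(rnorm(50), 5, 10)
  zm <- zscore_normalize(make_expr(m, stage = "log"))
  expect_true(all(abs(rowMeans(zm$values)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(zm$values^2)) - 1) < 1e-10))
  # idempotence
  expect_equal(zscore_normalize(zm)$values, zm$values, tolerance = 1e-10)
  # removing a per-gene affine transform: z(a*x + b) == z(x) for a > 0
  m2 <- m * 3.7 + 11
  expect_equal(zscore_normalize(make_expr(m2, stage = "log"))$values,
               zm$values, tolerance = 1e-8)

  expect_error(zscore_normalize(make_expr(matrix(1, 1, 4), stage = "log")),
               "zero-variance")
})

test_that("CDR categories map to binary labels and unknown categories error", {
  cdr <- tibble::tibble(
    patient_id = paste0("p", 1:4), drug_id = "cisplatin",
    category = c("complete response", "partial response", "stable disease",
                 "clinical progressive disease")
  )
  out <- map_cdr_labels(cdr)
  expect_equal(out$label, c("sensitive", "sensitive", "resistant", "resistant"))
  expect_error(
    map_cdr_labels(dplyr::mutate(cdr[1, ], category = "not evaluable")),
    "not evaluable"
  )
  expect_error(map_cdr_labels(dplyr::bind_rows(cdr, cdr[1, ])), "duplicate")
})

test_that("drug eligibility enforces per-class and total patient minimums", {
  mk <- function(drug, n_r, n_s) {
    tibble::tibble(
      patient_id = paste0(drug, seq_len(n_r + n_s)), drug_id = drug,
      label = rep(c("resistant", "sensitive"), c(n_r, n_s))
    )
  }
  resp <- dplyr::bind_rows(
    mk("one_res", 1, 10),    # fails per-class
    mk("boundary", 2, 6),    # exactly 2 + total 8 -> eligible
    mk("seven", 3, 4)        # total 7 -> fails
  )
  expect_equal(filter_eligible_drugs(resp), "boundary")
  # order independence
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(filter_eligible_drugs(shuffled), "boundary")
})

test_that("overlapping administration intervals flag combination patients", {
  cdr <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2"),
    drug_id = c("a", "b", "a", "b"),
    category = "stable disease",
    start_day = c(0, 10, 0, 50),
    end_day = c(20, 30, 20, 70)
  )
  out <- overlapping_administration(cdr)
  expect_setequal(paste(out$patient_id, out$drug_id),
                  c("p1 a", "p1 b"))
})

test_that("preprocessing then harmonization keeps gene order aligned", {
  cfg <- small_sim(seed = 3)
  b <- generate_cohorts(cfg)
  tl <- preprocess_tumor_fpkm(b$tumor)
  out <- harmonize_gene_space(b$ccl, tl)
  expect_identical(genes(out$a), genes(out$b))
  expect_true(all(genes(out$a) %in% genes(b$ccl)))
})
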