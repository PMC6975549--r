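---
title: "Tissue-guided LASSO: models, statistics and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-guided LASSO: models, statistics and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tglasso)
```

## The problem

Clinical drug response (CDR) of cancer patients is scarce: most patients
receive only the standard of care, so supervised models cannot be trained
per drug on patients alone. Large preclinical panels, by contrast, measure
genome-wide expression and continuous drug sensitivity — log(IC50) — for
hundreds of cancer cell lines (CCLs) across many drugs. `tglasso`
implements a preclinical-to-clinical transfer workflow: train sparse linear
models on CCL expression and log(IC50), predict log(IC50) for patient
tumors from their expression, and judge the predictions against the
patients' categorical CDR with rank-based statistics.

Two obstacles shape the design. First, the cohorts come from different
platforms (microarray intensities vs RNA-seq FPKM), so expression must be
harmonized before any model sees it. Second, drug response biology is
tissue-dependent, and how tissue of origin is injected into the model
matters; the package implements three strategies plus the tissue-naive
baseline.

## Preprocessing and harmonization

The clinical FPKM matrix is filtered and transformed: genes with any
missing value are dropped; genes not expressed (FPKM < 1) in strictly more
than 90% of samples are dropped (a gene unexpressed in exactly 90% is
kept); surviving values become `log2(FPKM + 0.1)`. The preclinical matrix
is already continuous on a log-like scale and is required to be complete —
it does not pass this filter.

Both cohorts are then restricted to their shared genes, genes with pooled
standard deviation below 0.1 are removed, the pooled matrix is
batch-corrected with the parametric empirical-Bayes ComBat algorithm
(cohort as the only batch factor, no covariates; delegated to
`sva::ComBat`), and every gene is z-scored across all samples. Choices
worth making explicit:

* **Standard deviations are population-style** (divide by *n*), both in the
  variability filter and in z-scoring, so the "mean 0, sd 1" postcondition
  of `zscore_normalize()` is exact rather than approximate.
* **The correction is transductive**: ComBat sees the pooled training and
  test expression at once. It never sees any response label, and the test
  suite verifies that permuting the clinical labels cannot change
  predictions. `combat_correct(method = "none")` is an identity backend for
  the no-homogenization ablation.
* ComBat's empirical-Bayes shrinkage means an isolated shifted gene among
  many unshifted ones is deliberately under-corrected; only batch-wide
  structure is fully removed. The harmonization tests therefore plant
  global shifts.

## The regression core

For one drug, with `X` the n-by-m z-scored CCL expression matrix and `y`
the log(IC50) vector, `fit_lasso()` minimizes

$$\frac{1}{2n}\lVert y - Xw - b\rVert_2^2 + \alpha \lVert w\rVert_1,$$

with an unpenalized intercept and no internal re-standardization (features
are z-scored upstream). The fit is delegated to glmnet along a short
warm-start path; the test suite holds the solution to a closed-form
single-feature oracle and to an independent proximal-gradient reference
within 1e-5 on the objective.

The penalty grid (`make_alpha_grid()`) has 100 log-spaced points from the
data-derived null-model boundary $\alpha_{\max} = \max_j |x_j^\top (y -
\bar y)|/n$ down to $10^{-3}\,\alpha_{\max}$ — a standard
regularization-path default. Cross-validation (`cv_select_alpha()`)
assigns folds by a seeded permutation and minimizes mean held-out squared
error; ties prefer the larger (sparser) penalty, which also makes
selection deterministic.

### Tissue strategies

* **Global LASSO** (`lasso_fit_predict()`): one cross-validated penalty,
  one model for all tumors.
* **Method 1** (`method1_fit_predict()`): one-hot tissue indicator columns
  appended to the expression features. The indicators are penalized like
  genes; with thousands of genes and a handful of indicators the gene
  block dominates, which is exactly why this strategy tracks plain LASSO.
* **Method 2** (`method2_fit_predict()`): a separate model per tissue,
  trained only on that tissue's cell lines, with the fold count shrunk to
  `min(5, n_t)`; tissues with no match or fewer than 3 cell lines fall
  back to the all-CCL model. Cross-validation needs at least 3 samples,
  hence the threshold.
* **TG-LASSO** (`tg_lasso_fit_predict()`): for each tumor tissue *t*, the
  cell lines of tissue *t* are held out as a validation set, a path is
  fitted on all other cell lines, and the penalty $\alpha_t$ minimizing
  the held-out mean squared error is selected ("accuracy" is interpreted
  as MSE — the natural loss for a continuous response). A single model is
  then refitted on **all** cell lines with $\alpha_t$ and used for the
  tumors of tissue *t*. Tissues that defeat the hold-out construction
  (no matching cell lines, or an empty training complement) are predicted
  by the cross-validated fallback model.

Cell lines missing the drug's log(IC50) are dropped before training.
Selected genes are the nonzero-coefficient genes, ordered by decreasing
absolute coefficient with gene-id tie-breaks.

## Evaluation statistics

Patient CDR categories map deterministically to binary labels: complete
and partial response are *sensitive*, stable disease and clinical
progressive disease are *resistant*. A drug enters evaluation only with at
least 2 patients per class and at least 8 labeled patients.

* `mwu_one_sided()` tests whether predicted log(IC50) of resistant
  patients is stochastically larger than that of sensitive patients. The
  exact null distribution is used when both groups have at most 8
  observations and no ties — small clinical groups are exactly where the
  normal approximation is least trustworthy — otherwise the tie- and
  continuity-corrected normal approximation.
* `fisher_combine()` combines the per-drug p-values of the whole panel
  (significant or not) as $-2\sum\ln p \sim \chi^2_{2k}$.
* `precision_at_k()` computes Precision@k%: the k-th and (100−k)-th
  percentiles of the *training* log(IC50) values (linear interpolation
  between closest ranks, the common numeric-stack convention) define
  calling thresholds; precision is computed over tumors predicted strictly
  outside them, and the measure is flagged undefined when no tumor falls
  outside either threshold.
* `threshold_scan_contingency()` scans all midpoints between consecutive
  sorted unique predictions, calls a tumor resistant when its prediction
  is strictly greater than the threshold (ties fall to sensitive), and
  returns the 2x2 table maximizing the odds ratio. Tables are ranked with
  the Haldane +0.5 correction only when a zero cell exists; the winning
  table is reported with its uncorrected odds ratio (infinity allowed) and
  both one- and two-sided Fisher exact p-values, since the sidedness
  convention of published tables is often unstated. Note that maximizing
  over cuts inflates the raw odds ratio — under label-permuted nulls the
  winning cut often isolates a pure tail, so null calibration should be
  read from the corrected odds ratio or the permutation itself.

## Signatures and survival

`aggregate_gene_selections()` tabulates, over a drug-by-tissue grid of
fitted models, how many tissues select each gene per drug and how many
drugs select it per tissue. A tissue's signature is the set of genes
selected for strictly more than 5 drugs in that tissue. Patients of that
tissue are clustered on signature-gene expression by agglomerative
hierarchical clustering with cosine distance and average linkage (the
standard pairing for cosine; the linkage is otherwise an open choice), cut
at two clusters, and compared with the standard two-group log-rank test.
Clustering operates on z-scored expression, so cosine similarity is not
dominated by high-mean genes.

## The synthetic cohort generator

`generate_cohorts()` draws paired cohorts with the statistical structure
the method presumes, plus ground truth for recovery tests:

* **Expression.** Gene baselines U(2, 10) on the log2 scale, per-gene
  tissue offsets N(0, 0.5), within-tissue noise N(0, 1). The clinical
  cohort is distorted by a per-gene batch effect in exactly ComBat's
  location/scale form — additive shift N(0, 1) and residual scale
  U(0.8, 1.25) — then exponentiated to FPKM, which also exercises the
  FPKM floor and the unexpressed-gene filter.
* **Response.** Each drug has a master signature whose effect sizes decay
  with depth ($\propto 1/\sqrt{j}$): a few strong pharmacogenes and a tail
  of weak modifiers. Shared tissues use nested prefixes of this master
  order — tissues differ in how much of the spectrum is active (support
  sizes 5, 10, 20, 40, 80) — so signal is partially transferable across
  tissues, which is the premise of hold-one-tissue-out tuning. One tissue
  uses a private signature instead, emulating lineages with idiosyncratic
  response biology (hormone-driven cancers being the canonical example);
  for such a tissue the correct tissue-specific penalty is large. log(IC50)
  is the tissue's linear signal plus N(0, 0.5) noise; 5% of entries are
  set missing. Cell-line and tumor counts default to 60 and 30 per tissue,
  the per-tissue scale of the large public panels once restricted to
  lineages shared between preclinical and clinical cohorts.
* **CDR.** A tumor is sensitive when its latent response (computed from
  its true, pre-batch expression) falls below the per-drug cohort median,
  flipped with 5% label noise, then expanded to the four clinical
  categories. This creates the resistant-stochastically-larger structure
  the Mann-Whitney evaluation assumes while keeping classes balanced.
* **Survival.** Exponential times with log-hazard linear in mean
  signature expression, independently censored at roughly 30% — the
  simplest link under which cluster separation is detectable by the
  log-rank test.

What the generator does **not** emulate: gene-gene correlation networks,
dose-response curve shape, tumor heterogeneity and purity, and any
preclinical-to-clinical concept shift beyond the platform batch effect.
Passing recovery tests on these cohorts therefore demonstrates correctness
of the machinery under the model's own assumptions, not clinical validity.

## Benchmark design and what it shows

The package's simulation suites (20 seeds each, run by the test suite on
one CPU) use the default benchmark — 2000 genes, 5 tissues, supports
{5, 10, 20, 40, 80}, response noise sd 0.5, 300 cell lines and 150 tumors
— and a lighter 600-gene, 40-cell-line variant for the harmonization
ablation. Three findings are stable across seed batches:

* the tissue-selected penalty $\alpha_t$ is anti-correlated with the true
  support size (sparser tissues get larger penalties);
* tissue-restricted training (Method 2) is clearly inferior to TG-LASSO —
  the small-sample regime of per-tissue panels dominates;
* with a strong injected batch shift (sd 2), enabling ComBat improves the
  panel's combined Mann-Whitney separation relative to the identity
  backend in nearly every replicate.

One finding is deliberately reported as fragile: the *per-tissue test MSE*
advantage of TG-LASSO over the single cross-validated global penalty. With
harmonized (hence nearly in-distribution) tumors, pooled cross-validation
is statistically efficient, and the leave-tissue-out validation curve on a
60-cell-line tissue panel is noisy; its argmin occasionally picks extreme
penalties, and that selection noise consumes most of the genuine but small
per-tissue adaptivity gain. Across many fresh seed batches the win rate
hovers near 0.5-0.65 rather than clearing a comfortable majority, and the
corresponding check in the test suite is expected to fall short of its
70% threshold rather than be weakened to pass. The adaptivity itself (the
$\alpha_t$ ordering) and the
robustness rankings against the baselines are the reproducible signal.

## Numerical conventions and degenerate inputs

* Constant response: `fit_lasso()` returns the mean model; grids cannot be
  built on it and say so.
* Penalties at or above $\alpha_{\max}$ return the exact null model (zero
  coefficients, intercept $\bar y$), not a numerically-almost-null one.
* Zero-variance genes are an error at z-scoring time (the variability
  filter should have removed them), as are zero-norm patient vectors in
  cosine clustering — both errors name the offender.
* All stochastic steps (fold assignment, the generator) flow from explicit
  integer seeds; reruns are byte-identical, and the tests assert it.

## Limitations

Identifier harmonization (probe-to-gene mapping, symbol aliasing) is out
of scope: gene sets intersect by exact string match. ComBat is implemented
for exactly two batches with no protected covariates. The survival module
fits no covariate-adjusted models (no Cox regression) — it reproduces the
two-cluster log-rank design only.
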