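---
title: "Serum small-RNA biomarker panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum small-RNA biomarker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panelmiR implements the analysis pattern used in circulating small-RNA
biomarker studies of rare diseases: a small patient cohort (typically eight
patients per disease) is compared against a larger pool of age- and
gender-matched healthy controls (twenty-two here), first by negative-binomial
differential expression, then by a cross-validated classifier that searches
for a compact miRNA panel, and finally by target-gene and functional
annotation of the selected markers. This vignette describes the models, the
tunable parameters, and the design decisions behind each stage.

## The count model and differential expression

Counts for miRNA $g$ in sample $s$ are modelled as negative binomial,
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$, with
$\mathrm{Var}(y) = \mu + \phi\mu^2$ and
$\log \mu_{gs} = x_s^\top\beta_g + \log(\tilde N_s)$, where $\tilde N_s$ is
the sample's *effective* library size and $x_s$ encodes the two-group
patient/control design with control as the reference level, so the group
coefficient is the patient-vs-control log fold-change.

Three standard steps surround the test:

* **Abundance filter** (`filter_low_expression()`): a miRNA is kept when it
  reaches at least 1 count per million in at least two libraries. CPM for the
  filter is computed from raw library sizes, *before* normalization, because
  the filtered matrix is what the normalization sees; both thresholds are
  inclusive (`>=`).
* **TMM normalization** (`tmm_factors()`): the trimmed mean of M-values with
  its published defaults — the reference is the sample whose upper-quartile
  CPM is closest to the mean upper-quartile, 30% of M-value extremes and 5%
  of A-value extremes are trimmed, the surviving M-values are averaged with
  inverse delta-method variances as weights, and the factors are re-centred
  to unit geometric mean. The pairwise factor computation is implemented in
  the package itself (and cross-checked against edgeR in the test suite)
  because the classifier needs the one-sample-versus-reference primitive to
  scale a held-out sample with training-derived quantities; edgeR does not
  expose that step.
* **Quasi-likelihood F-test** (`fit_dispersions()` / `ql_f_test()`, via
  edgeR): the common/trended/tagwise NB dispersions are estimated by
  Cox–Reid adjusted profile likelihood with empirical-Bayes shrinkage
  (`prior_df = 10` by default), per-miRNA GLMs are fitted with the
  log-library-size offset, and the group effect is tested with the QL
  F-statistic whose residual uncertainty is itself moderated. Fold changes
  carry a small abundance prior (prior count 0.125, library-size scaled), so
  zero counts give finite `log2fc`. Reported per miRNA: `log2fc`, `logcpm`,
  `f`, `p_value`, and Benjamini–Hochberg `fdr`.

Bit-equality with any particular external implementation is not a goal; the
contracts tested are calibration (null type-I error within three binomial
standard errors of 0.05 at $\alpha = 0.05$ on a 2,000-miRNA, 8-vs-22 null
cohort), parameter recovery (common dispersion estimated within
$[0.3, 0.5]$ when the truth is $0.4$), and agreement of a single-miRNA
p-value within a factor of two of an exact NB likelihood-ratio oracle
maximized directly on a grid.

Descriptive outputs follow the conventions of the field: volcano classes
(`over`/`under` at `p < 0.05` and `|log2FC| > 1`), one-decimal percentages of
significant miRNAs rounded half-away-from-zero, row-wise Z-scores for
heatmaps with constant rows mapped to zero, and percent variance from
centred PCA over samples.

## The nested cross-validated panel classifier

The classifier answers a different question from the per-miRNA tests: can a
*small panel* of miRNAs, acting jointly, separate patients from controls?
The procedure (`loocv_evaluate()`, `sweep_panel_sizes()`) is a leave-one-out
cross-validation in which **everything is refit inside each fold**:

1. remove one sample;
2. filter, TMM-normalize and run the QL F-test on the remaining samples
   only;
3. take the top-$k$ miRNAs by p-value (ties broken by larger `|log2fc|`,
   then identifier — a fully deterministic ordering);
4. train an SVM on the training samples' `log2(CPM + 1)` expression,
   standardized by training means and standard deviations;
5. scale the held-out sample by its pairwise TMM factor against the
   *training* reference (centred by the training factors' constant), apply
   the training standardization, and record the predicted label and decision
   score.

Pooled fold predictions give accuracy, sensitivity, specificity and the
Matthews correlation coefficient (zero-denominator convention: MCC = 0), and
the pooled decision scores give the Mann–Whitney AUC with ties counted one
half. The panel-size sweep starts at six miRNAs and grows the panel until
the best accuracy stops improving for `patience = 3` consecutive sizes; the
optimal size is the smallest achieving the best accuracy, and the *pooled
unique panel* is the union of fold-selected miRNAs at that size.

Decisions where the procedure is genuinely open, and our defaults:

* **SVM kernel and cost**: radial basis, cost 1, `gamma = 1/n_features` —
  the classical defaults of the e1071/libsvm implementation; a linear kernel
  is exposed via `kernel = "linear"`. No class weighting by default despite
  the 8-vs-22 imbalance.
* **Saturation rule**: `start = 6`, `step = 1`, `patience = 3`; all three
  are arguments.
* **Fold universe**: every sample (patients and controls) is held out in
  turn, so the fold count equals the cohort size.
* **AUC source**: pooled held-out decision values, not refit probabilities.

The test suite carries a *leakage sentinel*: on pure-noise cohorts, the
honest in-fold pipeline must score at least 0.05 mean accuracy below a
deliberately leaky variant that selects features on the full dataset. This
is the empirical proof that the in-fold machinery actually prevents
selection bias, which is the methodological point of the design.

## Target aggregation and enrichment

`load_edge_lists()` consumes per-database miRNA-to-gene edge tables with
kappa-like confidence scores, applying inclusive per-database thresholds
(defaults 0.6, and 0.8 for the miRDB-style predictions) and collapsing
within-database duplicates to their maximal score. `aggregate_targets()`
then ranks each miRNA's candidate genes by *support* — the number of
distinct databases containing the pair — with ties broken by maximal score
and then gene identifier, and caps each miRNA at 50 genes. The cap is
applied after aggregation (capping first and truncating later provably
yields the same set under this ranking, which the tests assert).
`disease_target_sets()` tabulates the full Venn partition across diseases,
and `annotate_mesh()` joins genes against a disease-term vocabulary.

`hypergeom_enrichment()` tests each term by the two-sided hypergeometric
test: with `K` of `N` population genes annotated and `k` of `n` study genes
observed, the two-sided p is twice the smaller of `P(X >= k)` and
`P(X <= k)`, capped at one. Tail-doubling is a declared choice (the exact
two-sided rule of upstream enrichment servers is undocumented) and is
verified against direct pmf enumeration; note it is *conservative* — on
uniformly drawn study sets the `p < 0.05` rate sits below the nominal level,
which the calibration test checks as an upper bound. Multiplicity is handled
by the step-down Holm (sequentially rejective Bonferroni) procedure. Term
levels are shortest-path distances from the ontology root (a deterministic
and cheap semantics; ontologies with multiple parents use the minimum
depth), and `level_filter()` keeps levels 4–16 by default, the customary
window that drops both uselessly broad and overly specific terms.

## The synthetic cohort generator

`simulate_counts()` draws
$y_{gs} \sim \mathrm{NB}\!\left(L_s\, q_g(c_s),\ \phi\right)$ with per-sample
library sizes $L_s$ uniform on 1–5 million reads (forcing non-trivial
normalization), per-miRNA baseline abundances $2^{u_g}$ with $u_g$ uniform
on 0–12 log2 units (a ~3.6-decade dynamic range, a realistic figure for
serum small-RNA libraries; no public distributional estimate exists for
this matrix, so this is a declared fixture choice, not an estimate), and
per-condition renormalization so the $q_g$ sum to one in each group. A
configured fraction of miRNAs is truly differential with log2 fold-change
$\pm$`lfc_magnitude`, signs by fair coin — cohorts contain both over- and
under-expressed markers. Dispersion is a single shared $\phi$ by default
(`per_mirna_dispersion = TRUE` draws log-normal per-miRNA values). One
integer seed governs a single generator stream with a documented draw order,
so identical configurations are bit-for-bit reproducible. Defaults are 8
patients versus 22 controls.

What the generator does *not* emulate: sequencing artifacts (adapters,
UMIs, mapping multi-hits), compositional outliers such as haemolysis-driven
erythrocyte miRNA bursts, correlated miRNA families, or batch structure.
Passing tests on this generator therefore demonstrate the statistical
machinery is correct and calibrated under its stated model — not that any
particular real cohort will yield stable panels.

`simulate_edge_lists()` and `simulate_annotations()` provide the matching
fixtures for the target and enrichment stages, with planted multi-database
pairs and a tree ontology of known depths.

## Numerical choices and degenerate inputs

* Percentages are rounded half-away-from-zero at one decimal.
* A sample sharing no nonzero miRNA with the TMM reference gets factor 1
  with a warning; an all-zero sample is rejected.
* Constant expression rows Z-score to zero; zero-variance matrices are
  rejected by the PCA.
* MCC is 0 when any denominator factor vanishes; undefined
  sensitivity/specificity is `NA`, not 0.
* An empty filtered matrix is allowed but flagged with a warning.
* Non-converged GLM fits are handled by the underlying QL machinery;
  p-values are never fabricated.

## Problem sizes used in the tests

The shipped test and acceptance workloads use cohorts of 120–2,000 miRNAs
at the 8-vs-22 design (and 30-vs-30 for dispersion recovery), chosen so the
Monte-Carlo tolerances stated above are meaningful while the whole suite
remains quick to run on a laptop. The moment-level check of the generator
uses 10,000 replicate samples. All simulation tests fix their seeds and are
exactly reproducible.

## Known limitations

* Two-group designs only; no paired, blocked or multi-factor models.
* The classifier evaluates panels by LOOCV; it does not nest a second
  hyperparameter search, so kernel and cost are taken as fixed conventions.
* Kappa scores are consumed as given; the package does not compute them,
  nor does it query live target or ontology services.
* Aggregation ranking is support-first; with a single database it reduces
  to score ranking.
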