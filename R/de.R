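#' Counts per million
#'
#' Scales each column of a count matrix to counts per million reads. With a
#' normalization result the effective (TMM-scaled) library sizes are used;
#' otherwise the raw library sizes (column sums unless supplied).
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param norm optional [tmm_factors()] result; when given, CPM uses the
#'   effective library sizes.
#' @param lib_sizes optional per-sample totals overriding column sums.
#' @return numeric matrix of the same shape as `counts`.
#' @export
compute_cpm <- function(counts, norm = NULL, lib_sizes = NULL) {
  assert_count_matrix(counts)
  ls <- if (!is.null(norm)) {
    norm$effective_lib_sizes[colnames(counts)]
  } else if (!is.null(lib_sizes)) {
    lib_sizes
  } else {
    colSums(counts)
  }
  if (any(!is.finite(ls)) || any(ls <= 0))
    stopf("library sizes must be positive for all samples")
  t(t(counts) / ls) * 1e6
}

#' Filter lowly expressed features
#'
#' Retains features with at least `min_cpm` counts per million in at least
#' `min_libraries` samples, the standard abundance filter for small-RNA count
#' matrices. CPM is computed from raw library sizes (column sums), before any
#' normalization, since filtering feeds the normalization step. Comparison is
#' inclusive (`>=` on both the CPM value and the library count).
#'
#' @param counts feature x sample count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_libraries minimum number of samples meeting the threshold
#'   (default 2).
#' @return The row-subset count matrix. A warning is raised if no feature
#'   survives.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_libraries = 2) {
  assert_count_matrix(counts)
  if (min_cpm <= 0 || min_libraries <= 0)
    stopf("min_cpm and min_libraries must be positive")
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm >= min_cpm) >= min_libraries
  if (!any(keep)) warnf("no feature passed the expression filter")
  counts[keep, , drop = FALSE]
}

# Pairwise TMM scaling factor of one sample against a reference column:
# M-values (log2 ratio of proportions) and A-values (average log2 abundance)
# over features nonzero in both, double trim (30% on M, 5% on A), then a
# precision-weighted mean of the surviving M-values with delta-method inverse
# asymptotic variances as weights.
tmm_pair_factor <- function(obs, ref, lib_obs = sum(obs), lib_ref = sum(ref),
                            logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  if (!any(fin)) return(NA_real_)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes between-sample scaling factors correcting for RNA composition.
#' The reference is the sample whose upper-quartile CPM is closest to the
#' mean upper-quartile; each sample's factor is the precision-weighted mean
#' of its trimmed M-values against that reference (30% trim on M, 5% on A),
#' and the factors are re-centred so that their geometric mean is one.
#'
#' @param counts feature x sample count matrix (ideally already filtered).
#' @param lib_sizes optional per-sample totals overriding column sums.
#' @return A list of class `tmm_norm`: `factors` (named, geometric mean 1),
#'   `lib_sizes`, `effective_lib_sizes` (`lib_sizes * factors`), and
#'   `ref_sample`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least two samples")
  ls <- if (is.null(lib_sizes)) colSums(counts) else lib_sizes
  if (any(ls <= 0) || any(colSums(counts) == 0))
    stopf("every sample needs at least one nonzero count")

  # reference: upper-quartile (p = 0.75) of counts scaled by library size,
  # sample closest to the mean across samples
  f75 <- apply(counts, 2, stats::quantile, p = 0.75) / ls
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    val <- tmm_pair_factor(counts[, j], counts[, ref], ls[j], ls[ref])
    if (is.na(val)) {
      warnf("sample %s shares no nonzero features with the reference; factor set to 1",
            colnames(counts)[j])
      val <- 1
    }
    val
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f,
                 lib_sizes = stats::setNames(as.numeric(ls), colnames(counts)),
                 effective_lib_sizes = stats::setNames(as.numeric(ls) * f,
                                                       colnames(counts)),
                 ref_sample = colnames(counts)[ref]),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference:", x$ref_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Estimate negative-binomial and quasi-likelihood dispersions
#'
#' Fits the dispersion components required by the quasi-likelihood F-test for
#' a two-group design: a common dispersion (Cox-Reid adjusted profile
#' likelihood), an abundance trend, empirical-Bayes shrunk tagwise values,
#' and the quasi-likelihood dispersions with their prior and residual degrees
#' of freedom. The estimation is delegated to edgeR's `estimateDisp` and
#' `glmQLFit`.
#'
#' @param counts filtered feature x sample count matrix.
#' @param samples sample sheet with `sample_id` and `group` columns
#'   (`patient` / `control`).
#' @param norm a [tmm_factors()] result for these samples.
#' @param prior_df prior degrees of freedom for tagwise shrinkage toward the
#'   trend (default 10).
#' @return A list of class `dispersion_fit` with elements `common`, `trended`,
#'   `tagwise` (per feature), `df_prior`, `df_residual`, and the underlying
#'   edgeR QL `fit` object consumed by [ql_f_test()].
#' @export
fit_dispersions <- function(counts, samples, norm, prior_df = 10) {
  assert_count_matrix(counts)
  assert_sample_sheet(samples, counts)
  grp <- group_factor(samples, colnames(counts))
  if (nlevels(droplevels(grp)) < 2)
    stopf("both groups must be present")
  if (ncol(counts) - 2 < 1)
    stopf("too few residual degrees of freedom to estimate dispersion")
  y <- edgeR::DGEList(counts = counts, group = grp,
                      lib.size = as.numeric(norm$lib_sizes),
                      norm.factors = as.numeric(norm$factors))
  design <- stats::model.matrix(~grp)
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  fit <- edgeR::glmQLFit(y, design)
  structure(list(common = y$common.dispersion,
                 trended = y$trended.dispersion,
                 tagwise = y$tagwise.dispersion,
                 df_prior = fit$df.prior,
                 df_residual = fit$df.residual.zeros,
                 fit = fit),
            class = "dispersion_fit")
}

#' Quasi-likelihood F-test for two-group differential expression
#'
#' Tests each feature for a patient-vs-control difference under the
#' negative-binomial GLM with log link and log effective-library-size offset.
#' The statistic is the deviance drop scaled by the squeezed quasi-likelihood
#' dispersion and referred to an F distribution. Fold changes use a small
#' abundance prior so zero counts yield finite log2 fold-changes.
#'
#' @param dispersions a [fit_dispersions()] result.
#' @return data.frame of class `de_result`: `mirna_id`, `log2fc`, `logcpm`,
#'   `f`, `p_value`, `fdr` (Benjamini-Hochberg), ordered as the input counts.
#' @export
ql_f_test <- function(dispersions) {
  if (!inherits(dispersions, "dispersion_fit"))
    stopf("dispersions must come from fit_dispersions()")
  res <- edgeR::glmQLFTest(dispersions$fit, coef = 2)
  tab <- res$table
  out <- data.frame(mirna_id = rownames(tab),
                    log2fc = tab$logFC,
                    logcpm = tab$logCPM,
                    f = tab$F,
                    p_value = tab$PValue,
                    fdr = bh_fdr(tab$PValue),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Full differential-expression analysis of a count matrix
#'
#' Convenience pipeline: expression filter, TMM normalization, dispersion
#' estimation, quasi-likelihood F-test, BH adjustment.
#'
#' @inheritParams fit_dispersions
#' @param min_cpm,min_libraries passed to [filter_low_expression()].
#' @return A `de_result` data.frame (see [ql_f_test()]).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(200, frac_de = 0.1, seed = 11))
#' de <- de_analysis(sim$counts, sim$samples)
#' head(de[order(de$p_value), ])
de_analysis <- function(counts, samples, min_cpm = 1, min_libraries = 2,
                        prior_df = 10) {
  kept <- filter_low_expression(counts, min_cpm, min_libraries)
  norm <- tmm_factors(kept)
  disp <- fit_dispersions(kept, samples, norm, prior_df = prior_df)
  ql_f_test(disp)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' capped at one.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA/NaN are rejected.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  assert_probabilities(p)
  stats::p.adjust(p, method = "BH")
}

# Deterministic DE ordering: ascending p, then larger |log2FC|, then ID.
rank_de <- function(de) {
  de[order(de$p_value, -abs(de$log2fc), de$mirna_id), , drop = FALSE]
}

#' Summarize a differential-expression result
#'
#' Counts the features called significant at `p_value < p_thresh` and
#' `|log2FC| > lfc_thresh`, splits them into over- and under-expressed, and
#' reports the percentage at one decimal (half away from zero). Also callable
#' in reporting mode from bare totals, e.g. to recompute a published
#' percentage from its published counts.
#'
#' @param de a `de_result` data.frame, or `NULL` in reporting mode.
#' @param p_thresh,lfc_thresh significance thresholds (defaults 0.05 and 1).
#' @param n_tested,n_significant reporting mode: supply both totals instead
#'   of `de`.
#' @return A list of class `de_summary`: `n_tested`, `n_significant`,
#'   `percent_significant`, and (when computed from a table) `n_over`,
#'   `n_under`, `n_fdr_significant`.
#' @export
#' @examples
#' summarize_de(n_tested = 948, n_significant = 175)$percent_significant # 18.5
summarize_de <- function(de = NULL, p_thresh = 0.05, lfc_thresh = 1,
                         n_tested = NULL, n_significant = NULL) {
  if (is.null(de)) {
    if (is.null(n_tested) || is.null(n_significant))
      stopf("reporting mode needs both n_tested and n_significant")
    if (n_tested <= 0) stopf("n_tested must be positive")
    out <- list(n_tested = as.integer(n_tested),
                n_significant = as.integer(n_significant),
                percent_significant = round_half_up(100 * n_significant / n_tested, 1),
                n_over = NA_integer_, n_under = NA_integer_,
                n_fdr_significant = NA_integer_)
    class(out) <- "de_summary"
    return(out)
  }
  if (nrow(de) == 0) stopf("empty DE result")
  sig <- de$p_value < p_thresh & abs(de$log2fc) > lfc_thresh
  out <- list(n_tested = nrow(de),
              n_significant = sum(sig),
              percent_significant = round_half_up(100 * mean(sig), 1),
              n_over = sum(sig & de$log2fc > 0),
              n_under = sum(sig & de$log2fc < 0),
              n_fdr_significant = sum(de$fdr < 0.05))
  class(out) <- "de_summary"
  out
}

#' @export
print.de_summary <- function(x, ...) {
  cat(sprintf("%d of %d features significant (%.1f%%)",
              x$n_significant, x$n_tested, x$percent_significant))
  if (!is.na(x$n_over))
    cat(sprintf(" [%d over, %d under; %d at FDR < 0.05]",
                x$n_over, x$n_under, x$n_fdr_significant))
  cat("\n")
  invisible(x)
}

#' Volcano-plot significance classes
#'
#' Labels each feature `over` (p below threshold and log2FC above
#' `lfc_thresh`), `under` (p below threshold and log2FC below
#' `-lfc_thresh`), or `ns`.
#'
#' @inheritParams summarize_de
#' @return character vector aligned with the rows of `de`.
#' @export
volcano_classes <- function(de, p_thresh = 0.05, lfc_thresh = 1) {
  ifelse(de$p_value < p_thresh & de$log2fc > lfc_thresh, "over",
         ifelse(de$p_value < p_thresh & de$log2fc < -lfc_thresh, "under", "ns"))
}

#' Row-wise Z-score matrix
#'
#' Standardizes each row by subtracting the row mean and dividing by the
#' sample (n-1) standard deviation; constant rows map to all zeros. This is
#' the transformation behind expression heatmaps.
#'
#' @param x numeric matrix with at least two columns.
#' @return matrix of the same shape, each non-constant row with mean 0 and
#'   sd 1.
#' @export
zscore_matrix <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2)
    stopf("need a matrix with at least two columns")
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Percent variance explained by principal components
#'
#' Centred PCA over samples (columns of the expression matrix are samples,
#' treated as observations), returning the percentage of total variance
#' carried by each of the leading components in descending order.
#'
#' @param x features x samples numeric matrix.
#' @param n_components number of leading components to report.
#' @return numeric vector of percentages, length `n_components` (or fewer if
#'   the matrix rank is smaller).
#' @export
pca_variance <- function(x, n_components = 2) {
  if (!is.matrix(x) || ncol(x) < 2)
    stopf("need a matrix with at least two samples")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stopf("zero-variance input")
  pct <- 100 * v / sum(v)
  pct[seq_len(min(n_components, length(pct)))]
}
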