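#' Rank features inside a training fold
#'
#' Runs the full differential-expression pipeline (expression filter, TMM,
#' quasi-likelihood F-test) on the training samples only and returns the top
#' `k` features by ascending p-value, ties broken by larger absolute log2
#' fold-change and then feature identifier. Performing the selection inside
#' the fold is what keeps the downstream cross-validation honest.
#'
#' @param train_counts count matrix restricted to the training samples.
#' @param train_samples sample sheet rows for those samples.
#' @param k number of features to return.
#' @return character vector of feature identifiers, best first.
#' @export
rank_features_in_fold <- function(train_counts, train_samples, k) {
  if (k < 1) stopf("k must be at least 1")
  grp <- group_factor(train_samples, colnames(train_counts))
  if (nlevels(droplevels(grp)) < 2)
    stopf("both classes must be present in the training fold")
  de <- de_analysis(train_counts, train_samples)
  ranked <- rank_de(de)$mirna_id
  if (k > length(ranked)) {
    warnf("requested %d features but only %d available after filtering",
          k, length(ranked))
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}

# log2(CPM + 1) expression for classifier input
log_cpm <- function(counts, eff_lib_sizes) {
  log2(t(t(counts) / eff_lib_sizes) * 1e6 + 1)
}

# One LOOCV pass of fold-wise preprocessing that does not depend on the panel
# size: for each held-out sample, the in-fold DE ranking (or the deliberately
# leaky whole-data ranking) plus training / test expression on the fold's own
# normalization. Reused across panel sizes by sweep_panel_sizes().
loocv_fold_prep <- function(counts, samples, leaky = FALSE,
                            min_cpm = 1, min_libraries = 2) {
  assert_count_matrix(counts)
  assert_sample_sheet(samples, counts)
  grp <- group_factor(samples, colnames(counts))
  if (min(table(grp)) < 2) stopf("need at least two samples per class")

  leaky_rank <- NULL
  if (leaky) {
    de_all <- de_analysis(counts, samples, min_cpm, min_libraries)
    leaky_rank <- rank_de(de_all)$mirna_id
  }

  lapply(seq_len(ncol(counts)), function(i) {
    train <- counts[, -i, drop = FALSE]
    test_id <- colnames(counts)[i]
    train_samples <- samples[samples$sample_id != test_id, , drop = FALSE]
    if (nlevels(droplevels(group_factor(train_samples, colnames(train)))) < 2)
      stopf("class absent from training fold when holding out %s", test_id)

    kept <- filter_low_expression(train, min_cpm, min_libraries)
    norm <- tmm_factors(kept)
    ranking <- if (leaky) {
      intersect(leaky_rank, rownames(kept))
    } else {
      disp <- fit_dispersions(kept, train_samples, norm)
      rank_de(ql_f_test(disp))$mirna_id
    }

    # training-derived scaling for the held-out sample: pairwise TMM factor
    # against the training reference, centred by the training factors' own
    # centring constant
    ref <- norm$ref_sample
    raw <- vapply(colnames(kept), function(s)
      tmm_pair_factor(kept[, s], kept[, ref]), numeric(1))
    centring <- exp(mean(log(raw)))
    test_counts <- counts[rownames(kept), i]
    test_raw <- tmm_pair_factor(test_counts, kept[, ref],
                                sum(counts[, i]), sum(kept[, ref]))
    if (is.na(test_raw)) test_raw <- 1
    test_eff <- sum(counts[, i]) * test_raw / centring

    list(test_id = test_id,
         truth = as.character(samples$group[samples$sample_id == test_id]),
         ranking = ranking,
         train_expr = log_cpm(kept, norm$effective_lib_sizes),
         test_expr = log2(test_counts / test_eff * 1e6 + 1))
  })
}

# Train an SVM on standardized training expression for the selected features
# and score the held-out sample. Returns label + decision score with larger
# values favouring "patient".
svm_fold_predict <- function(prep, features, kernel = "radial", cost = 1) {
  x <- t(prep$train_expr[features, , drop = FALSE])
  y <- factor(prep$train_groups, levels = c("control", "patient"))
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- scale(x, center = mu, scale = sd)
  fit <- e1071::svm(xs, y, kernel = kernel, cost = cost,
                    gamma = 1 / ncol(xs), scale = FALSE)
  xt <- matrix((prep$test_expr[features] - mu) / sd, nrow = 1,
               dimnames = list(prep$test_id, features))
  pred <- stats::predict(fit, xt, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[1, 1]
  # e1071 reports the decision value for "first/second" in its column name;
  # flip so positive always means "patient"
  if (!grepl("^patient", colnames(dv)[1])) score <- -score
  list(label = as.character(pred[1]), score = score)
}

#' Leave-one-out cross-validated panel evaluation
#'
#' For each sample in turn: hold it out, select the top `panel_size` features
#' by in-fold differential expression, normalize the training fold and apply
#' the training-derived scaling to the held-out sample, train an SVM on the
#' standardized training expression, and predict the held-out label and
#' decision score. Fold predictions are pooled into confusion-matrix metrics
#' and a Mann-Whitney AUC.
#'
#' @param counts feature x sample count matrix.
#' @param samples sample sheet (`sample_id`, `group`).
#' @param panel_size number of features selected within each fold.
#' @param kernel,cost SVM kernel and cost (defaults: radial basis, cost 1,
#'   gamma `1/n_features`).
#' @param folds optional precomputed result of the internal fold preparation
#'   (used by [sweep_panel_sizes()] to avoid redundant in-fold DE runs).
#' @param leaky if `TRUE`, feature ranking uses the whole dataset including
#'   the held-out sample — a deliberately biased variant kept only as the
#'   comparison arm of the information-leakage sentinel; never use it for a
#'   real evaluation.
#' @return A list of class `loocv_result`: `metrics` (accuracy, sensitivity,
#'   specificity, mcc, auc), `confusion` (TP/FP/TN/FN with patient as the
#'   positive class), `fold_records` (one row per held-out sample: selected
#'   features, predicted label, decision score), `panel_size`.
#' @export
loocv_evaluate <- function(counts, samples, panel_size,
                           kernel = "radial", cost = 1, folds = NULL,
                           leaky = FALSE) {
  if (is.null(folds)) folds <- loocv_fold_prep(counts, samples, leaky = leaky)
  assert_sample_sheet(samples)

  records <- lapply(folds, function(prep) {
    features <- utils::head(prep$ranking, panel_size)
    prep$train_groups <- samples$group[match(colnames(prep$train_expr),
                                             samples$sample_id)]
    out <- svm_fold_predict(prep, features, kernel, cost)
    list(sample_id = prep$test_id, truth = prep$truth,
         features = features, predicted = out$label, score = out$score)
  })

  truth <- vapply(records, `[[`, character(1), "truth")
  predicted <- vapply(records, `[[`, character(1), "predicted")
  scores <- vapply(records, `[[`, numeric(1), "score")
  conf <- list(TP = sum(truth == "patient" & predicted == "patient"),
               FP = sum(truth == "control" & predicted == "patient"),
               TN = sum(truth == "control" & predicted == "control"),
               FN = sum(truth == "patient" & predicted == "control"))
  metrics <- confusion_metrics(conf)
  roc <- roc_auc(scores, truth == "patient")
  metrics$auc <- roc$auc

  fold_records <- data.frame(
    sample_id = vapply(records, `[[`, character(1), "sample_id"),
    truth = truth, predicted = predicted, score = scores,
    features = vapply(records, function(r) paste(r$features, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE)

  structure(list(metrics = metrics, confusion = conf,
                 fold_records = fold_records, roc = roc$points,
                 panel_size = panel_size),
            class = "loocv_result")
}

#' Panel-size sweep to accuracy saturation
#'
#' Evaluates [loocv_evaluate()] at increasing panel sizes, starting from
#' `start` (default six features, the conventional opening panel) and
#' stepping by `step`, stopping once `patience` consecutive sizes fail to
#' improve the best accuracy seen, or `max_size` is reached. The optimal size
#' is the smallest achieving the best accuracy; the pooled unique panel is
#' the union of features selected across folds at that size.
#'
#' @inheritParams loocv_evaluate
#' @param start first panel size evaluated (default 6).
#' @param step increment between sizes (default 1).
#' @param patience number of consecutive non-improving sizes tolerated before
#'   stopping (default 3).
#' @param max_size largest panel size to consider (default: number of
#'   features available in every fold, capped at 30).
#' @return A list of class `panel_sweep`: `trace` (data.frame of size and
#'   metrics per evaluated size), `optimal_size`, `pooled_unique_mirnas`,
#'   `best` (the `loocv_result` at the optimal size).
#' @export
sweep_panel_sizes <- function(counts, samples, start = 6, step = 1,
                              patience = 3, max_size = NULL,
                              kernel = "radial", cost = 1) {
  if (start < 1) stopf("start must be at least 1")
  folds <- loocv_fold_prep(counts, samples)
  avail <- min(vapply(folds, function(f) length(f$ranking), integer(1)))
  if (start > avail)
    stopf("start (%d) exceeds the %d features available in every fold",
          start, avail)
  if (is.null(max_size)) max_size <- min(avail, 30)
  max_size <- min(max_size, avail)

  sizes <- seq(start, max_size, by = step)
  evals <- list()
  best_acc <- -Inf
  stall <- 0
  trace <- NULL
  for (sz in sizes) {
    ev <- loocv_evaluate(counts, samples, sz, kernel, cost, folds = folds)
    evals[[as.character(sz)]] <- ev
    trace <- rbind(trace, data.frame(panel_size = sz,
                                     accuracy = ev$metrics$accuracy,
                                     sensitivity = ev$metrics$sensitivity,
                                     specificity = ev$metrics$specificity,
                                     mcc = ev$metrics$mcc,
                                     auc = ev$metrics$auc))
    if (ev$metrics$accuracy > best_acc + 1e-12) {
      best_acc <- ev$metrics$accuracy
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  optimal <- trace$panel_size[which(trace$accuracy >= best_acc - 1e-12)[1]]
  best <- evals[[as.character(optimal)]]
  pooled <- sort(unique(unlist(strsplit(best$fold_records$features, ";",
                                        fixed = TRUE))))
  structure(list(trace = trace, optimal_size = optimal,
                 pooled_unique_mirnas = pooled, best = best),
            class = "panel_sweep")
}

#' @export
print.panel_sweep <- function(x, ...) {
  cat(sprintf("Panel sweep: optimal size %d (accuracy %.3f, AUC %.3f); %d pooled unique features\n",
              x$optimal_size, x$best$metrics$accuracy, x$best$metrics$auc,
              length(x$pooled_unique_mirnas)))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Binary classification metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity, specificity and Matthews correlation
#' coefficient with the patient class as positive. When any factor of the
#' MCC denominator is zero the coefficient is reported as 0 (the usual
#' convention); an undefined sensitivity or specificity is reported as `NA`.
#'
#' @param conf list or vector with non-negative integer components `TP`,
#'   `FP`, `TN`, `FN`.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `mcc`.
#' @export
#' @examples
#' confusion_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))$mcc  # 14/24
confusion_metrics <- function(conf) {
  tp <- conf[["TP"]]; fp <- conf[["FP"]]; tn <- conf[["TN"]]; fn <- conf[["FN"]]
  if (any(c(tp, fp, tn, fn) < 0)) stopf("confusion counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stopf("empty confusion matrix")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

#' Mann-Whitney AUC and ROC points
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability (ties count one half), plus the ROC operating points at every
#' distinct score threshold.
#'
#' @param scores numeric decision scores, larger meaning more positive.
#' @param labels logical (or coercible) vector, `TRUE` for the positive
#'   class.
#' @return list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`, sorted from the strictest threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stopf("scores and labels must be equal-length and complete")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)

  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, vapply(thr, function(t) mean(scores[!labels] >= t),
                                      numeric(1))),
                    tpr = c(0, vapply(thr, function(t) mean(scores[labels] >= t),
                                      numeric(1))))
  list(auc = auc, points = pts)
}
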