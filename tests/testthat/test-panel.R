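test_that("confusion metrics follow their formulas and conventions", {
  perfect <- confusion_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  onesided <- confusion_metrics(list(TP = 0, FP = 0, TN = 7, FN = 3))
  expect_equal(onesided$mcc, 0)  # zero-denominator convention
  expect_equal(onesided$sensitivity, 0)
  nopos <- confusion_metrics(list(TP = 0, FP = 2, TN = 5, FN = 0))
  expect_true(is.na(nopos$sensitivity))

  mixed <- confusion_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(mixed$mcc, 14 / 24)
  expect_equal(mixed$accuracy, 0.8)
  expect_equal(mixed$sensitivity, 0.75)
  expect_equal(mixed$specificity, 5 / 6)
  expect_error(confusion_metrics(list(TP = -1, FP = 0, TN = 0, FN = 1)),
               "non-negative")
})

test_that("MCC is symmetric under simultaneous class swap", {
  set.seed(6)
  for (i in 1:20) {
    c0 <- as.list(setNames(sample(0:8, 4, replace = TRUE),
                           c("TP", "FP", "TN", "FN")))
    if (sum(unlist(c0)) == 0) next
    swapped <- list(TP = c0$TN, FP = c0$FN, TN = c0$TP, FN = c0$FP)
    expect_equal(confusion_metrics(c0)$mcc, confusion_metrics(swapped)$mcc)
  }
})

test_that("AUC equals exhaustive pair counting with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)

  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force some ties
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb))
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(3 * sc), lb)$auc, roc_auc(sc, lb)$auc)
  }
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- rnorm(40)
  lb <- runif(40) < 0.5
  got <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("ROC points step from (0,0) to (1,1) monotonically", {
  set.seed(30)
  sc <- rnorm(25)
  lb <- runif(25) < 0.4
  pts <- roc_auc(sc, lb)$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("in-fold ranking equals the sorted fold DE table", {
  sim <- simulate_counts(sim_config(120, frac_de = 0.1, dispersion = 0.15,
                                    n_patients = 5, n_controls = 7, seed = 14))
  de <- de_analysis(sim$counts, sim$samples)
  want <- de[order(de$p_value, -abs(de$log2fc), de$mirna_id), "mirna_id"]
  got_all <- suppressWarnings(
    rank_features_in_fold(sim$counts, sim$samples, k = 1e6))
  expect_identical(got_all, want)           # k > available: all, in order
  expect_setequal(got_all, de$mirna_id)     # a permutation of the tested set
  expect_identical(rank_features_in_fold(sim$counts, sim$samples, 5),
                   want[1:5])
})

test_that("one overwhelming planted feature is ranked first", {
  sim <- simulate_counts(sim_config(100, frac_de = 0.01, lfc_magnitude = 6,
                                    dispersion = 0.05, seed = 31))
  expect_identical(rank_features_in_fold(sim$counts, sim$samples, 1),
                   sim$truth$mirna_id)
})

test_that("LOOCV is perfect on a widely separable feature", {
  sim <- simulate_counts(sim_config(60, frac_de = 0, dispersion = 0.05,
                                    n_patients = 5, n_controls = 5, seed = 12))
  cnt <- sim$counts
  # plant an unmistakable marker
  pat <- sim$samples$group == "patient"
  cnt["mir-0001", ] <- ifelse(pat, 20000L, 50L)
  ev <- loocv_evaluate(cnt, sim$samples, panel_size = 1)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$metrics$mcc, 1)
  expect_equal(ev$metrics$auc, 1)
  expect_identical(nrow(ev$fold_records), ncol(cnt))
  expect_true(all(ev$fold_records$features == "mir-0001"))
})

test_that("LOOCV metrics are invariant to sample order", {
  sim <- simulate_counts(sim_config(80, frac_de = 0.1, dispersion = 0.1,
                                    n_patients = 4, n_controls = 6, seed = 18))
  ev1 <- loocv_evaluate(sim$counts, sim$samples, 4)
  set.seed(1)
  perm <- sample(ncol(sim$counts))
  ev2 <- loocv_evaluate(sim$counts[, perm],
                        sim$samples[perm, , drop = FALSE], 4)
  expect_equal(ev1$metrics, ev2$metrics)
  expect_identical(sort(ev1$fold_records$sample_id),
                   sort(ev2$fold_records$sample_id))
})

test_that("LOOCV rejects degenerate class layouts", {
  sim <- simulate_counts(sim_config(40, n_patients = 1, n_controls = 5, seed = 2))
  expect_error(loocv_evaluate(sim$counts, sim$samples, 3), "two samples per class")
})

test_that("panel sweep stops at saturation and prefers the smallest size", {
  # half the features carry an overwhelming signal, so every panel size is
  # perfect: immediate saturation at the opening size
  sim <- simulate_counts(sim_config(60, frac_de = 0.5, lfc_magnitude = 6,
                                    dispersion = 0.05,
                                    n_patients = 5, n_controls = 5, seed = 12))
  sw <- sweep_panel_sizes(sim$counts, sim$samples, start = 2, step = 1,
                          patience = 3, max_size = 12)
  # accuracy 1 at the opening size: stop after `patience` further sizes
  expect_equal(sw$optimal_size, 2)
  expect_identical(nrow(sw$trace), 1L + 3L)
  expect_equal(sw$trace$accuracy[1], 1)
  # monotone-flat trace: smallest size wins the tie
  expect_true(all(sw$trace$accuracy == 1))
  expect_error(sweep_panel_sizes(sim$counts, sim$samples, start = 1e5),
               "exceeds")
})
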