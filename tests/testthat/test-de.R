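test_that("CPM matches its definition elementwise", {
  m <- matrix(c(5L, 0L, 3L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- compute_cpm(m, lib_sizes = c(5e6, 1e6))
  expect_equal(cpm["a", "s1"], 1.0)
  expect_equal(cpm["b", ], c(s1 = 0, s2 = 0))

  r <- toy_counts(20, 6, seed = 2)
  cpm2 <- compute_cpm(r)
  brute <- r
  for (j in 1:6) brute[, j] <- r[, j] / sum(r[, j]) * 1e6
  expect_equal(cpm2, brute)
  expect_error(compute_cpm(r, lib_sizes = c(0, rep(1e6, 5))), "positive")
})

test_that("expression filter applies the CPM-in-enough-libraries rule", {
  # rows engineered to given CPM at libsize 1e6 per sample
  m <- rbind(drop2 = c(2, 0.5, 0.2), keep = c(1, 1, 0), zero = c(0, 0, 0),
             big = c(50, 60, 70))
  m <- round(m)
  storage.mode(m) <- "integer"
  filler <- matrix(as.integer(1e6 - colSums(m)), 1, 3)
  cnt <- rbind(m, filler)
  rownames(cnt) <- c(rownames(m), "filler")
  colnames(cnt) <- c("s1", "s2", "s3")
  kept <- filter_low_expression(cnt, min_cpm = 1, min_libraries = 2)
  expect_false("drop2" %in% rownames(kept))  # only one sample at >= 1 CPM
  expect_true("keep" %in% rownames(kept))    # boundary >= is inclusive
  expect_false("zero" %in% rownames(kept))
  expect_true("big" %in% rownames(kept))
  expect_identical(colnames(kept), colnames(cnt))
})

test_that("expression filter equals a brute-force row scan and is idempotent", {
  cnt <- toy_counts(60, 8, mu = 4, size = 1, seed = 5)
  kept <- filter_low_expression(cnt, 1, 2)
  cpm <- t(t(cnt) / colSums(cnt)) * 1e6
  manual <- rownames(cnt)[vapply(seq_len(nrow(cnt)), function(g)
    sum(cpm[g, ] >= 1) >= 2, logical(1))]
  expect_identical(rownames(kept), manual)
  # idempotent up to the library-size change caused by removing rows
  expect_true(all(rownames(filter_low_expression(kept, 1, 2)) %in%
                    rownames(kept)))
  ones <- matrix(1L, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_warning(filter_low_expression(ones, min_cpm = 1e6), "no feature")
})

test_that("TMM factors are unit for identical or depth-scaled libraries", {
  cnt <- toy_counts(50, 4, seed = 3)
  same <- cnt[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 4))

  depth <- cbind(s1 = cnt[, 1], s2 = 2L * cnt[, 1])
  expect_equal(unname(tmm_factors(depth)$factors), c(1, 1), tolerance = 1e-6)
})

test_that("TMM factors match the enumeration oracle and edgeR", {
  # 8-feature 3-sample toy checked against the hand-rolled oracle
  toy <- matrix(c(100L, 47L, 250L, 33L, 600L, 12L, 89L, 210L,
                  88L, 63L, 310L, 21L, 540L, 19L, 70L, 180L,
                  120L, 39L, 200L, 45L, 700L, 8L, 95L, 260L), 8, 3,
                dimnames = list(letters[1:8], c("s1", "s2", "s3")))
  res <- tmm_factors(toy)
  ls <- colSums(toy)
  f75 <- apply(toy, 2, quantile, 0.75) / ls
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- vapply(1:3, function(j) oracle_tmm_pair(toy[, j], toy[, ref]),
                numeric(1))
  expect_equal(unname(res$factors), raw / exp(mean(log(raw))), tolerance = 1e-10)

  # random matrix against edgeR's implementation
  r <- toy_counts(150, 7, seed = 9)
  expect_equal(unname(tmm_factors(r)$factors),
               edgeR::calcNormFactors(edgeR::DGEList(r),
                                      method = "TMM")$samples$norm.factors,
               tolerance = 1e-12)
})

test_that("TMM is sample-permutation equivariant with unit geometric mean", {
  r <- toy_counts(120, 6, seed = 13)
  f <- tmm_factors(r)$factors
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  perm <- c(4, 2, 6, 1, 5, 3)
  fp <- tmm_factors(r[, perm])$factors
  expect_equal(fp, f[perm], tolerance = 1e-12)
  # invariant to global depth scaling
  expect_equal(tmm_factors(3L * r)$factors, f, tolerance = 1e-10)
  expect_error(tmm_factors(r[, 1, drop = FALSE]), "two samples")
})

test_that("dispersion estimation recovers Poisson and shrinks to the trend", {
  simp <- simulate_counts(sim_config(200, frac_de = 0, dispersion = 0, seed = 3))
  kept <- filter_low_expression(simp$counts)
  fitp <- fit_dispersions(kept, simp$samples, tmm_factors(kept))
  expect_lte(fitp$common, 0.05)

  s <- simulate_counts(sim_config(150, frac_de = 0, dispersion = 0.3, seed = 2))
  k <- filter_low_expression(s$counts)
  inf_prior <- fit_dispersions(k, s$samples, tmm_factors(k), prior_df = 1e8)
  expect_equal(inf_prior$tagwise, inf_prior$trended, tolerance = 1e-8)
})

test_that("a feature with identical counts in every sample shows no signal", {
  col <- c(30L, 55L, 80L, 120L, 200L, 350L, 500L, 90L, 45L, 150L, 250L, 100L)
  cnt <- matrix(rep(col, 6), ncol = 6,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:6)))
  samples <- toy_samples(cnt, 3)
  de <- suppressWarnings(suppressMessages(de_analysis(cnt, samples)))
  expect_lt(max(abs(de$log2fc)), 1e-6)
  expect_gt(min(de$p_value), 0.5)
})

test_that("QLF p-value agrees with an exact NB likelihood-ratio oracle", {
  set.seed(9)
  base <- matrix(rnbinom(12 * 6, mu = 200, size = 10), 12, 6)
  set.seed(4)
  base[1, ] <- c(rpois(3, 300), rpois(3, 190))
  dimnames(base) <- list(sprintf("g%02d", 1:12), sprintf("s%d", 1:6))
  samples <- toy_samples(base, 3)
  kept <- filter_low_expression(base)
  norm <- tmm_factors(kept)
  disp <- fit_dispersions(kept, samples, norm)
  de <- ql_f_test(disp)
  p_qlf <- de$p_value[de$mirna_id == "g01"]

  phi <- disp$tagwise[rownames(kept) == "g01"]
  y <- kept["g01", ]
  off <- log(norm$effective_lib_sizes)
  x <- as.numeric(samples$group == "patient")
  nll0 <- function(b) -sum(dnbinom(y, mu = exp(b + off), size = 1 / phi,
                                   log = TRUE))
  nll1 <- function(par) -sum(dnbinom(y, mu = exp(par[1] + par[2] * x + off),
                                     size = 1 / phi, log = TRUE))
  o0 <- optimize(nll0, c(-30, 10))
  o1 <- optim(c(o0$minimum, 0), nll1)
  p_lr <- pchisq(2 * (o0$objective - o1$value), df = 1, lower.tail = FALSE)
  expect_gt(p_qlf / p_lr, 0.5)
  expect_lt(p_qlf / p_lr, 2)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("BH and Holm equal exhaustive evaluation for all lengths <= 6", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    p <- round(runif(n), 3)
    if (rep %% 4 == 0 && n > 1) p[2] <- p[1]  # exercise ties
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(holm_adjust(p), oracle_holm(p), tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p))
  }
})

test_that("DE summary reproduces printed percentages from printed counts", {
  expect_equal(summarize_de(n_tested = 948, n_significant = 175)$percent_significant, 18.5)
  expect_equal(summarize_de(n_tested = 1014, n_significant = 179)$percent_significant, 17.7)
  expect_equal(summarize_de(n_tested = 100, n_significant = 0)$percent_significant, 0)
  expect_error(summarize_de(n_tested = 0, n_significant = 0), "positive")

  de <- data.frame(mirna_id = c("a", "b", "c", "d"),
                   log2fc = c(2, -3, 0.5, 1.2),
                   logcpm = 5, f = 1,
                   p_value = c(0.01, 0.02, 0.001, 0.2),
                   fdr = c(0.02, 0.04, 0.004, 0.2))
  s <- summarize_de(de)
  expect_identical(s$n_significant, 2L + 0L)
  expect_identical(s$n_over + s$n_under, s$n_significant)
  expect_equal(s$percent_significant, 50)
  expect_identical(s$n_fdr_significant, 3L)
})

test_that("volcano classes equal the defining predicate", {
  de <- data.frame(mirna_id = letters[1:4],
                   log2fc = c(2, -0.5, -1.4, 1.01),
                   p_value = c(0.01, 0.01, 0.03, 0.2))
  expect_identical(volcano_classes(de), c("over", "ns", "under", "ns"))
  set.seed(1)
  rnd <- data.frame(mirna_id = sprintf("m%d", 1:200),
                    log2fc = rnorm(200, sd = 2),
                    p_value = runif(200))
  got <- volcano_classes(rnd)
  want <- ifelse(rnd$p_value < 0.05 & rnd$log2fc > 1, "over",
                 ifelse(rnd$p_value < 0.05 & rnd$log2fc < -1, "under", "ns"))
  expect_identical(got, want)
})

test_that("Z-score rows have mean zero and unit sd; constant rows map to zero", {
  expect_equal(unname(zscore_matrix(matrix(c(1, 2, 3), 1))[1, ]), c(-1, 0, 1))
  expect_equal(unname(zscore_matrix(matrix(5, 1, 3))[1, ]), c(0, 0, 0))
  set.seed(2)
  m <- matrix(rnorm(80), 10, 8)
  z <- zscore_matrix(m)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_error(zscore_matrix(matrix(1, 3, 1)), "two columns")
})

test_that("PCA variance percentages match the eigen-decomposition", {
  rank1 <- outer(c(1, 2, 3), c(1, 2, 3, 4))
  expect_equal(pca_variance(rank1, 1), 100)
  sym <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(pca_variance(sym, 2), c(50, 50))
  set.seed(3)
  m <- matrix(rnorm(80), 10, 8)
  ev <- eigen(cov(t(m)))$values
  expect_equal(pca_variance(m, 3), 100 * ev[1:3] / sum(ev), tolerance = 1e-8)
  expect_error(pca_variance(matrix(1, 4, 3)), "zero-variance")
})
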