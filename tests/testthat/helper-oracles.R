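# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition (enumeration, direct formulas, BFS) rather than sharing
# any code path with the implementation under test.

# Pairwise TMM factor by explicit enumeration: M/A values over features
# nonzero in both samples, trimming by order statistics, inverse-variance
# weighted mean of the surviving M values.
oracle_tmm_pair <- function(obs, ref) {
  nO <- sum(obs); nR <- sum(ref)
  both <- obs > 0 & ref > 0
  o <- obs[both]; r <- ref[both]
  M <- log2((o / nO) / (r / nR))
  A <- (log2(o / nO) + log2(r / nR)) / 2
  w <- 1 / ((nO - o) / (nO * o) + (nR - r) / (nR * r))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  dropM <- floor(n * 0.3)
  dropA <- floor(n * 0.05)
  keepM <- order(M)[(dropM + 1):(n - dropM)]
  keepA <- order(A)[(dropA + 1):(n - dropA)]
  sel <- intersect(keepM, keepA)
  2^(sum(M[sel] * w[sel]) / sum(w[sel]))
}

# BH adjusted p-values straight from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[js] / js))
  }, numeric(1))
}

# Holm adjusted p-values straight from the step-down definition.
oracle_holm <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    i <- max(which(ps <= pi + 1e-15))
    min(1, max((m - seq_len(i) + 1) * ps[seq_len(i)]))
  }, numeric(1))
}

# AUC by exhaustive pair counting (ties worth one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Two-sided hypergeometric p by direct pmf enumeration with choose().
oracle_hyper <- function(N, K, n, k) {
  pmf <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  supp <- max(0, n - (N - K)):min(K, n)
  over <- sum(vapply(supp[supp >= k], pmf, numeric(1)))
  under <- sum(vapply(supp[supp <= k], pmf, numeric(1)))
  min(1, 2 * min(over, under))
}

# Ontology levels by hand-rolled breadth-first search from the roots.
oracle_bfs_levels <- function(edges, roots) {
  children <- split(edges$child_id, edges$parent_id)
  lev <- stats::setNames(rep(0L, length(roots)), roots)
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(lev))
    if (length(nxt)) lev[nxt] <- d
    frontier <- nxt
  }
  lev
}

# Small deterministic count fixture.
toy_counts <- function(n_feat = 20, n_samp = 6, mu = 80, size = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_feat * n_samp, mu = mu, size = size),
              n_feat, n_samp,
              dimnames = list(sprintf("g%03d", seq_len(n_feat)),
                              sprintf("s%d", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}

toy_samples <- function(counts, n_patients = ncol(counts) %/% 2) {
  n <- ncol(counts)
  data.frame(sample_id = colnames(counts),
             group = c(rep("patient", n_patients),
                       rep("control", n - n_patients)),
             disease = "toy", stringsAsFactors = FALSE)
}
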