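#' Two-sided hypergeometric term enrichment
#'
#' Tests each annotation term for over- or under-representation of a study
#' gene set within a population. For a term annotating `K` of the `N`
#' population genes, with `k` of the `n` study genes annotated, the
#' over-representation tail is `P(X >= k)` and the under-representation tail
#' `P(X <= k)` under `X ~ Hypergeometric(N, K, n)`; the two-sided p-value is
#' the doubled smaller tail, capped at one. Fold enrichment is
#' `observed / expected` with `expected = K * n / N`. Adjusted p-values use
#' the step-down (Holm) procedure.
#'
#' @param study_genes character vector; must be a subset of the population.
#' @param annotation data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; restricted to the population before testing.
#' @param population_genes character vector of background gene identifiers.
#' @return data.frame of class `enrichment_result`, one row per term with a
#'   positive population count: `term_id`, `term_name`, `observed`,
#'   `expected`, `fold_enrichment`, `log10_fold_enrichment`, `direction`
#'   (`enriched` / `depleted` / `none`), `p_raw`, `p_adj`; sorted by `p_adj`
#'   then `p_raw`.
#' @export
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"), term_id = "T1")
#' hypergeom_enrichment(c("g1", "g2"), ann, paste0("g", 1:10))
hypergeom_enrichment <- function(study_genes, annotation, population_genes) {
  population_genes <- unique(as.character(population_genes))
  study_genes <- unique(as.character(study_genes))
  if (length(study_genes) == 0) stopf("study gene set is empty")
  if (!all(study_genes %in% population_genes))
    stopf("study genes must be a subset of the population")
  need <- c("gene_id", "term_id")
  if (!all(need %in% names(annotation)))
    stopf("annotation must have columns %s", paste(need, collapse = ", "))
  ann <- annotation[annotation$gene_id %in% population_genes, , drop = FALSE]
  ann <- ann[!duplicated(paste(ann$gene_id, ann$term_id, sep = "\r")), ,
             drop = FALSE]
  if (nrow(ann) == 0) stopf("no annotation overlaps the population")

  N <- length(population_genes)
  n <- length(study_genes)
  terms <- split(ann$gene_id, ann$term_id)
  term_names <- if ("term_name" %in% names(ann)) {
    tn <- tapply(as.character(ann$term_name), ann$term_id, `[`, 1)
    as.character(tn[names(terms)])
  } else names(terms)

  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(study_genes %in% g), integer(1))
  over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  p_raw <- pmin(1, 2 * pmin(over, under))
  expected <- K * n / N
  fold <- k / expected
  out <- data.frame(term_id = names(terms),
                    term_name = term_names,
                    observed = as.integer(k),
                    expected = expected,
                    fold_enrichment = fold,
                    log10_fold_enrichment = ifelse(fold > 0, log10(fold), NA_real_),
                    direction = ifelse(k > expected, "enriched",
                                       ifelse(k < expected, "depleted", "none")),
                    p_raw = p_raw,
                    p_adj = holm_adjust(p_raw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Step-down (Holm) adjusted p-values
#'
#' The sequentially rejective Bonferroni procedure: sort p-values ascending,
#' multiply the i-th smallest by `m - i + 1`, enforce monotonicity by a
#' running maximum, cap at one, and restore the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA/NaN rejected.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  assert_probabilities(p)
  stats::p.adjust(p, method = "holm")
}

#' Filter terms by ontology level
#'
#' Computes each term's level as its shortest-path distance from the ontology
#' root (root = level 0) over the parent/child edge list, and retains terms
#' whose level lies within `[min_level, max_level]` — the customary way of
#' discarding uselessly broad (shallow) and overly specific (deep) terms.
#'
#' @param terms character vector of term identifiers to filter.
#' @param ontology_edges data.frame with columns `child_id`, `parent_id`;
#'   must be acyclic.
#' @param min_level,max_level inclusive level bounds (defaults 4 and 16).
#' @param roots optional explicit root identifiers; by default every node
#'   that never appears as a child.
#' @return character vector: the subset of `terms` with a defined level in
#'   range. Terms absent from the ontology are dropped.
#' @export
level_filter <- function(terms, ontology_edges, min_level = 4, max_level = 16,
                         roots = NULL) {
  need <- c("child_id", "parent_id")
  if (!all(need %in% names(ontology_edges)))
    stopf("ontology edges must have columns %s", paste(need, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ontology_edges$parent_id, to = ontology_edges$child_id),
    directed = TRUE)
  if (!igraph::is_dag(g)) stopf("ontology contains a cycle")
  if (is.null(roots)) {
    roots <- setdiff(unique(ontology_edges$parent_id),
                     unique(ontology_edges$child_id))
  }
  roots <- intersect(roots, igraph::V(g)$name)
  if (length(roots) == 0) stopf("no root found in the ontology")
  d <- igraph::distances(g, v = roots, mode = "out")
  lev <- apply(d, 2, min)
  known <- intersect(terms, names(lev))
  known[is.finite(lev[known]) & lev[known] >= min_level & lev[known] <= max_level]
}

# exposed for tests / reporting: the level of every term
ontology_levels <- function(ontology_edges, roots = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = ontology_edges$parent_id, to = ontology_edges$child_id),
    directed = TRUE)
  if (!igraph::is_dag(g)) stopf("ontology contains a cycle")
  if (is.null(roots)) {
    roots <- setdiff(unique(ontology_edges$parent_id),
                     unique(ontology_edges$child_id))
  }
  d <- igraph::distances(g, v = roots, mode = "out")
  apply(d, 2, min)
}
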