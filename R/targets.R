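#' Default per-database kappa-score thresholds
#'
#' Edge-confidence thresholds conventionally applied when loading miRNA
#' target edge lists from the four common prediction/validation sources:
#' 0.6 for the microRNA.org-style predictions, validated miRTarBase and
#' miRecords lists, 0.8 for the miRDB predictions.
#'
#' @return named numeric vector of thresholds.
#' @export
default_kappa_thresholds <- function() {
  c(CluePedia = 0.6, miRDB = 0.8, miRTarBase = 0.6, miRecords = 0.6)
}

#' Load and threshold miRNA-to-gene target edge lists
#'
#' Reads one edge table per source database (TSV files or in-memory
#' data.frames with columns `mirna_id`, `gene_id`, `score`, `source_db`),
#' drops edges whose score falls below their database's kappa threshold
#' (inclusive: `score >= threshold` is kept), and collapses duplicate
#' (miRNA, gene) records within a database keeping the maximal score.
#'
#' @param edge_lists list of data.frames, or character vector of TSV paths.
#' @param thresholds named numeric vector of per-database thresholds (see
#'   [default_kappa_thresholds()]).
#' @param default_threshold fallback for databases absent from `thresholds`;
#'   if `NULL` (default) an unknown database is an error.
#' @return data.frame of retained edges (`mirna_id`, `gene_id`, `score`,
#'   `source_db`).
#' @export
load_edge_lists <- function(edge_lists, thresholds = default_kappa_thresholds(),
                            default_threshold = NULL) {
  if (is.character(edge_lists)) {
    edge_lists <- lapply(edge_lists, utils::read.delim,
                         stringsAsFactors = FALSE)
  }
  need <- c("mirna_id", "gene_id", "score", "source_db")
  edges <- do.call(rbind, lapply(edge_lists, function(df) {
    if (!all(need %in% names(df)))
      stopf("edge list must have columns %s", paste(need, collapse = ", "))
    df[, need]
  }))
  if (is.null(edges) || nrow(edges) == 0) stopf("no edges supplied")
  if (any(edges$score < 0 | edges$score > 1))
    stopf("edge scores must lie in [0, 1]")

  dbs <- unique(edges$source_db)
  thr <- vapply(dbs, function(db) {
    if (db %in% names(thresholds)) return(thresholds[[db]])
    if (!is.null(default_threshold)) return(default_threshold)
    stopf("no kappa threshold for database '%s' and no default given", db)
  }, numeric(1))
  names(thr) <- dbs

  edges <- edges[edges$score >= thr[edges$source_db], , drop = FALSE]
  key <- paste(edges$source_db, edges$mirna_id, edges$gene_id, sep = "\r")
  mx <- tapply(edges$score, key, max)
  out <- edges[!duplicated(key), , drop = FALSE]
  out$score <- as.numeric(mx[paste(out$source_db, out$mirna_id, out$gene_id,
                                   sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Aggregate target edges across databases into ranked predictions
#'
#' Collapses (miRNA, gene) pairs over source databases: the pair's support is
#' the number of distinct databases containing it, its score the maximum seen.
#' Within each miRNA, pairs are ranked by support (descending), then maximal
#' score (descending), then gene identifier, and only the top `cap` genes per
#' miRNA are retained — interactions recovered by several independent sources
#' outrank single-source predictions.
#'
#' @param edges thresholded edges from [load_edge_lists()].
#' @param cap maximum genes retained per miRNA (default 50).
#' @return data.frame (`mirna_id`, `gene_id`, `support`, `max_score`,
#'   `rank`), ranks 1..n within each miRNA without gaps.
#' @export
aggregate_targets <- function(edges, cap = 50) {
  if (is.null(edges) || nrow(edges) == 0) stopf("no edges to aggregate")
  if (cap < 1) stopf("cap must be at least 1")
  key <- paste(edges$mirna_id, edges$gene_id, sep = "\r")
  support <- tapply(edges$source_db, key, function(d) length(unique(d)))
  max_score <- tapply(edges$score, key, max)
  first <- !duplicated(key)
  agg <- data.frame(mirna_id = edges$mirna_id[first],
                    gene_id = edges$gene_id[first],
                    support = as.integer(support[key[first]]),
                    max_score = as.numeric(max_score[key[first]]),
                    stringsAsFactors = FALSE)
  parts <- lapply(split(agg, agg$mirna_id), function(df) {
    df <- df[order(-df$support, -df$max_score, df$gene_id), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df[df$rank <= cap, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-disease target-set partition (Venn cells)
#'
#' Given one predicted target gene set per disease, tabulates every Venn cell
#' (membership pattern) and derives the counts usually reported: genes unique
#' to each disease, genes shared by all, and genes found in at least two.
#'
#' @param sets named list (length >= 2) of character vectors of gene IDs, or
#'   of [aggregate_targets()] tables (the `gene_id` column is used).
#' @return list with `cells` (named list: membership pattern such as
#'   `"A&B"` -> genes), `unique_per_set`, `in_all`, `in_two_or_more`,
#'   `pairwise` (matrix of pairwise intersection sizes), `union_size`.
#' @export
disease_target_sets <- function(sets) {
  if (length(sets) < 2) stopf("need at least two diseases")
  sets <- lapply(sets, function(s) {
    if (is.data.frame(s)) s <- s$gene_id
    unique(as.character(s))
  })
  if (all(lengths(sets) == 0)) stopf("all target sets are empty")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]

  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  cells <- split(genes, pattern)

  n_in <- rowSums(member)
  unique_per_set <- lapply(names(sets), function(nm)
    genes[member[, nm] & n_in == 1])
  names(unique_per_set) <- names(sets)
  pairwise <- outer(names(sets), names(sets),
                    Vectorize(function(a, b) length(intersect(sets[[a]], sets[[b]]))))
  dimnames(pairwise) <- list(names(sets), names(sets))

  list(cells = cells,
       unique_per_set = unique_per_set,
       in_all = genes[n_in == length(sets)],
       in_two_or_more = genes[n_in >= 2],
       pairwise = pairwise,
       union_size = length(genes))
}

#' Annotate genes with disease vocabulary terms
#'
#' Inner join of a gene set against a (gene, term) annotation table such as
#' MeSH disease headings, optionally restricted to terms matching a filter
#' (regular expression or explicit term vector). An empty result is valid.
#'
#' @param genes character vector of gene identifiers.
#' @param gene_to_term data.frame with columns `gene_id` and `term`.
#' @param term_filter `NULL` (keep all), a single regular expression matched
#'   against terms, or a character vector (length > 1) of exact terms.
#' @return list with `by_term` (term -> genes) and `by_gene` (gene -> terms);
#'   both empty when nothing matches.
#' @export
annotate_mesh <- function(genes, gene_to_term, term_filter = NULL) {
  need <- c("gene_id", "term")
  if (!all(need %in% names(gene_to_term)))
    stopf("annotation table must have columns %s", paste(need, collapse = ", "))
  hit <- gene_to_term[gene_to_term$gene_id %in% genes, , drop = FALSE]
  if (!is.null(term_filter)) {
    keep <- if (length(term_filter) == 1) {
      grepl(term_filter, hit$term)
    } else {
      hit$term %in% term_filter
    }
    hit <- hit[keep, , drop = FALSE]
  }
  list(by_term = lapply(split(hit$gene_id, hit$term), unique),
       by_gene = lapply(split(hit$term, hit$gene_id), unique))
}
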