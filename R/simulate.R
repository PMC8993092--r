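#' Simulation configuration for synthetic serum small-RNA counts
#'
#' Bundles and validates the parameters of the negative-binomial count
#' simulator. Defaults mirror the study design the pipeline targets: eight
#' patients per disease versus twenty-two age- and gender-matched healthy
#' controls, with library sizes varying uniformly between one and five
#' million reads so that between-sample normalization is never trivial.
#'
#' @param n_mirnas number of miRNAs (rows) to simulate.
#' @param n_patients number of patient samples (default 8).
#' @param n_controls number of control samples (default 22).
#' @param frac_de fraction of miRNAs that are truly differential, in `[0, 1]`.
#' @param lfc_magnitude absolute log2 fold-change given to each true-DE miRNA
#'   (sign drawn by fair coin).
#' @param dispersion negative-binomial dispersion `phi`; the count variance is
#'   `mu + phi * mu^2`. A single shared value by default; see
#'   `per_mirna_dispersion`.
#' @param per_mirna_dispersion if `TRUE`, per-miRNA dispersions are drawn from
#'   a log-normal centred on `dispersion` (sdlog 0.5) instead of being shared.
#' @param libsize_range length-2 vector; per-sample library sizes are drawn
#'   uniformly on this range.
#' @param baseline_logmean_range length-2 vector; per-miRNA baseline relative
#'   abundances are `2^u` with `u` uniform on this range, then normalized to
#'   sum to one. The default spans ~3.6 decades, a realistic dynamic range for
#'   serum small-RNA libraries.
#' @param seed integer seed governing every random draw.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(n_mirnas,
                       n_patients = 8,
                       n_controls = 22,
                       frac_de = 0,
                       lfc_magnitude = 2,
                       dispersion = 0.2,
                       per_mirna_dispersion = FALSE,
                       libsize_range = c(1e6, 5e6),
                       baseline_logmean_range = c(0, 12),
                       seed = 1L) {
  if (n_mirnas < 1 || n_patients < 1 || n_controls < 1)
    stopf("n_mirnas, n_patients and n_controls must be positive")
  if (n_patients + n_controls < 4)
    stopf("need at least 4 samples in total")
  if (!is.numeric(frac_de) || frac_de < 0 || frac_de > 1)
    stopf("frac_de must lie in [0, 1]")
  if (lfc_magnitude <= 0) stopf("lfc_magnitude must be positive")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2])
    stopf("libsize_range must be a positive pair with low <= high")
  if (length(baseline_logmean_range) != 2 ||
      baseline_logmean_range[1] > baseline_logmean_range[2])
    stopf("baseline_logmean_range must be a pair with low <= high")
  structure(list(
    n_mirnas = as.integer(n_mirnas),
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    frac_de = frac_de,
    lfc_magnitude = lfc_magnitude,
    dispersion = dispersion,
    per_mirna_dispersion = isTRUE(per_mirna_dispersion),
    libsize_range = as.numeric(libsize_range),
    baseline_logmean_range = as.numeric(baseline_logmean_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a negative-binomial miRNA count matrix with planted signal
#'
#' Generates counts `y[g, s] ~ NB(mean = L_s * q_g(condition_s), phi)` where
#' `L_s` is the sample's library size and `q_g` the miRNA's relative abundance
#' in that condition; true-DE miRNAs have their patient-side abundance
#' multiplied by `2^lfc` before per-condition renormalization, with the sign
#' of `lfc` a fair coin. The same seed reproduces the same dataset
#' bit-for-bit.
#'
#' Draw order under the single seeded stream: (1) per-sample library sizes,
#' patients then controls; (2) per-miRNA baseline log2 abundances; (3) the
#' true-DE subset; (4) their fold-change signs; (5) per-miRNA dispersions when
#' `per_mirna_dispersion = TRUE`; (6) counts, column by column.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{counts}{integer matrix, miRNAs x samples.}
#'     \item{samples}{sample sheet data.frame (`sample_id`, `group`,
#'       `disease`).}
#'     \item{truth}{data.frame of truly differential miRNAs (`mirna_id`,
#'       `log2fc`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_mirnas = 50, frac_de = 0.1, seed = 7))
#' dim(sim$counts)
#' sim$truth
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("config must be created with sim_config()")
  cfg <- config
  n <- cfg$n_patients + cfg$n_controls
  set.seed(cfg$seed)

  lib_sizes <- round(stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2]))
  u <- stats::runif(cfg$n_mirnas, cfg$baseline_logmean_range[1],
                    cfg$baseline_logmean_range[2])
  base_abund <- 2^u

  n_de <- round(cfg$frac_de * cfg$n_mirnas)
  mirna_ids <- sprintf("mir-%04d", seq_len(cfg$n_mirnas))
  de_idx <- if (n_de > 0) sort(sample.int(cfg$n_mirnas, n_de)) else integer(0)
  lfc <- numeric(cfg$n_mirnas)
  if (n_de > 0) {
    signs <- ifelse(stats::runif(n_de) < 0.5, -1, 1)
    lfc[de_idx] <- signs * cfg$lfc_magnitude
  }
  phi <- if (cfg$per_mirna_dispersion) {
    stats::rlnorm(cfg$n_mirnas, meanlog = log(cfg$dispersion), sdlog = 0.5)
  } else {
    rep(cfg$dispersion, cfg$n_mirnas)
  }

  # Per-condition relative abundances, each normalized to sum to one.
  q_control <- base_abund / sum(base_abund)
  abund_pat <- base_abund * 2^lfc
  q_patient <- abund_pat / sum(abund_pat)

  sample_ids <- c(sprintf("P%02d", seq_len(cfg$n_patients)),
                  sprintf("C%02d", seq_len(cfg$n_controls)))
  group <- c(rep("patient", cfg$n_patients), rep("control", cfg$n_controls))

  counts <- matrix(0L, cfg$n_mirnas, n, dimnames = list(mirna_ids, sample_ids))
  for (s in seq_len(n)) {
    mu <- lib_sizes[s] * (if (group[s] == "patient") q_patient else q_control)
    counts[, s] <- if (cfg$dispersion == 0 && !cfg$per_mirna_dispersion) {
      stats::rpois(cfg$n_mirnas, mu)
    } else {
      stats::rnbinom(cfg$n_mirnas, mu = mu, size = 1 / phi)
    }
  }
  storage.mode(counts) <- "integer"

  samples <- data.frame(sample_id = sample_ids, group = group,
                        disease = ifelse(group == "patient", "disease", "healthy"),
                        stringsAsFactors = FALSE)
  truth <- data.frame(mirna_id = mirna_ids[de_idx], log2fc = lfc[de_idx],
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, truth = truth,
                 config = cfg, lib_sizes = stats::setNames(lib_sizes, sample_ids)),
            class = "sim_dataset")
}

#' Simulate a null dataset (no differential miRNAs)
#'
#' Convenience wrapper around [simulate_counts()] with `frac_de` forced to
#' zero; useful for type-I-error calibration of the downstream tests.
#'
#' @inheritParams simulate_counts
#' @return A `sim_dataset` whose `truth` table is empty.
#' @export
simulate_null <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("config must be created with sim_config()")
  config$frac_de <- 0
  simulate_counts(config)
}

#' Simulate per-database miRNA-to-gene target edge lists
#'
#' Produces one edge table per source database, each row a
#' (miRNA, gene, score, database) record with scores uniform on `[0, 1]`.
#' A configurable number of planted pairs is inserted into a fixed number of
#' databases with near-maximal scores, so that support-based ranking after
#' aggregation is testable against a known answer.
#'
#' @param n_mirnas,n_genes size of the bipartite candidate space.
#' @param n_databases number of source databases (must be >= 1).
#' @param density probability that a given (miRNA, gene) pair appears in a
#'   given database, in `(0, 1]`.
#' @param n_planted number of pairs planted in `planted_support` databases.
#' @param planted_support how many databases each planted pair appears in
#'   (default: all of them).
#' @param seed integer seed.
#' @return A list with `edges` (one data.frame per database, columns
#'   `mirna_id`, `gene_id`, `score`, `source_db`) and `planted` (data.frame of
#'   planted pairs).
#' @export
simulate_edge_lists <- function(n_mirnas, n_genes, n_databases,
                                density = 0.1, n_planted = 0,
                                planted_support = n_databases, seed = 1L) {
  if (n_databases < 1) stopf("need at least one database")
  if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
  if (planted_support > n_databases)
    stopf("planted_support cannot exceed n_databases")
  set.seed(as.integer(seed))

  mirnas <- sprintf("mir-%04d", seq_len(n_mirnas))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  dbs <- sprintf("db%d", seq_len(n_databases))

  pairs <- expand.grid(mirna_id = mirnas, gene_id = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  edges <- lapply(dbs, function(db) {
    keep <- stats::runif(nrow(pairs)) < density
    df <- pairs[keep, , drop = FALSE]
    df$score <- stats::runif(nrow(df))
    df$source_db <- db
    rownames(df) <- NULL
    df
  })
  names(edges) <- dbs

  planted <- data.frame(mirna_id = character(0), gene_id = character(0))
  if (n_planted > 0) {
    pick <- sample.int(nrow(pairs), n_planted)
    planted <- pairs[pick, , drop = FALSE]
    rownames(planted) <- NULL
    for (i in seq_len(n_planted)) {
      in_dbs <- sample.int(n_databases, planted_support)
      for (d in in_dbs) {
        row <- data.frame(mirna_id = planted$mirna_id[i],
                          gene_id = planted$gene_id[i],
                          score = stats::runif(1, 0.9, 1),
                          source_db = dbs[d], stringsAsFactors = FALSE)
        edges[[d]] <- rbind(edges[[d]], row)
      }
    }
    # collapse any duplicates the random stage may also have drawn (keep max)
    edges <- lapply(edges, function(df) {
      key <- paste(df$mirna_id, df$gene_id, sep = "\r")
      mx <- tapply(df$score, key, max)
      out <- df[!duplicated(key), , drop = FALSE]
      out$score <- as.numeric(mx[paste(out$mirna_id, out$gene_id, sep = "\r")])
      rownames(out) <- NULL
      out
    })
  }
  list(edges = edges, planted = planted)
}

#' Simulate gene-to-term annotations and a term ontology
#'
#' Fixture generator for the enrichment stage of a fully synthetic run: draws
#' a random gene-to-term annotation table plus a rooted tree-like ontology
#' edge list whose term levels are known by construction.
#'
#' @param genes character vector of gene identifiers (the population).
#' @param n_terms number of annotation terms.
#' @param genes_per_term expected number of genes annotated to each term.
#' @param max_depth depth of the generated ontology below the root.
#' @param seed integer seed.
#' @return A list with `annotation` (data.frame: `gene_id`, `term_id`,
#'   `term_name`), `ontology` (data.frame: `child_id`, `parent_id`) and
#'   `root` (the root term identifier).
#' @export
simulate_annotations <- function(genes, n_terms = 50, genes_per_term = 20,
                                 max_depth = 8, seed = 1L) {
  if (n_terms < 1) stopf("need at least one term")
  set.seed(as.integer(seed))
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  ann <- do.call(rbind, lapply(terms, function(tm) {
    k <- min(length(genes), max(1, stats::rpois(1, genes_per_term)))
    data.frame(gene_id = sample(genes, k), term_id = tm,
               term_name = paste("process", tm), stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  # tree: each term's parent is the root or an earlier term at depth < max_depth
  root <- "TERM:ROOT"
  depth <- integer(n_terms)
  parent <- character(n_terms)
  for (i in seq_len(n_terms)) {
    cand <- which(depth[seq_len(i - 1)] < max_depth)
    if (i == 1 || length(cand) == 0 || stats::runif(1) < 0.15) {
      parent[i] <- root
      depth[i] <- 1
    } else {
      j <- cand[sample.int(length(cand), 1)]
      parent[i] <- terms[j]
      depth[i] <- depth[j] + 1
    }
  }
  ontology <- data.frame(child_id = terms, parent_id = parent,
                         stringsAsFactors = FALSE)
  list(annotation = ann, ontology = ontology, root = root,
       depth = stats::setNames(depth, terms))
}
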