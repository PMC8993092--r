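#' Read a count matrix from TSV
#'
#' First column = feature identifiers, header = sample identifiers. Values
#' must be non-negative integers; duplicate identifiers, ragged rows and
#' negative or non-numeric entries are rejected with context.
#'
#' @param path TSV file path.
#' @return integer matrix, features x samples.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stopf("count file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("count file needs an ID column plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate feature identifiers: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp))
    stopf("duplicate sample columns: %s",
          paste(unique(samp[duplicated(samp)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- samp[!vapply(df[-1], is.numeric, logical(1))]
    stopf("non-numeric counts in column(s): %s", paste(bad, collapse = ", "))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stopf("negative count at feature '%s', sample '%s'",
          ids[bad[1]], samp[bad[2]])
  }
  if (any(m != round(m))) warnf("non-integer counts were rounded")
  m <- round(m)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, samp)
  m
}

#' Write a count matrix to TSV
#'
#' @param counts feature x sample matrix.
#' @param path output path.
#' @param id_column name for the identifier column (default `mirna_id`).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_column = "mirna_id") {
  assert_count_matrix(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Expects columns `sample_id`, `group` (`patient` / `control`) and
#' optionally `disease`.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_sample_sheet(df)
  df
}

#' Small-RNA class composition report
#'
#' Summarizes, per sample group, the percentage of total counts attributed to
#' each small-RNA class (miRNA, lncRNA, tRNA, snoRNA, snRNA, other). Features
#' missing from the biotype table are assigned `other`. Percentages within a
#' group sum to 100.
#'
#' @param counts feature x sample count matrix.
#' @param biotypes data.frame with columns `feature_id`, `class`.
#' @param grouping named character vector or factor mapping each sample to a
#'   group (e.g. its disease label).
#' @return data.frame (`group`, `class`, `percent`).
#' @export
composition_report <- function(counts, biotypes,
                               grouping = stats::setNames(rep("all", ncol(counts)),
                                                          colnames(counts))) {
  assert_count_matrix(counts)
  vocab <- c("miRNA", "lncRNA", "tRNA", "snoRNA", "snRNA", "other")
  if (!all(c("feature_id", "class") %in% names(biotypes)))
    stopf("biotypes must have columns feature_id, class")
  bad <- setdiff(unique(biotypes$class), vocab)
  if (length(bad))
    stopf("unknown small-RNA class label(s): %s", paste(bad, collapse = ", "))
  cls <- biotypes$class[match(rownames(counts), biotypes$feature_id)]
  cls[is.na(cls)] <- "other"
  grouping <- grouping[colnames(counts)]
  if (anyNA(grouping)) stopf("grouping must cover every sample")

  out <- do.call(rbind, lapply(unique(as.character(grouping)), function(g) {
    sub <- counts[, grouping == g, drop = FALSE]
    tot <- sum(sub)
    if (tot == 0) stopf("group '%s' has no counts", g)
    per_class <- tapply(rowSums(sub), factor(cls, levels = vocab), sum,
                        default = 0)
    data.frame(group = g, class = vocab,
               percent = 100 * as.numeric(per_class) / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in study order — simulate (or read) counts,
#' small-RNA composition, differential expression, panel-size sweep, target
#' aggregation, term enrichment — writing every stage's tables plus a run
#' manifest (parameters, seed, input checksums, output files) to the output
#' directory. Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' The configuration may be a named list, or a path to a YAML/JSON file with
#' the same structure. Recognized entries:
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{integer seed recorded in the manifest and used by the
#'     simulation stages (default 1).}
#'   \item{counts, samples}{paths to count matrix / sample sheet TSVs; if
#'     absent and `simulate` is given, data is simulated.}
#'   \item{simulate}{list of [sim_config()] arguments.}
#'   \item{biotypes}{optional path to a biotype TSV (`feature_id`, `class`)
#'     for the composition stage.}
#'   \item{de}{list: `p_thresh`, `lfc_thresh`, `min_cpm`, `min_libraries`.}
#'   \item{panel}{list passed to [sweep_panel_sizes()] (`start`, `step`,
#'     `patience`, `max_size`, `kernel`, `cost`); set to `NULL` to skip.}
#'   \item{targets}{list: `edge_files` (TSV paths) or `simulate_edges`
#'     (arguments to [simulate_edge_lists()]), `thresholds`, `cap`.}
#'   \item{enrichment}{list: `annotation` / `ontology` TSV paths or
#'     `simulate_annotations` arguments, plus `min_level`, `max_level`.}
#' }
#'
#' @param config named list or YAML/JSON file path.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$out_dir)) stopf("config must name an out_dir")
  for (p in c(config$counts, config$samples, config$biotypes,
              config$targets$edge_files, config$enrichment$annotation,
              config$enrichment$ontology)) {
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(config$out_dir, name)
  }
  stage <- "input"
  res <- tryCatch({
    # --- counts ---------------------------------------------------------
    if (!is.null(config$counts)) {
      counts <- read_count_matrix(config$counts)
      samples <- read_sample_sheet(config$samples)
      truth <- NULL
    } else if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim_args <- config$simulate
      sim_args$seed <- if (is.null(sim_args$seed)) seed else sim_args$seed
      sim <- simulate_counts(do.call(sim_config, sim_args))
      counts <- sim$counts
      samples <- sim$samples
      truth <- sim$truth
      write_count_matrix(counts, emit("counts.tsv"))
      utils::write.table(samples, emit("samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(truth, emit("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      stopf("config must provide either counts+samples paths or a simulate block")
    }

    # --- composition ----------------------------------------------------
    if (!is.null(config$biotypes)) {
      stage <- "composition"
      biotypes <- utils::read.delim(config$biotypes, stringsAsFactors = FALSE)
      grouping <- stats::setNames(
        samples$disease[match(colnames(counts), samples$sample_id)],
        colnames(counts))
      comp <- composition_report(counts, biotypes, grouping)
      utils::write.table(comp, emit("composition.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    # --- differential expression ---------------------------------------
    stage <- "de"
    de_cfg <- config$de
    de <- de_analysis(counts, samples,
                      min_cpm = de_cfg$min_cpm %||% 1,
                      min_libraries = de_cfg$min_libraries %||% 2)
    p_thresh <- de_cfg$p_thresh %||% 0.05
    lfc_thresh <- de_cfg$lfc_thresh %||% 1
    de_out <- rank_de(de)
    utils::write.table(de_out, emit("de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summ <- summarize_de(de, p_thresh, lfc_thresh)
    jsonlite::write_json(unclass(summ), emit("de_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    volc <- data.frame(mirna_id = de$mirna_id, log2fc = de$log2fc,
                       p_value = de$p_value,
                       class = volcano_classes(de, p_thresh, lfc_thresh))
    utils::write.table(volc, emit("volcano.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    kept <- filter_low_expression(counts, de_cfg$min_cpm %||% 1,
                                  de_cfg$min_libraries %||% 2)
    norm <- tmm_factors(kept)
    z <- zscore_matrix(log_cpm(kept, norm$effective_lib_sizes))
    utils::write.table(
      data.frame(mirna_id = rownames(z), z, check.names = FALSE),
      emit("zscores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

    # --- panel classifier ----------------------------------------------
    sweep <- NULL
    if (!isFALSE(config$panel)) {
      stage <- "panel"
      pc <- config$panel
      sweep <- sweep_panel_sizes(counts, samples,
                                 start = pc$start %||% 6,
                                 step = pc$step %||% 1,
                                 patience = pc$patience %||% 3,
                                 max_size = pc$max_size,
                                 kernel = pc$kernel %||% "radial",
                                 cost = pc$cost %||% 1)
      utils::write.table(sweep$trace, emit("panel_trace.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(sweep$best$fold_records, emit("fold_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(sweep$pooled_unique_mirnas, emit("pooled_panel.tsv"))
      jsonlite::write_json(c(list(optimal_size = sweep$optimal_size),
                             sweep$best$metrics),
                           emit("panel_metrics.json"), auto_unbox = TRUE,
                           digits = NA)
      utils::write.table(sweep$best$roc, emit("roc_points.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    # --- target aggregation --------------------------------------------
    agg <- NULL
    if (!is.null(config$targets)) {
      stage <- "targets"
      tc <- config$targets
      raw_edges <- if (!is.null(tc$edge_files)) {
        load_edge_lists(tc$edge_files,
                        thresholds = unlist(tc$thresholds) %||%
                          default_kappa_thresholds(),
                        default_threshold = tc$default_threshold)
      } else if (!is.null(tc$simulate_edges)) {
        se <- tc$simulate_edges
        se$seed <- se$seed %||% (seed + 1)
        sim_edges <- do.call(simulate_edge_lists, se)
        load_edge_lists(sim_edges$edges, thresholds = numeric(0),
                        default_threshold = tc$default_threshold %||% 0.6)
      } else {
        stopf("targets block needs edge_files or simulate_edges")
      }
      agg <- aggregate_targets(raw_edges, cap = tc$cap %||% 50)
      utils::write.table(agg, emit("aggregated_targets.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    # --- enrichment -----------------------------------------------------
    if (!is.null(config$enrichment)) {
      stage <- "enrichment"
      ec <- config$enrichment
      if (!is.null(ec$annotation)) {
        ann <- utils::read.delim(ec$annotation, stringsAsFactors = FALSE)
        ont <- if (!is.null(ec$ontology))
          utils::read.delim(ec$ontology, stringsAsFactors = FALSE)
      } else {
        if (is.null(agg)) stopf("enrichment on simulated annotations needs a targets stage")
        sa <- ec$simulate_annotations %||% list()
        sa$genes <- unique(agg$gene_id)
        sa$seed <- sa$seed %||% (seed + 2)
        gen <- do.call(simulate_annotations, sa)
        ann <- gen$annotation
        ont <- gen$ontology
      }
      population <- unique(ann$gene_id)
      study <- if (!is.null(agg)) intersect(unique(agg$gene_id), population)
               else population
      study <- utils::head(study, max(1, length(population) %/% 4))
      enr <- hypergeom_enrichment(study, ann, population)
      if (!is.null(ont)) {
        keep <- level_filter(enr$term_id, ont,
                             min_level = ec$min_level %||% 4,
                             max_level = ec$max_level %||% 16)
        enr <- enr[enr$term_id %in% keep, , drop = FALSE]
      }
      utils::write.table(enr, emit("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    inputs <- c(config$counts, config$samples, config$biotypes,
                config$targets$edge_files, config$enrichment$annotation,
                config$enrichment$ontology)
    manifest <- list(
      package = "panelmiR",
      version = as.character(utils::packageVersion("panelmiR")),
      seed = seed,
      parameters = config[setdiff(names(config), "out_dir")],
      input_checksums = if (length(inputs))
        as.list(tools::md5sum(unlist(inputs))) else list(),
      outputs = outputs,
      output_checksums = as.list(stats::setNames(
        tools::md5sum(file.path(config$out_dir, outputs)), outputs)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
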