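# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals. base::round() rounds half to
# even, which would misreport printed percentages that land exactly on a .x5.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate feature identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers in count matrix")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts contain negative values")
  invisible(counts)
}

assert_sample_sheet <- function(samples, counts = NULL) {
  need <- c("sample_id", "group")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stopf("sample sheet must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(samples$group), c("patient", "control"))
  if (length(bad))
    stopf("sample sheet group must be 'patient' or 'control' (found: %s)",
          paste(bad, collapse = ", "))
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), samples$sample_id)
    if (length(missing))
      stopf("samples missing from sample sheet: %s",
            paste(missing, collapse = ", "))
  }
  invisible(samples)
}

# Two-level group factor with control as the reference level, so the fitted
# group coefficient is patient-vs-control.
group_factor <- function(samples, sample_ids) {
  g <- samples$group[match(sample_ids, samples$sample_id)]
  factor(g, levels = c("control", "patient"))
}

assert_probabilities <- function(p, what = "p-values") {
  if (!is.numeric(p) || length(p) == 0)
    stopf("%s must be a non-empty numeric vector", what)
  if (anyNA(p)) stopf("%s contain NA/NaN", what)
  if (any(p < 0 | p > 1)) stopf("%s outside [0, 1]", what)
  invisible(p)
}
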