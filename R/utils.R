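# Internal helpers shared across modules.

# Decimal rounding with ties away from zero (matches how percentages such as
# 99.63% are conventionally reported). `num/den` is rounded at `digits`
# decimals; passing the ratio as two numbers keeps integer-valued numerators
# exact in double arithmetic.
round_half_up_frac <- function(num, den, digits = 2) {
  p <- 10^digits
  floor(num * p / den + 0.5) / p
}

round_half_up <- function(x, digits = 2) {
  round_half_up_frac(x, 1, digits)
}

# Coerce a genes-x-samples tibble (first column = gene identifier, remaining
# columns = numeric sample values) to a named numeric matrix.
as_assay_matrix <- function(x, what = "expression") {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort(sprintf("%s input must be a data frame with a gene column plus >= 1 sample column", what))
  }
  genes <- as.character(x[[1]])
  if (anyNA(genes) || any(genes == "")) {
    abort(sprintf("%s input has missing gene identifiers", what))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(sprintf(
      "%s input has duplicated gene identifiers (%s%s); collapse probes first",
      what, paste(head(dup, 3), collapse = ", "), if (length(dup) > 3) ", ..." else ""
    ))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s values must all be numeric", what))
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

as_assay_tibble <- function(m, id_col = "gene") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

# Align an assay matrix with a clinical table on shared samples, preserving
# the matrix column order. Errors when the overlap is empty.
align_samples <- function(m, clinical, sample_col = "sample_id") {
  if (!sample_col %in% names(clinical)) {
    abort(sprintf("clinical table lacks a '%s' column", sample_col))
  }
  common <- intersect(colnames(m), clinical[[sample_col]])
  if (length(common) == 0) {
    abort("no samples shared between the assay matrix and the clinical table")
  }
  list(
    matrix = m[, common, drop = FALSE],
    clinical = clinical[match(common, clinical[[sample_col]]), , drop = FALSE]
  )
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_event_flags <- function(event, what = "event") {
  bad <- !is.na(event) & !event %in% c(0, 1)
  if (any(bad)) {
    abort(sprintf("%s flags must be 0 or 1 (found: %s)", what,
                  paste(unique(event[bad]), collapse = ", ")))
  }
  invisible(event)
}

check_nonneg_time <- function(time, what = "time") {
  bad <- !is.na(time) & time < 0
  if (any(bad)) abort(sprintf("%s contains negative values", what))
  invisible(time)
}
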