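#' Read a genes-by-samples expression matrix
#'
#' Reads a tab- or comma-separated matrix whose header row holds sample
#' identifiers and whose first column holds gene (or probe) identifiers.
#' Because downstream classification uses only within-sample orderings, the
#' measurement units (FPKM, microarray intensity, log-intensity) are
#' irrelevant and are never rescaled.
#'
#' When `probe_map` is supplied, rows are treated as probe-level measurements:
#' probes mapping to the same gene are collapsed to their arithmetic mean
#' (computed per sample, ignoring missing cells), and probes absent from the
#' map are dropped with a message reporting the count.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   extension (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param probe_map Optional data frame with columns `probe` and `gene`.
#' @param sep Optional field delimiter override.
#' @param na Strings interpreted as missing values.
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample. Missing cells are kept as `NA` (REO votes involving them abstain;
#'   nothing is imputed).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tS1\tS2", "p1\t2\t4", "p2\t6\t8"), tf)
#' read_expression(tf, probe_map = data.frame(probe = c("p1", "p2"), gene = "G"))
read_expression <- function(path, probe_map = NULL, sep = NULL, na = c("", "NA", "NaN")) {
  tbl <- read_matrix_file(path, sep = sep, na = na, what = "expression")
  if (!is.null(probe_map)) {
    tbl <- collapse_probes(tbl, probe_map)
  }
  validate_expression(tbl)
  tbl
}

#' Read a genes-by-samples methylation beta-value matrix
#'
#' Same layout as [read_expression()]; additionally enforces that every finite
#' value lies in `[0, 1]` (beta values are methylated-fraction estimates).
#'
#' @inheritParams read_expression
#' @return A tibble with a `gene` column followed by numeric beta columns.
#' @export
read_methylation <- function(path, sep = NULL, na = c("", "NA", "NaN")) {
  tbl <- read_matrix_file(path, sep = sep, na = na, what = "methylation")
  m <- as_assay_matrix(tbl, "methylation")
  bad <- is.finite(m) & (m < 0 | m > 1)
  if (any(bad)) {
    abort(sprintf("methylation beta values must lie in [0, 1]; %d value(s) outside", sum(bad)))
  }
  tbl
}

# Shared matrix-file reader: character-first parsing so a non-numeric cell can
# be reported by row/column rather than silently coerced to NA.
read_matrix_file <- function(path, sep = NULL, na = c("", "NA", "NaN"), what = "matrix") {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = na, quote = "\"",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort(sprintf("%s file '%s' has no sample columns", what, path))
  ids <- names(raw)[-1]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate sample IDs in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  vals <- lapply(names(raw)[-1], function(cn) {
    v <- raw[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in %s file at row '%s', column '%s'",
                    v[bad[1]], what, raw[[1]][bad[1]], cn))
    }
    num
  })
  names(vals) <- ids
  dplyr::bind_cols(tibble::tibble(gene = as.character(raw[[1]])), tibble::as_tibble(vals))
}

validate_expression <- function(tbl) {
  m <- as_assay_matrix(tbl, "expression")
  all_missing <- rowSums(is.finite(m)) == 0
  if (any(all_missing)) {
    abort(sprintf("expression rows with no finite values: %s",
                  paste(head(rownames(m)[all_missing], 5), collapse = ", ")))
  }
  # a sample supports an REO only with >= 2 finite values; a single-gene
  # matrix is still a valid (if unclassifiable) read, so require >= 1 there
  thin <- colSums(is.finite(m)) < min(2L, nrow(m))
  if (any(thin)) {
    abort(sprintf("sample(s) with < 2 finite values (no REO defined): %s",
                  paste(head(colnames(m)[thin], 5), collapse = ", ")))
  }
  invisible(tbl)
}

#' Collapse probe-level rows to gene level by arithmetic mean
#'
#' Rows mapping to the same gene are averaged per sample, ignoring missing
#' cells (a cell where every contributing probe is missing stays `NA`).
#' Probes absent from `probe_map` are dropped and their count reported.
#' The operation is invariant to input row order and idempotent.
#'
#' @param expr Probe-level tibble (first column = probe ID).
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @return Gene-level tibble (first column `gene`).
#' @export
collapse_probes <- function(expr, probe_map) {
  require_columns(probe_map, c("probe", "gene"), "probe_map")
  if (anyDuplicated(probe_map$probe)) abort("probe_map has duplicated probe entries")
  probes <- as.character(expr[[1]])
  idx <- match(probes, probe_map$probe)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(sprintf("collapse_probes: dropped %d unmapped probe(s)", dropped))
  }
  keep <- !is.na(idx)
  if (!any(keep)) abort("no probes map to any gene")
  m <- as.matrix(expr[keep, -1, drop = FALSE])
  storage.mode(m) <- "double"
  gene <- as.character(probe_map$gene[idx[keep]])
  # Per-cell mean over available probes: sum of non-missing / count non-missing.
  sums <- rowsum(ifelse(is.na(m), 0, m), gene)
  cnts <- rowsum((!is.na(m)) * 1, gene)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out <- out[order(rownames(out)), , drop = FALSE]
  as_assay_tibble(out, "gene")
}

#' Read a per-sample clinical table
#'
#' Reads survival endpoints (overall survival `os_time`/`os_event`,
#' disease-free survival `dfs_time`/`dfs_event`) and covariates (stage, grade,
#' age, gender). `event = 1` marks an observed event at `*_time`; `event = 0`
#' marks right-censoring. Survival-time units are carried as metadata
#' (attribute `time_unit`) and never converted.
#'
#' Tumour grade is harmonised to a binary scale with [harmonize_grade()]:
#' under a three-level system grade 1 maps to `"low"`, grade 3 to `"high"`,
#' and grade 2 to `"excluded"` (such samples are dropped from grade-adjusted
#' analyses to avoid the ambiguity of the middle grade); a two-level system
#' passes `"low"`/`"high"` through.
#'
#' @param path TSV/CSV file, one row per sample.
#' @param grade_system `"two_level"` or `"three_level"`.
#' @param col_map Optional named character vector renaming file columns to the
#'   standard names, e.g. `c(sample_id = "Patient.ID", os_time = "OS.months")`.
#' @param sep,na As in [read_expression()].
#' @param time_unit Unit label stored as an attribute (default `"months"`).
#' @return A tibble with standard columns plus `grade_binary`.
#' @export
read_clinical <- function(path, grade_system = c("two_level", "three_level"),
                          col_map = NULL, sep = NULL,
                          na = c("", "NA", "[Not Available]"),
                          time_unit = "months") {
  grade_system <- match.arg(grade_system)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    na.strings = na, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort(sprintf("col_map column '%s' not found in '%s'", col_map[[std]], path))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  require_columns(raw, c("sample_id", "os_time", "os_event"), "clinical table")
  tbl <- tibble::as_tibble(raw)
  tbl$os_time <- as.numeric(tbl$os_time)
  tbl$os_event <- as.numeric(tbl$os_event)
  check_nonneg_time(tbl$os_time, "os_time")
  check_event_flags(tbl$os_event, "os_event")
  if ("dfs_time" %in% names(tbl)) {
    tbl$dfs_time <- as.numeric(tbl$dfs_time)
    tbl$dfs_event <- as.numeric(tbl$dfs_event)
    check_nonneg_time(tbl$dfs_time, "dfs_time")
    check_event_flags(tbl$dfs_event, "dfs_event")
  }
  if ("age" %in% names(tbl)) tbl$age <- as.numeric(tbl$age)
  tbl <- harmonize_grade(tbl, grade_system)
  attr(tbl, "time_unit") <- time_unit
  tbl
}

#' Harmonise tumour grade to a binary scale
#'
#' Three-level grading (grade 1/2/3) is mapped to `low`/`excluded`/`high`:
#' the extreme grades anchor the binary scale and the ambiguous middle grade
#' is excluded from grade-adjusted analyses. Two-level grading
#' (`"low"`/`"high"`) passes through. Unrecognised labels become `NA`.
#'
#' @param clinical Data frame with a `grade` column (absent: `grade_binary`
#'   is filled with `NA`).
#' @param grade_system `"two_level"` or `"three_level"`.
#' @return The input with a `grade_binary` column
#'   (`"low"`, `"high"`, `"excluded"`, or `NA`).
#' @export
harmonize_grade <- function(clinical, grade_system = c("two_level", "three_level")) {
  grade_system <- match.arg(grade_system)
  if (!"grade" %in% names(clinical)) {
    clinical$grade_binary <- NA_character_
    return(clinical)
  }
  g <- tolower(trimws(as.character(clinical$grade)))
  g <- gsub("^(grade|g)\\s*", "", g)
  clinical$grade_binary <- if (grade_system == "three_level") {
    dplyr::case_when(
      g %in% c("1", "i") ~ "low",
      g %in% c("2", "ii") ~ "excluded",
      g %in% c("3", "iii") ~ "high",
      .default = NA_character_
    )
  } else {
    dplyr::case_when(
      g %in% c("low", "lg") ~ "low",
      g %in% c("high", "hg") ~ "high",
      .default = NA_character_
    )
  }
  clinical
}
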