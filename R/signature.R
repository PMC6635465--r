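#' Construct a gene-pair signature
#'
#' A signature is an ordered list of gene pairs, each carrying a risk
#' orientation: the within-sample ordering (`"A_lt_B"` means
#' \eqn{E_A < E_B}) that votes for high recurrence risk. A sample is
#' classified by counting pairs whose observed relative expression ordering
#' (REO) matches their risk orientation ([classify_cohort()]): at least
#' `vote_threshold_high` risk votes puts the sample in the high-risk group;
#' an optional `vote_threshold_highest` defines a third, highest-risk tier.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` and optionally
#'   `risk_orientation` (`"A_lt_B"`, default, or `"A_gt_B"`), `beta`
#'   (Cox log-hazard of the risk ordering) and `c_index` (the pair's
#'   individual concordance index, in `[0.5, 1]`).
#' @param vote_threshold_high Votes needed for the high-risk call; defaults
#'   to `ceiling(nrow(pairs) / 2)` ("at least half of the pairs").
#' @param vote_threshold_highest Optional votes needed for the highest-risk
#'   tier; must exceed `vote_threshold_high`.
#' @param meta Optional named list of provenance metadata (discovery policy,
#'   ensemble C-index, ...).
#' @return An object of class `gene_pair_signature`.
#' @export
#' @examples
#' sig <- gene_pair_signature(
#'   data.frame(gene_a = c("G1", "G3"), gene_b = c("G2", "G4"))
#' )
#' sig
gene_pair_signature <- function(pairs, vote_threshold_high = NULL,
                                vote_threshold_highest = NULL, meta = list()) {
  pairs <- tibble::as_tibble(pairs)
  require_columns(pairs, c("gene_a", "gene_b"), "signature pairs")
  if (nrow(pairs) == 0) abort("a signature needs at least one gene pair")
  if (!"risk_orientation" %in% names(pairs)) pairs$risk_orientation <- "A_lt_B"
  if (!"beta" %in% names(pairs)) pairs$beta <- NA_real_
  if (!"c_index" %in% names(pairs)) pairs$c_index <- NA_real_
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (any(pairs$gene_a == pairs$gene_b)) {
    abort("gene_a and gene_b must differ within every pair")
  }
  if (!all(pairs$risk_orientation %in% c("A_lt_B", "A_gt_B"))) {
    abort("risk_orientation must be 'A_lt_B' or 'A_gt_B'")
  }
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate gene pair(s): %s",
                  paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", ")))
  }
  ok_c <- is.na(pairs$c_index) | (pairs$c_index >= 0.5 & pairs$c_index <= 1)
  if (!all(ok_c)) abort("pair c_index values must lie in [0.5, 1]")
  n <- nrow(pairs)
  vote_threshold_high <- vote_threshold_high %||% ceiling(n / 2)
  if (vote_threshold_high < 1 || vote_threshold_high > n) {
    abort("vote_threshold_high must lie in [1, number of pairs]")
  }
  if (!is.null(vote_threshold_highest)) {
    if (vote_threshold_highest <= vote_threshold_high || vote_threshold_highest > n) {
      abort("vote_threshold_highest must exceed vote_threshold_high and not exceed the pair count")
    }
  }
  structure(
    list(
      pairs = pairs[, c("gene_a", "gene_b", "risk_orientation", "beta", "c_index")],
      vote_threshold_high = as.integer(vote_threshold_high),
      vote_threshold_highest = if (is.null(vote_threshold_highest)) NULL else as.integer(vote_threshold_highest),
      meta = meta
    ),
    class = "gene_pair_signature"
  )
}

#' @export
print.gene_pair_signature <- function(x, ...) {
  cat(sprintf("<gene_pair_signature: %d pairs, high-risk >= %d votes%s>\n",
              nrow(x$pairs), x$vote_threshold_high,
              if (!is.null(x$vote_threshold_highest))
                sprintf(", highest-risk >= %d", x$vote_threshold_highest) else ""))
  print(x$pairs, ...)
  if (!is.null(x$meta$ensemble_c_index)) {
    cat(sprintf("ensemble C-index: %.3f\n", x$meta$ensemble_c_index))
  }
  invisible(x)
}

#' @export
length.gene_pair_signature <- function(x) nrow(x$pairs)

#' @rdname gene_pair_signature
#' @param x A `gene_pair_signature`.
#' @param ... Unused.
#' @method tidy gene_pair_signature
#' @export
tidy.gene_pair_signature <- function(x, ...) x$pairs

#' @rdname gene_pair_signature
#' @method glance gene_pair_signature
#' @export
glance.gene_pair_signature <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    vote_threshold_high = x$vote_threshold_high,
    vote_threshold_highest = x$vote_threshold_highest %||% NA_integer_,
    ensemble_c_index = x$meta$ensemble_c_index %||% NA_real_,
    policy = x$meta$policy %||% NA_character_
  )
}

#' Read or write a gene-pair signature
#'
#' The native serialisation is JSON with explicit field names (self-describing
#' and diff-friendly); a two-plus-column TSV (`gene_a`, `gene_b`, optional
#' `risk_orientation`, `beta`, `c_index`) is accepted for interoperability.
#' `read_signature(write_signature(sig, path))` is an identity.
#'
#' @param path File path (`.json` or `.tsv`).
#' @return `read_signature()` returns a [gene_pair_signature()];
#'   `write_signature()` returns `path` invisibly.
#' @export
read_signature <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    gene_pair_signature(
      pairs = tibble::as_tibble(obj$pairs),
      vote_threshold_high = obj$vote_threshold_high,
      vote_threshold_highest = obj$vote_threshold_highest,
      meta = obj$meta %||% list()
    )
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    gene_pair_signature(tbl)
  }
}

#' @rdname read_signature
#' @param sig A `gene_pair_signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_pair_signature"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      pairs = sig$pairs,
      vote_threshold_high = sig$vote_threshold_high,
      vote_threshold_highest = sig$vote_threshold_highest,
      meta = sig$meta
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  } else {
    readr::write_tsv(sig$pairs, path)
  }
  invisible(path)
}

#' The packaged 12-gene-pair bladder-cancer signature (12-GPS)
#'
#' Twelve ordered gene pairs with published Cox coefficients and individual
#' C-indexes. Every pair votes high-risk when gene A is expressed below gene B
#' within the sample; a patient is high-risk with >= 6 risk votes and
#' highest-risk with >= 9.
#'
#' @return A [gene_pair_signature()] with 12 pairs and thresholds 6 / 9.
#' @export
#' @examples
#' twelve_gps()
twelve_gps <- function() {
  read_signature(system.file("extdata", "12gps.json", package = "reopair", mustWork = TRUE))
}
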