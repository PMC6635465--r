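#' Relative expression ordering of two genes within a sample
#'
#' The REO is the strict comparison of two expression values measured in the
#' same sample: `"A_gt_B"`, `"A_lt_B"`, or `"undefined"` when either value is
#' missing or the two are exactly equal. Because it depends only on the
#' ordering, the REO is invariant to any strictly increasing transform of the
#' sample's measurements.
#'
#' @param e_a,e_b Numeric vectors of expression values (recycled pairwise).
#' @return Character vector in `{"A_gt_B", "A_lt_B", "undefined"}`.
#' @export
#' @examples
#' reo(c(5, 3, 3, NA), c(3, 5, 3, 1))
reo <- function(e_a, e_b) {
  out <- rep("undefined", length(e_a))
  ok <- !is.na(e_a) & !is.na(e_b)
  out[ok & e_a > e_b] <- "A_gt_B"
  out[ok & e_a < e_b] <- "A_lt_B"
  out
}

#' Classify a cohort by majority vote over a gene-pair signature
#'
#' For each sample, each signature pair casts a high-risk vote when its
#' observed REO matches the pair's risk orientation. A sample is high-risk
#' when `votes_high >= vote_threshold_high` ("at least half of the pairs"
#' under the default threshold), otherwise low-risk. With
#' `three_tier = TRUE` and a signature carrying `vote_threshold_highest`,
#' the high-risk group is further split into `middle_high`
#' (`threshold_high <= votes_high < threshold_highest`) and `highest`
#' (`votes_high >= threshold_highest`).
#'
#' Undefined REOs (missing value or exact tie) never vote high. Under the
#' default policy `undefined_votes = "count_as_low"` they still count toward
#' `votes_total`, i.e. an abstention is conservatively a low vote; with
#' `"exclude"` they are removed from the denominator and a sample with no
#' defined REO at all is flagged unclassifiable (`tier = NA`).
#'
#' Classification of one sample depends only on that sample's column and the
#' signature — adding or removing other samples never changes a call.
#'
#' @param expr Expression tibble (first column `gene`, then sample columns).
#'   Every signature gene must be present, otherwise an error lists the
#'   missing genes (validated once, up front, not per sample).
#' @param signature A [gene_pair_signature()].
#' @param three_tier Use the three-tier rule (requires
#'   `vote_threshold_highest` in the signature).
#' @param undefined_votes `"count_as_low"` (default) or `"exclude"`.
#' @return A tibble of class `reo_risk_calls` with columns `sample_id`,
#'   `votes_high`, `votes_total`, `tier`, `unclassifiable`, in input sample
#'   order.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = c("G1", "G2"), S1 = c(1, 2), S2 = c(2, 1))
#' sig <- gene_pair_signature(data.frame(gene_a = "G1", gene_b = "G2"))
#' classify_cohort(expr, sig)
classify_cohort <- function(expr, signature, three_tier = FALSE,
                            undefined_votes = c("count_as_low", "exclude")) {
  undefined_votes <- match.arg(undefined_votes)
  stopifnot(inherits(signature, "gene_pair_signature"))
  m <- as_assay_matrix(expr, "expression")
  genes_needed <- unique(c(signature$pairs$gene_a, signature$pairs$gene_b))
  missing <- setdiff(genes_needed, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("signature gene(s) absent from the expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  if (three_tier && is.null(signature$vote_threshold_highest)) {
    abort("three_tier = TRUE requires a signature with vote_threshold_highest")
  }
  a <- m[signature$pairs$gene_a, , drop = FALSE]
  b <- m[signature$pairs$gene_b, , drop = FALSE]
  defined <- !is.na(a) & !is.na(b) & a != b
  risk_lt <- signature$pairs$risk_orientation == "A_lt_B"
  vote_high <- defined & ((risk_lt & a < b) | (!risk_lt & a > b))
  votes_high <- as.integer(colSums(vote_high))
  votes_total <- if (undefined_votes == "count_as_low") {
    rep(nrow(signature$pairs), ncol(m))
  } else {
    as.integer(colSums(defined))
  }
  unclassifiable <- votes_total == 0
  if (any(unclassifiable)) {
    warn(sprintf("%d sample(s) unclassifiable (no defined REO): %s",
                 sum(unclassifiable),
                 paste(head(colnames(m)[unclassifiable], 5), collapse = ", ")))
  }
  tier <- tier_from_votes(votes_high, signature, three_tier)
  tier[unclassifiable] <- NA_character_
  out <- tibble::tibble(
    sample_id = colnames(m),
    votes_high = votes_high,
    votes_total = as.integer(votes_total),
    tier = tier,
    unclassifiable = unclassifiable
  )
  class(out) <- c("reo_risk_calls", class(out))
  attr(out, "three_tier") <- three_tier
  attr(out, "vote_threshold_high") <- signature$vote_threshold_high
  attr(out, "vote_threshold_highest") <- signature$vote_threshold_highest
  out
}

tier_from_votes <- function(votes_high, signature, three_tier) {
  if (three_tier) {
    dplyr::case_when(
      votes_high >= signature$vote_threshold_highest ~ "highest",
      votes_high >= signature$vote_threshold_high ~ "middle_high",
      .default = "low"
    )
  } else {
    ifelse(votes_high >= signature$vote_threshold_high, "high", "low")
  }
}

#' Classify a single sample
#'
#' Convenience wrapper around [classify_cohort()] for one named expression
#' vector.
#'
#' @param sample_expr Named numeric vector (names = gene identifiers).
#' @param signature A [gene_pair_signature()].
#' @param sample_id Identifier used in the returned row.
#' @inheritParams classify_cohort
#' @return One-row tibble as in [classify_cohort()].
#' @export
classify_sample <- function(sample_expr, signature, sample_id = "sample",
                            three_tier = FALSE,
                            undefined_votes = c("count_as_low", "exclude")) {
  if (is.null(names(sample_expr))) abort("sample_expr must be a named numeric vector")
  expr <- tibble::tibble(gene = names(sample_expr), !!sample_id := unname(sample_expr))
  classify_cohort(expr, signature, three_tier = three_tier,
                  undefined_votes = undefined_votes)
}

#' Plot the vote distribution of a set of risk calls
#'
#' Histogram of high-risk vote counts coloured by assigned tier, with the
#' decision threshold(s) marked.
#'
#' @param object A `reo_risk_calls` tibble from [classify_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reo_risk_calls
#' @export
autoplot.reo_risk_calls <- function(object, ...) {
  th <- attr(object, "vote_threshold_high")
  th2 <- attr(object, "vote_threshold_highest")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$votes_high, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = th - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "high-risk votes", y = "samples", fill = "risk tier") +
    ggplot2::theme_minimal()
  if (isTRUE(attr(object, "three_tier")) && !is.null(th2)) {
    p <- p + ggplot2::geom_vline(xintercept = th2 - 0.5, linetype = "dotted")
  }
  p
}
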