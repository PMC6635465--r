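#' Build a directional gene list
#'
#' A directional gene list records, per gene, a dysregulation direction:
#' `"up"` / `"down"`, read in the context of the assay (for expression,
#' up = overexpressed in the high-risk group; for methylation,
#' up = hypermethylated in the high-risk group). Genes must be unique.
#'
#' @param gene Character vector of gene symbols.
#' @param direction Character vector, `"up"` or `"down"`.
#' @param context Optional label (`"expression"`, `"methylation"`, ...)
#'   stored as an attribute.
#' @return Tibble with columns `gene`, `direction`.
#' @export
directional_list <- function(gene, direction, context = NULL) {
  gene <- as.character(gene)
  direction <- as.character(direction)
  if (length(gene) != length(direction)) abort("gene and direction lengths differ")
  if (anyDuplicated(gene)) abort("genes must be unique within a directional list")
  if (!all(direction %in% c("up", "down"))) abort("direction must be 'up' or 'down'")
  out <- tibble::tibble(gene = gene, direction = direction)
  attr(out, "context") <- context
  out
}

#' Concordance score between two directional gene lists
#'
#' With `k` overlapping genes of which `s` agree in direction, the
#' concordance score is the ratio `s / k`. Agreement is direction-equality
#' for two lists of the same modality (`mapping = "same_direction"`, e.g.
#' two differential-expression lists) and direction-opposition for
#' methylation-versus-expression comparisons
#' (`mapping = "inverse_direction"`: hypermethylation is expected to pair
#' with underexpression). Chance agreement is a Binomial(`k`, `p0`) draw,
#' so the reported p-value is the exact upper tail
#' \eqn{P(X \ge s)} from [binomial_tail()], by default with `p0 = 0.5`.
#'
#' @param list_a,list_b Data frames with columns `gene` and `direction`
#'   (see [directional_list()]).
#' @param mapping `"same_direction"` or `"inverse_direction"`.
#' @param p0 Chance agreement probability (default 0.5).
#' @return One-row tibble of class `concordance_result`: `k`, `s`, `score`,
#'   `score_pct` (score as a percentage, two decimals), `p_value`. A zero
#'   overlap yields `k = 0` with `score`/`p_value` `NA` (flagged, not an
#'   error).
#' @export
#' @examples
#' a <- directional_list(c("G1", "G2", "G3"), c("up", "up", "down"))
#' b <- directional_list(c("G2", "G3", "G4"), c("up", "up", "up"))
#' concordance_score(a, b)
concordance_score <- function(list_a, list_b,
                              mapping = c("same_direction", "inverse_direction"),
                              p0 = 0.5) {
  mapping <- match.arg(mapping)
  require_columns(list_a, c("gene", "direction"), "list_a")
  require_columns(list_b, c("gene", "direction"), "list_b")
  if (nrow(list_a) == 0 || nrow(list_b) == 0) abort("both gene lists must be non-empty")
  if (anyDuplicated(list_a$gene) || anyDuplicated(list_b$gene)) {
    abort("genes must be unique within each list")
  }
  shared <- intersect(list_a$gene, list_b$gene)
  k <- length(shared)
  if (k == 0) {
    out <- tibble::tibble(k = 0L, s = NA_integer_, score = NA_real_,
                          score_pct = NA_real_, p_value = NA_real_)
    class(out) <- c("concordance_result", class(out))
    return(out)
  }
  da <- list_a$direction[match(shared, list_a$gene)]
  db <- list_b$direction[match(shared, list_b$gene)]
  s <- if (mapping == "same_direction") sum(da == db) else sum(da != db)
  out <- tibble::tibble(
    k = as.integer(k), s = as.integer(s), score = s / k,
    score_pct = round_half_up_frac(100 * s, k, digits = 2),
    p_value = binomial_tail(k, s, p0)
  )
  class(out) <- c("concordance_result", class(out))
  out
}

#' Exact upper tail of a binomial distribution
#'
#' Computes \eqn{P(X \ge s)} for \eqn{X \sim Binomial(k, p_0)}, i.e.
#' \eqn{1 - \sum_{i=0}^{s-1} \binom{k}{i} p_0^i (1-p_0)^{k-i}}, summed in
#' log space so that extreme tails (e.g. `k = 800, s = 797`) are resolved
#' far below double rounding of the complement instead of collapsing to 0 or
#' 1. `s = 0` returns exactly 1.
#'
#' @param k Number of trials (non-negative integer).
#' @param s Observed count, `0 <= s <= k`.
#' @param p0 Success probability, strictly inside (0, 1).
#' @return The tail probability as a double.
#' @export
#' @examples
#' binomial_tail(3, 3, 0.5)   # 0.125
binomial_tail <- function(k, s, p0 = 0.5) {
  if (length(k) != 1 || length(s) != 1 || k < 0 || k != round(k) || s != round(s)) {
    abort("k and s must be single non-negative integers")
  }
  if (s > k) abort("s must not exceed k")
  if (s < 0) abort("s must be non-negative")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly inside (0, 1)")
  if (s == 0) return(1)
  i <- s:k
  lt <- lchoose(k, i) + i * log(p0) + (k - i) * log1p(-p0)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}

# Shared rank-sum screen over a genes-x-samples matrix split by group labels.
rank_sum_screen <- function(m, groups, high = "high", low = "low",
                            direction_stat = c("median", "mean")) {
  direction_stat <- match.arg(direction_stat)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("groups must label every sample column")
  hi <- groups == high; lo <- groups == low
  if (sum(hi) < 2 || sum(lo) < 2) abort("need >= 2 samples per group")
  stat_fun <- if (direction_stat == "median") {
    function(v, sel) median(v[sel], na.rm = TRUE)
  } else {
    function(v, sel) mean(v[sel], na.rm = TRUE)
  }
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    a <- v[hi][!is.na(v[hi])]; b <- v[lo][!is.na(v[lo])]
    p <- if (length(unique(c(a, b))) < 2) {
      1  # constant gene: no evidence either way
    } else {
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }
    tibble::tibble(gene = rownames(m)[i], p_value = p,
                   delta = stat_fun(v, hi) - stat_fun(v, lo))
  })
  res$fdr <- bh_adjust(res$p_value)
  res
}

#' Differentially methylated genes between risk groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on beta values between the
#' high- and low-risk groups, Benjamini-Hochberg adjusted; direction is the
#' sign of the high-minus-low difference of medians (means via
#' `direction_stat = "mean"`). Genes significant at the FDR threshold are
#' split into hypermethylated (`direction = "up"`, higher beta in high-risk)
#' and hypomethylated (`"down"`). A constant beta row is assigned p = 1,
#' never an error.
#'
#' @param meth Methylation tibble (first column `gene`, then beta columns).
#' @param groups Character vector of risk labels, one per sample column
#'   (values `high`/`low`), or a data frame with `sample_id` and `tier`
#'   columns (e.g. [classify_cohort()] output).
#' @param fdr FDR threshold (default 0.01).
#' @param direction_stat `"median"` (default) or `"mean"`.
#' @param high,low Labels marking the groups.
#' @return Tibble `gene`, `delta`, `p_value`, `fdr`, `direction`, restricted
#'   to significant genes; full per-gene table in attribute `all_genes`.
#' @export
detect_dmg <- function(meth, groups, fdr = 0.01,
                       direction_stat = c("median", "mean"),
                       high = "high", low = "low") {
  m <- as_assay_matrix(meth, "methylation")
  groups <- resolve_groups(groups, colnames(m))
  res <- rank_sum_screen(m, groups, high = high, low = low,
                         direction_stat = direction_stat)
  out <- res |>
    dplyr::filter(.data$fdr < !!fdr, .data$delta != 0) |>
    dplyr::mutate(direction = ifelse(.data$delta > 0, "up", "down")) |>
    dplyr::arrange(.data$fdr, .data$p_value, .data$gene)
  attr(out, "all_genes") <- res
  attr(out, "context") <- "methylation"
  out
}

#' Differentially expressed genes by rank-sum test
#'
#' A plain Wilcoxon rank-sum differential-expression screen between risk
#' groups, with the same mechanics as [detect_dmg()]. This is a simple
#' stand-in usable with any expression matrix; the pipeline equally accepts
#' externally produced directional DEG lists from dedicated callers.
#' Direction `"up"` means higher expression in the high-risk group.
#'
#' @inheritParams detect_dmg
#' @param expr Expression tibble (first column `gene`).
#' @return As [detect_dmg()], with context `"expression"`.
#' @export
detect_deg_ranksum <- function(expr, groups, fdr = 0.01,
                               direction_stat = c("median", "mean"),
                               high = "high", low = "low") {
  m <- as_assay_matrix(expr, "expression")
  groups <- resolve_groups(groups, colnames(m))
  res <- rank_sum_screen(m, groups, high = high, low = low,
                         direction_stat = direction_stat)
  out <- res |>
    dplyr::filter(.data$fdr < !!fdr, .data$delta != 0) |>
    dplyr::mutate(direction = ifelse(.data$delta > 0, "up", "down")) |>
    dplyr::arrange(.data$fdr, .data$p_value, .data$gene)
  attr(out, "all_genes") <- res
  attr(out, "context") <- "expression"
  out
}

resolve_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    require_columns(groups, c("sample_id", "tier"), "groups")
    groups <- setNames(as.character(groups$tier), groups$sample_id)[sample_ids]
  }
  as.character(groups)
}

#' Fisher's exact test on binary event frequencies between risk groups
#'
#' For a genes-by-samples binary matrix (mutation present / copy-number
#' alteration present), tests per gene whether the event frequency differs
#' between the high- and low-risk groups (two-sided Fisher's exact test on
#' the 2x2 table), with Benjamini-Hochberg adjustment. A gene with identical
#' frequencies, or no events at all, simply gets p = 1.
#'
#' @param events Tibble (first column `gene`, then 0/1 sample columns).
#' @inheritParams detect_dmg
#' @return Tibble `gene`, `n_high`, `n_low`, `p_value`, `fdr` restricted to
#'   significant genes (often empty); full table in attribute `all_genes`.
#' @export
fisher_frequency_test <- function(events, groups, fdr = 0.01,
                                  high = "high", low = "low") {
  m <- as_assay_matrix(events, "event")
  if (!all(is.na(m) | m %in% c(0, 1))) abort("event matrix entries must be 0 or 1")
  groups <- resolve_groups(groups, colnames(m))
  hi <- groups == high; lo <- groups == low
  if (sum(hi) < 1 || sum(lo) < 1) abort("need >= 1 sample per group")
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    tab <- matrix(c(sum(v[hi] == 1, na.rm = TRUE), sum(v[hi] == 0, na.rm = TRUE),
                    sum(v[lo] == 1, na.rm = TRUE), sum(v[lo] == 0, na.rm = TRUE)),
                  nrow = 2)
    p <- if (sum(tab[1, ]) == 0 || all(tab[1, ] == 0)) 1 else
      min(fisher.test(tab)$p.value, 1)  # guard against p = 1 + eps round-off
    tibble::tibble(gene = rownames(m)[i], n_high = tab[1, 1], n_low = tab[1, 2],
                   p_value = p)
  })
  res$fdr <- bh_adjust(res$p_value)
  out <- res |> dplyr::filter(.data$fdr < !!fdr) |>
    dplyr::arrange(.data$fdr, .data$p_value, .data$gene)
  attr(out, "all_genes") <- res
  out
}

#' Pool directional gene lists, excluding direction conflicts
#'
#' Unions several directional gene lists; genes reported with contradictory
#' directions in different lists are excluded from the pool and returned in
#' the conflict report.
#'
#' @param ... Two or more data frames with `gene` and `direction` columns,
#'   or a single list of them.
#' @return A list: `pooled` (tibble `gene`, `direction`) and `conflicts`
#'   (character vector of excluded genes).
#' @export
#' @examples
#' a <- directional_list(c("G1", "G2"), c("up", "up"))
#' b <- directional_list(c("G2", "G3"), c("up", "down"))
#' pool_deg_lists(a, b)
pool_deg_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && !is.data.frame(lists[[1]])) lists <- lists[[1]]
  if (length(lists) < 2) abort("pool_deg_lists needs at least two lists")
  all_entries <- purrr::map_dfr(lists, function(l) {
    require_columns(l, c("gene", "direction"), "directional list")
    tibble::tibble(gene = as.character(l$gene), direction = as.character(l$direction))
  })
  by_gene <- all_entries |>
    dplyr::distinct() |>
    dplyr::count(.data$gene, name = "n_directions")
  conflicts <- sort(by_gene$gene[by_gene$n_directions > 1])
  pooled <- all_entries |>
    dplyr::filter(!.data$gene %in% conflicts) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene)
  if (length(conflicts) > 0) {
    inform(sprintf("pool_deg_lists: excluded %d gene(s) with contradictory directions",
                   length(conflicts)))
  }
  list(pooled = pooled, conflicts = conflicts)
}
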