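#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]), with input validation; adjusted values are returned
#' in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the same order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Shared fast path for many univariate Cox fits on a fixed survival outcome.
# Returns beta and Wald p (NA when the fit degenerates).
cox_scan <- function(tm, ev, x) {
  d <- data.frame(.time = tm, .event = ev, x = x)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2 || sum(d$.event) < 1 || length(unique(d$x)) < 2) {
    return(c(beta = NA_real_, p = NA_real_))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(.time, .event) ~ x,
                                     data = d, ties = "efron")),
    error = function(e) NULL
  )
  if (is.null(fit)) return(c(beta = NA_real_, p = NA_real_))
  sm <- summary(fit)$coefficients
  c(beta = unname(sm[1, "coef"]), p = unname(sm[1, "Pr(>|z|)"]))
}

#' Filter genes whose expression is associated with survival
#'
#' Step one of signature discovery: a univariate Cox proportional-hazards
#' model per gene, with the continuous expression value as the covariate,
#' Benjamini-Hochberg adjustment over all testable genes, and retention of
#' genes below the FDR threshold.
#'
#' @param expr Expression tibble (first column `gene`, then sample columns).
#' @param clinical Data frame with `sample_id` plus the survival columns.
#' @param time,event Survival column names (defaults: overall survival).
#' @param fdr FDR threshold (default 0.05).
#' @return Tibble `gene`, `beta`, `hr`, `p_value`, `fdr`, restricted to
#'   retained genes and sorted by `fdr` then `p_value`. The unfiltered table
#'   is attached as attribute `all_genes`.
#' @export
filter_prognostic_genes <- function(expr, clinical, time = "os_time",
                                    event = "os_event", fdr = 0.05) {
  m_al <- align_samples(as_assay_matrix(expr, "expression"), clinical)
  tm <- as.numeric(m_al$clinical[[time]])
  ev <- as.numeric(m_al$clinical[[event]])
  check_nonneg_time(tm, time); check_event_flags(ev, event)
  if (sum(ev, na.rm = TRUE) < 2) abort("need at least 2 samples with events")
  m <- m_al$matrix
  stats_m <- t(vapply(seq_len(nrow(m)), function(i) cox_scan(tm, ev, m[i, ]),
                      c(beta = 0, p = 0)))
  res <- tibble::tibble(
    gene = rownames(m), beta = stats_m[, "beta"],
    hr = exp(stats_m[, "beta"]), p_value = stats_m[, "p"]
  )
  n_dropped <- sum(is.na(res$p_value))
  if (n_dropped > 0) {
    inform(sprintf("filter_prognostic_genes: %d gene(s) untestable (constant or degenerate fit)",
                   n_dropped))
  }
  res$fdr <- bh_adjust(res$p_value)
  out <- res |>
    dplyr::filter(!is.na(.data$fdr), .data$fdr < !!fdr) |>
    dplyr::arrange(.data$fdr, .data$p_value, .data$gene)
  attr(out, "all_genes") <- res
  out
}

#' Screen all gene pairs for survival-associated REO patterns
#'
#' Step two of discovery: for every unordered pair of the supplied genes,
#' samples are split into two groups by the pair's within-sample REO pattern
#' (\eqn{E_A < E_B} vs \eqn{E_A > E_B}; samples with a tie or missing value
#' are left out of that pair's test). Pairs with both groups non-empty are
#' tested by univariate Cox regression on the group indicator;
#' Benjamini-Hochberg adjustment runs over all tested pairs. Each surviving
#' candidate records the risk orientation (the REO pattern of the
#' higher-hazard group), the absolute Cox coefficient of that orientation,
#' and its individual C-index from the two-group split
#' ([c_index_groups()], reflected to `[0.5, 1]`).
#'
#' @param expr,clinical,time,event As in [filter_prognostic_genes()].
#' @param genes Character vector of gene symbols (or the tibble returned by
#'   [filter_prognostic_genes()], whose `gene` column is used).
#' @param fdr FDR threshold over tested pairs (default 0.01).
#' @return Tibble of candidate pairs: `gene_a`, `gene_b`, `cox_p`, `cox_fdr`,
#'   `beta`, `risk_orientation`, `c_index`; attributes `n_tested` and
#'   `n_skipped` (pairs with a single REO pattern across all samples).
#' @export
screen_pairs <- function(expr, clinical, genes, time = "os_time",
                         event = "os_event", fdr = 0.01) {
  if (is.data.frame(genes)) genes <- genes$gene
  genes <- unique(as.character(genes))
  if (length(genes) < 2) abort("need at least 2 prognostic genes to form pairs")
  m_al <- align_samples(as_assay_matrix(expr, "expression"), clinical)
  m <- m_al$matrix
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  tm <- as.numeric(m_al$clinical[[time]])
  ev <- as.numeric(m_al$clinical[[event]])
  pairs <- combn(sort(genes), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    va <- m[ga, ]; vb <- m[gb, ]
    # indicator of the E_A < E_B pattern; NA = undefined REO, dropped per pair
    x <- ifelse(is.na(va) | is.na(vb) | va == vb, NA_real_, as.numeric(va < vb))
    if (length(unique(x[!is.na(x)])) < 2) {
      return(tibble::tibble(gene_a = ga, gene_b = gb, beta_raw = NA_real_,
                            cox_p = NA_real_, skipped = TRUE))
    }
    st <- cox_scan(tm, ev, x)
    tibble::tibble(gene_a = ga, gene_b = gb, beta_raw = st[["beta"]],
                   cox_p = st[["p"]], skipped = FALSE)
  })
  n_skipped <- sum(res$skipped | is.na(res$cox_p))
  if (n_skipped > 0) {
    inform(sprintf("screen_pairs: skipped %d pair(s) with a single REO pattern or degenerate fit",
                   n_skipped))
  }
  tested <- res |> dplyr::filter(!.data$skipped, !is.na(.data$cox_p))
  tested$cox_fdr <- bh_adjust(tested$cox_p)
  cand <- tested |> dplyr::filter(.data$cox_fdr < !!fdr)
  if (nrow(cand) > 0) {
    cand <- cand |>
      dplyr::mutate(
        risk_orientation = ifelse(.data$beta_raw > 0, "A_lt_B", "A_gt_B"),
        beta = abs(.data$beta_raw)
      )
    cand$c_index <- vapply(seq_len(nrow(cand)), function(i) {
      va <- m[cand$gene_a[i], ]; vb <- m[cand$gene_b[i], ]
      r <- reo(va, vb)
      lab <- ifelse(r == "undefined", NA_character_,
                    ifelse(r == cand$risk_orientation[i], "high", "low"))
      d <- data.frame(time = tm, event = ev, group = lab)
      c_index_groups(d)$c_index
    }, numeric(1))
  } else {
    cand <- tibble::tibble(gene_a = character(), gene_b = character(),
                           beta_raw = numeric(), cox_p = numeric(),
                           cox_fdr = numeric(), risk_orientation = character(),
                           beta = numeric(), c_index = numeric())
  }
  out <- cand[, c("gene_a", "gene_b", "cox_p", "cox_fdr", "beta",
                  "risk_orientation", "c_index")]
  attr(out, "n_tested") <- nrow(tested)
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Greedy forward selection of a gene-pair signature
#'
#' Step three of discovery. Candidates are ranked by individual C-index
#' (descending; ties broken by smaller Cox p, then lexicographic gene names,
#' so the result is reproducible without a seed). The top pair seeds the
#' signature; remaining candidates are then tried one at a time in rank
#' order. Each tentative addition reclassifies the cohort under the
#' majority-vote rule (high-risk votes `>= ceiling(current_size / 2)`, i.e.
#' "at least half of the pairs") and is kept only if the ensemble C-index
#' strictly improves.
#'
#' Two stopping policies: `"scan_all"` (default) skips a non-improving pair
#' and keeps scanning the rest of the ranked list;
#' `"stop_at_first_failure"` stops at the first non-improving pair. The
#' chosen policy is recorded in the returned signature's metadata.
#'
#' @param candidates Candidate tibble from [screen_pairs()].
#' @param expr,clinical,time,event As in [filter_prognostic_genes()].
#' @param policy `"scan_all"` or `"stop_at_first_failure"`.
#' @return A [gene_pair_signature()] whose metadata records
#'   `ensemble_c_index`, `policy`, and the selection order.
#' @export
forward_select <- function(candidates, expr, clinical, time = "os_time",
                           event = "os_event",
                           policy = c("scan_all", "stop_at_first_failure")) {
  policy <- match.arg(policy)
  if (nrow(candidates) == 0) abort("forward_select needs at least one candidate pair")
  ranked <- candidates |>
    dplyr::arrange(dplyr::desc(.data$c_index), .data$cox_p, .data$gene_a, .data$gene_b)
  m_al <- align_samples(as_assay_matrix(expr, "expression"), clinical)
  m <- m_al$matrix
  surv <- data.frame(time = as.numeric(m_al$clinical[[time]]),
                     event = as.numeric(m_al$clinical[[event]]))

  ensemble_c <- function(rows) {
    sig <- gene_pair_signature(ranked[rows, ],
                               vote_threshold_high = ceiling(length(rows) / 2))
    calls <- suppressWarnings(classify_cohort(as_assay_tibble(m), sig))
    d <- data.frame(time = surv$time, event = surv$event, group = calls$tier)
    tryCatch(c_index_groups(d)$c_index, error = function(e) NA_real_)
  }

  selected <- 1L
  best_c <- ensemble_c(selected)
  if (is.na(best_c)) abort("seed pair yields an undefined ensemble C-index")
  if (nrow(ranked) > 1) {
    for (i in 2:nrow(ranked)) {
      cand_c <- ensemble_c(c(selected, i))
      if (!is.na(cand_c) && cand_c > best_c) {
        selected <- c(selected, i)
        best_c <- cand_c
      } else if (policy == "stop_at_first_failure") {
        break
      }
    }
  }
  gene_pair_signature(
    ranked[selected, ],
    vote_threshold_high = ceiling(length(selected) / 2),
    meta = list(ensemble_c_index = best_c, policy = policy,
                seed_c_index = ranked$c_index[1],
                n_candidates = nrow(ranked))
  )
}

#' Full signature-discovery pipeline
#'
#' Runs the three discovery stages in sequence: per-gene prognostic filter
#' ([filter_prognostic_genes()], FDR < `gene_fdr`), all-pairs REO screen
#' ([screen_pairs()], FDR < `pair_fdr`), and C-index-ranked greedy forward
#' selection under the majority-vote rule ([forward_select()]). Given fixed
#' data and thresholds the result is fully deterministic.
#'
#' @inheritParams filter_prognostic_genes
#' @param gene_fdr FDR threshold of the per-gene filter (default 0.05).
#' @param pair_fdr FDR threshold of the pair screen (default 0.01).
#' @param policy Forward-selection stopping policy (see [forward_select()]).
#' @param verbose Report stage-wise counts as messages.
#' @return A [gene_pair_signature()]; metadata additionally records
#'   stage-wise counts (`n_genes_retained`, `n_pairs_tested`,
#'   `n_candidates`).
#' @export
discover_signature <- function(expr, clinical, time = "os_time",
                               event = "os_event", gene_fdr = 0.05,
                               pair_fdr = 0.01,
                               policy = c("scan_all", "stop_at_first_failure"),
                               verbose = TRUE) {
  policy <- match.arg(policy)
  genes <- filter_prognostic_genes(expr, clinical, time, event, fdr = gene_fdr)
  if (verbose) inform(sprintf("discovery: %d prognostic gene(s) at FDR < %g",
                              nrow(genes), gene_fdr))
  if (nrow(genes) < 2) abort("fewer than 2 prognostic genes; cannot form pairs")
  cands <- screen_pairs(expr, clinical, genes, time, event, fdr = pair_fdr)
  if (verbose) inform(sprintf("discovery: %d candidate pair(s) at FDR < %g (of %d tested)",
                              nrow(cands), pair_fdr, attr(cands, "n_tested")))
  if (nrow(cands) == 0) abort("no candidate pairs passed the REO screen")
  sig <- forward_select(cands, expr, clinical, time, event, policy = policy)
  sig$meta$n_genes_retained <- nrow(genes)
  sig$meta$n_pairs_tested <- attr(cands, "n_tested")
  sig$meta$n_candidates <- nrow(cands)
  sig$meta$gene_fdr <- gene_fdr
  sig$meta$pair_fdr <- pair_fdr
  if (verbose) inform(sprintf("discovery: final signature has %d pair(s), ensemble C-index %.3f",
                              length(sig), sig$meta$ensemble_c_index))
  sig
}
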