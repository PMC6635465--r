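# Fixture builders, all programmatic.

expr_tbl <- function(m) {
  tibble::tibble(gene = rownames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(m, .name_repair = "minimal"))
}

# random right-censored two-group survival data
rand_surv <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- rexp(n, 0.2)
  if (runif(1) < 0.3) time <- ceiling(time)  # induce tied times sometimes
  data.frame(
    time = time,
    event = rbinom(n, 1, 0.6),
    group = sample(c("high", "low"), n, replace = TRUE)
  )
}

# small random expression cohort (iid per-gene means, modest noise) plus a
# random signature over its genes
rand_cohort_and_signature <- function(n_genes = 20, n_samples = 30,
                                      n_pairs = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = rep(runif(n_genes, 0, 10), n_samples), sd = 0.5),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samples)))
  idx <- matrix(sample(n_genes, 2 * n_pairs), ncol = 2)
  sig <- gene_pair_signature(tibble::tibble(
    gene_a = rownames(m)[idx[, 1]],
    gene_b = rownames(m)[idx[, 2]],
    risk_orientation = sample(c("A_lt_B", "A_gt_B"), n_pairs, replace = TRUE)
  ))
  list(expr = expr_tbl(m), sig = sig, m = m)
}

write_tmp <- function(lines, ext = ".tsv") {
  tf <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
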