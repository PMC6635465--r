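test_that("cohorts are a pure function of the configuration and seed", {
  a <- simulate_cohort(n_samples = 60, seed = 5)
  b <- simulate_cohort(n_samples = 60, seed = 5)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(n_samples = 60, seed = 6)
  expect_false(identical(a$expression, c2$expression))
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  simulate_cohort(n_samples = 30, seed = 99)
  set.seed(123); expect_identical(before, rnorm(1))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_cohort(n_genes = 8, n_planted_pairs = 5),
               "infeasible")
  expect_error(simulate_cohort(censoring_rate = 1), "censoring_rate")
  expect_error(simulate_cohort(n_genes = 60, n_planted_pairs = 5,
                               n_methyl_coupled_genes = 51),
               "exceeds")
})

test_that("cohort structure is internally consistent", {
  coh <- simulate_cohort(seed = 3)
  expect_true(all(coh$truth$pairs$gene_a %in% coh$expression$gene))
  expect_true(all(coh$truth$coupled_genes$gene %in% coh$methylation$gene))
  expect_true(all(coh$clinical$os_time >= 0))
  expect_true(all(coh$clinical$dfs_time <= coh$clinical$os_time + 1e-9))
  beta <- as.matrix(coh$methylation[, -1])
  expect_true(all(beta >= 0 & beta <= 1))
  # planted orientation holds in most samples of either risk state
  m <- as.matrix(coh$expression[, -1]); rownames(m) <- coh$expression$gene
  p1 <- coh$truth$pairs[1, ]
  state <- coh$truth$risk_states[1, ]
  frac_risk_ordering <- mean((m[p1$gene_a, ] < m[p1$gene_b, ]) == (state == 1))
  expect_gte(frac_risk_ordering, 0.95)
})

test_that("the realised censoring fraction tracks the configured rate", {
  for (s in 1:3) {
    coh <- simulate_cohort(n_samples = 400, censoring_rate = 0.3, seed = s)
    expect_lt(abs(mean(coh$clinical$os_event == 0) - 0.3), 0.05)
  }
  coh0 <- simulate_cohort(n_samples = 100, censoring_rate = 0, seed = 1)
  expect_true(all(coh0$clinical$os_event == 1))
})

test_that("null coupling yields no survival separation between true-risk strata", {
  pvals <- sapply(1:15, function(s) {
    coh <- simulate_cohort(n_samples = 150, pair_log_hazard = 0, seed = 200 + s)
    d <- data.frame(time = coh$clinical$os_time, event = coh$clinical$os_event,
                    group = ifelse(coh$truth$true_risk, "high", "low"))
    km_logrank(d)$p_value
  })
  # p-values behave like a null sample: no pile-up at small values
  expect_lte(sum(pvals < 0.05), 3)
  expect_gt(median(pvals), 0.1)
})

test_that("monotone batch distortions leave risk calls bit-identical", {
  rc <- rand_cohort_and_signature(seed = 31)
  base <- classify_cohort(rc$expr, rc$sig)
  dist <- apply_distortion(rc$expr, "batch_affine",
                           params = list(scale = 3.7, offset = 12), seed = 1)
  expect_identical(classify_cohort(dist, rc$sig), base)
  # random per-sample affine + power transforms
  dist2 <- apply_distortion(rc$expr, "batch_affine", seed = 2,
                            params = list(power = runif(ncol(rc$m), 0.5, 2)))
  expect_identical(classify_cohort(dist2, rc$sig)[, 1:4], base[, 1:4])
  expect_error(apply_distortion(rc$expr, "batch_affine",
                                params = list(scale = -1)),
               "monotone")
})

test_that("noise distortions degrade gracefully and vanish in the zero limit", {
  coh <- simulate_cohort(n_samples = 150, seed = 8)
  sig <- gene_pair_signature(coh$truth$pairs)
  base <- classify_cohort(coh$expression, sig)
  none <- apply_distortion(coh$expression, "degradation",
                           params = list(sigma = 0), seed = 4)
  expect_identical(classify_cohort(none, sig), base)
  deg <- apply_distortion(coh$expression, "degradation",
                          params = list(sigma = 0.2), seed = 4)
  agree <- mean(classify_cohort(deg, sig)$tier == base$tier)
  expect_gte(agree, 0.9)
  mix <- apply_distortion(coh$expression, "subsample_cells", seed = 5)
  agree_mix <- mean(classify_cohort(mix, sig)$tier == base$tier)
  expect_gte(agree_mix, 0.8)
})

test_that("batch labels partition samples and shared risk states correlate pairs", {
  coh <- simulate_cohort(n_samples = 90, n_batches = 3, seed = 12)
  expect_equal(sort(unique(coh$clinical$batch)), c("b1", "b2", "b3"))
  shared <- simulate_cohort(n_samples = 200, shared_risk_state = TRUE, seed = 13)
  rs <- shared$truth$risk_states
  expect_true(all(apply(rs, 2, function(col) length(unique(col)) == 1)))
})

test_that("cohorts round-trip through the plain-text writers", {
  coh <- simulate_cohort(n_samples = 30, n_genes = 10, n_planted_pairs = 2,
                         n_methyl_coupled_genes = 3, seed = 44)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_setequal(list.files(dir),
                  c("expr.tsv", "meth.tsv", "clinical.tsv", "truth.json"))
  back <- read_expression(file.path(dir, "expr.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(coh$expression),
               tolerance = 1e-12)
  cl <- read_clinical(file.path(dir, "clinical.tsv"), grade_system = "three_level")
  expect_equal(cl$os_event, coh$clinical$os_event)
})
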