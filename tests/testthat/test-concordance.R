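test_that("concordance score counts overlap and directional agreement", {
  a <- directional_list(c("G1", "G2", "G3"), c("up", "up", "down"))
  b <- directional_list(c("G2", "G3", "G4"), c("up", "up", "up"))
  r <- concordance_score(a, b)
  expect_equal(r$k, 2L)
  expect_equal(r$s, 1L)   # G2 agrees, G3 disagrees
  expect_equal(r$score, 0.5)

  # a list compared with itself is fully concordant
  self <- concordance_score(a, a)
  expect_equal(self$score, 1)
  expect_equal(self$score_pct, 100)

  # symmetry under swapping the lists (same-direction mapping)
  r_sw <- concordance_score(b, a)
  expect_equal(r_sw[, c("k", "s", "score", "p_value")],
               r[, c("k", "s", "score", "p_value")])
})

test_that("inverse mapping enumerates the 2x2 direction table correctly", {
  for (da in c("up", "down")) {
    for (db in c("up", "down")) {
      r <- concordance_score(directional_list("G1", da),
                             directional_list("G1", db),
                             mapping = "inverse_direction")
      expect_equal(r$s, as.integer(da != db))
    }
  }
  # hypermethylated + underexpressed is the concordant configuration
  hyper <- directional_list("G1", "up", context = "methylation")
  expect_equal(concordance_score(hyper, directional_list("G1", "down"),
                                 mapping = "inverse_direction")$s, 1L)
  expect_equal(concordance_score(hyper, directional_list("G1", "up"),
                                 mapping = "inverse_direction")$s, 0L)
})

test_that("zero overlap is flagged, not an error; empty lists are errors", {
  r <- concordance_score(directional_list("G1", "up"),
                         directional_list("G2", "up"))
  expect_equal(r$k, 0L)
  expect_true(is.na(r$score) && is.na(r$p_value))
  expect_error(concordance_score(directional_list(character(), character()),
                                 directional_list("G1", "up")),
               "non-empty")
})

test_that("binomial tail matches enumeration and survives extreme tails", {
  expect_equal(binomial_tail(3, 3, 0.5), 0.125, tolerance = 1e-12)
  expect_identical(binomial_tail(100, 0, 0.3), 1)
  expect_error(binomial_tail(3, 4, 0.5), "exceed")
  expect_error(binomial_tail(3, 2, 1), "p0")

  # cross-check against an independent summation for moderate sizes
  set.seed(3)
  for (i in 1:30) {
    k <- sample(1:500, 1); s <- sample(0:k, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_tail(k, s, p0), oracle_binom_tail(k, s, p0),
                 tolerance = 1e-10)
  }

  # extreme tails resolve instead of flushing to 0 via the complement
  expect_lt(binomial_tail(800, 797, 0.5), 2.2e-16)
  expect_gt(binomial_tail(800, 797, 0.5), 0)
  expect_equal(binomial_tail(475, 475, 0.5), 2^-475, tolerance = 1e-10)
})

test_that("binomial tail is monotone in s and complements sum to one", {
  for (k in c(10, 101, 1000)) {
    s_grid <- unique(round(seq(0, k, length.out = 25)))
    tails <- vapply(s_grid, function(s) binomial_tail(k, s, 0.5), numeric(1))
    expect_true(all(diff(tails) <= 0))
    # P(X >= s) + P(X <= s - 1) = 1; at p0 = 0.5, P(X <= s-1) = P(X >= k-s+1)
    for (s in s_grid[s_grid >= 1]) {
      expect_equal(binomial_tail(k, s, 0.5) + binomial_tail(k, k - s + 1, 0.5),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("DMG detection recovers a planted beta shift and controls the null", {
  set.seed(91)
  n_per <- 40
  n_genes <- 200
  groups <- rep(c("high", "low"), each = n_per)
  base <- matrix(runif(n_genes, 0.2, 0.6), n_genes, 2 * n_per) +
    matrix(rnorm(n_genes * 2 * n_per, sd = 0.08), n_genes)
  rownames(base) <- sprintf("g%03d", 1:n_genes)
  colnames(base) <- sprintf("s%03d", 1:(2 * n_per))
  planted <- rownames(base)[1:50]
  base[planted, groups == "high"] <- base[planted, groups == "high"] + 0.3
  m <- pmin(pmax(base, 0), 1)

  got <- detect_dmg(expr_tbl(m), groups)
  hyper <- got$gene[got$direction == "up"]
  expect_gte(length(intersect(hyper, planted)), 45)
  # no planted gene called in the wrong direction
  expect_length(intersect(got$gene[got$direction == "down"], planted), 0)

  # permuted labels: discoveries at FDR < 1% stay near zero
  set.seed(92)
  perm <- sample(groups)
  expect_lte(nrow(detect_dmg(expr_tbl(m[51:200, ]), perm)), 3)

  # identical group distributions -> empty; constant row -> p = 1
  flat <- matrix(0.5, 10, 20, dimnames = list(sprintf("f%02d", 1:10),
                                              sprintf("s%02d", 1:20)))
  got_flat <- detect_dmg(expr_tbl(flat), rep(c("high", "low"), each = 10))
  expect_equal(nrow(got_flat), 0)
  expect_true(all(attr(got_flat, "all_genes")$p_value == 1))
})

test_that("rank-sum DEG stand-in recovers planted expression shifts", {
  set.seed(14)
  n_per <- 30
  groups <- rep(c("high", "low"), each = n_per)
  m <- matrix(rnorm(100 * 2 * n_per, mean = 5), 100, 2 * n_per,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:(2 * n_per))))
  m[1:10, groups == "high"] <- m[1:10, groups == "high"] + log(2) / log(exp(1)) * 2
  got <- detect_deg_ranksum(expr_tbl(m), groups)
  expect_gte(length(intersect(got$gene[got$direction == "up"], rownames(m)[1:10])), 9)
  # constant gene is never reported
  m2 <- rbind(m, const = rep(1, 2 * n_per))
  got2 <- detect_deg_ranksum(expr_tbl(m2), groups)
  expect_false("const" %in% got2$gene)
})

test_that("Fisher frequency test matches hypergeometric enumeration", {
  groups <- rep(c("high", "low"), each = 10)
  ev <- matrix(0L, 3, 20, dimnames = list(c("allhigh", "even", "none"),
                                          sprintf("s%02d", 1:20)))
  ev["allhigh", groups == "high"] <- 1L
  ev["even", c(1:5, 11:15)] <- 1L
  res <- attr(fisher_frequency_test(expr_tbl(ev), groups), "all_genes")
  expect_equal(res$p_value[res$gene == "allhigh"], oracle_fisher_p(10, 0, 0, 10))
  expect_equal(res$p_value[res$gene == "even"], 1)
  expect_equal(res$p_value[res$gene == "none"], 1)
  expect_error(fisher_frequency_test(expr_tbl(ev * 2), groups), "0 or 1")

  # random small tables agree with the enumeration oracle
  set.seed(6)
  for (i in 1:40) {
    nh <- sample(2:15, 1); nl <- sample(2:15, 1)
    g <- rep(c("high", "low"), c(nh, nl))
    v <- rbinom(nh + nl, 1, runif(1, 0.2, 0.8))
    if (sum(v) == 0) next
    mm <- matrix(v, 1, dimnames = list("g1", sprintf("s%02d", 1:(nh + nl))))
    got <- attr(fisher_frequency_test(expr_tbl(mm), g), "all_genes")$p_value
    expect_equal(got, oracle_fisher_p(sum(v[g == "high"]), sum(1 - v[g == "high"]),
                                      sum(v[g == "low"]), sum(1 - v[g == "low"])),
                 tolerance = 1e-9)
  }
})

test_that("pooling unions lists and excludes direction conflicts", {
  a <- directional_list(c("G1", "G2"), c("up", "up"))
  b <- directional_list(c("G2", "G3"), c("up", "down"))
  r <- pool_deg_lists(a, b)
  expect_equal(r$pooled$gene, c("G1", "G2", "G3"))
  expect_equal(r$pooled$direction, c("up", "up", "down"))
  expect_length(r$conflicts, 0)

  conf <- suppressMessages(pool_deg_lists(directional_list("G1", "up"),
                                          directional_list("G1", "down")))
  expect_equal(nrow(conf$pooled), 0)
  expect_equal(conf$conflicts, "G1")

  disj <- pool_deg_lists(directional_list("G1", "up"),
                         directional_list("G2", "down"))
  expect_equal(nrow(disj$pooled), 2)
  expect_length(disj$conflicts, 0)
})
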