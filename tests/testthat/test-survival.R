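test_that("group C-index handles the textbook extremes", {
  # perfect separation: every high-risk event precedes every low-risk time
  d <- data.frame(time = c(1, 2, 3, 4), event = 1,
                  group = c("high", "high", "low", "low"))
  r <- c_index_groups(d)
  expect_equal(r$c_index, 1)
  expect_equal(r$n_usable, 4L)

  # balanced fully-observed toy with equal concordant/discordant pairs
  d2 <- data.frame(time = c(1, 4, 2, 3), event = 1,
                   group = c("high", "high", "low", "low"))
  expect_equal(c_index_groups(d2)$c_index, 0.5)

  # worse-than-chance labelling is reflected into [0.5, 1], raw retained
  d3 <- data.frame(time = c(3, 4, 1, 2), event = 1,
                   group = c("high", "high", "low", "low"))
  r3 <- c_index_groups(d3)
  expect_equal(r3$c_raw, 0)
  expect_equal(r3$c_index, 1)
})

test_that("group C-index equals brute-force enumeration under censoring", {
  # a fixed 6-sample mixed-censoring fixture, then a random sweep
  d <- data.frame(time = c(2, 5, 5, 1, 3, 7),
                  event = c(1, 0, 1, 1, 0, 1),
                  group = c("high", "high", "high", "low", "low", "low"))
  o <- oracle_c_index(d$time, d$event, d$group)
  r <- c_index_groups(d)
  expect_identical(r$n_concordant, o$n_concordant)
  expect_identical(r$n_usable, o$n_usable)
  expect_equal(r$c_raw, o$c_raw)

  for (seed in 1:300) {
    d <- rand_surv(sample(6:60, 1), seed = seed)
    if (length(unique(d$group)) < 2 || sum(d$event) == 0) next
    o <- oracle_c_index(d$time, d$event, d$group)
    if (o$n_usable == 0) {
      expect_error(c_index_groups(d), "undefined")
      next
    }
    r <- c_index_groups(d)
    expect_identical(c(r$n_concordant, r$n_usable),
                     c(o$n_concordant, o$n_usable))
  }
})

test_that("group C-index is invariant to order-preserving time rescaling", {
  d <- rand_surv(40, seed = 9)
  r1 <- c_index_groups(d)
  d$time <- exp(d$time / 3) * 100
  r2 <- c_index_groups(d)
  expect_equal(r1$c_index, r2$c_index)
  expect_identical(r1$n_usable, r2$n_usable)
})

test_that("group C-index rejects degenerate inputs", {
  expect_error(c_index_groups(data.frame(time = 1:3, event = 1, group = "high")),
               "each risk group")
  expect_error(c_index_groups(data.frame(time = 1:4, event = 0,
                                         group = c("high", "high", "low", "low"))),
               "event")
  # only pair is tied in time -> no usable pair
  expect_error(c_index_groups(data.frame(time = c(2, 2), event = c(1, 1),
                                         group = c("high", "low"))),
               "undefined")
})

test_that("Kaplan-Meier estimates and the log-rank test match first principles", {
  # identical survival in both groups: chi2 ~ 0, p ~ 1, identical curves
  base <- data.frame(time = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 1))
  d <- rbind(cbind(base, group = "A"), cbind(base, group = "B"))
  km <- km_logrank(d)
  expect_lt(km$chi2, 1e-10)
  expect_gt(km$p_value, 0.999)
  cv <- tidy(km)
  expect_equal(cv$estimate[cv$group == "A"], cv$estimate[cv$group == "B"])

  # product-limit definition: after the first of n fully-observed events,
  # S = (n-1)/n
  first_a <- cv[cv$group == "A" & cv$n_event > 0, ][1, ]
  expect_equal(first_a$estimate, 4 / 5)

  # no censoring: KM equals the empirical survival function
  d2 <- data.frame(time = c(1, 2, 3, 4, 6, 9), event = 1,
                   group = rep(c("A", "B"), 3))
  cv2 <- tidy(km_logrank(d2))
  ecdf_surv <- sapply(cv2$time[cv2$group == "A"],
                      function(t) mean(d2$time[d2$group == "A"] > t))
  expect_equal(cv2$estimate[cv2$group == "A"], ecdf_surv)

  # two-group toy matches the hand observed-minus-expected formula
  d3 <- data.frame(time = c(1, 3, 4, 2, 5, 8), event = c(1, 1, 0, 1, 1, 1),
                   group = c("A", "A", "A", "B", "B", "B"))
  expect_equal(km_logrank(d3)$chi2,
               oracle_logrank_chi2(d3$time, d3$event, d3$group))
  expect_error(km_logrank(base |> transform(group = "A")), ">= 2")
})

test_that("Cox fits agree with a grid search of the partial likelihood", {
  set.seed(21)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(os_time = rexp(n, 0.1 * exp(0.8 * x)), os_event = 1, x = x)
  fit <- cox_fit(d, "x")
  opt <- stats::optimize(
    function(b) -oracle_log_partial_lik(b, d$os_time, d$os_event, d$x),
    interval = c(-5, 5), tol = 1e-9
  )
  expect_equal(fit$beta, opt$minimum, tolerance = 1e-3)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("Cox fit flags separation and rejects constant covariates", {
  d <- data.frame(os_time = c(1, 2, 3, 10, 11, 12),
                  os_event = c(1, 1, 1, 0, 0, 0),
                  g = c(rep("high", 3), rep("low", 3)))
  fit <- cox_fit(d, "g")
  expect_equal(fit$flag, "separation")
  expect_error(cox_fit(transform(d, z = 1), "z"), "constant")
})

test_that("Cox model recovers a doubled hazard at n = 500", {
  set.seed(77)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * 2^x)
  cens <- rexp(n, 0.02)
  d <- data.frame(os_time = pmin(t_ev, cens), os_event = as.numeric(t_ev <= cens), x = x)
  fit <- cox_fit(d, "x")
  expect_true(fit$ci_low < 2 && 2 < fit$ci_high)
  expect_equal(fit$hr, 2, tolerance = 0.25)
})

test_that("univariate mode fits covariates separately and glance summarises", {
  set.seed(5)
  n <- 120
  d <- data.frame(os_time = rexp(n, 0.1), os_event = rbinom(n, 1, 0.8),
                  a = rnorm(n), b = rnorm(n))
  uni <- cox_fit(d, c("a", "b"), mode = "univariate")
  expect_equal(nrow(uni), 2)
  expect_true(all(uni$model == "univariate"))
  sep_a <- cox_fit(d, "a")
  expect_equal(uni$beta[uni$term == "a"], sep_a$beta)
  g <- glance(sep_a)
  expect_equal(g$n, n)
  expect_false(g$any_separation)
})
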