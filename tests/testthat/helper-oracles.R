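# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# C-index for a binary grouping by exhaustive enumeration of all high-low
# sample pairs: a pair is usable when times differ and the earlier time is an
# observed event; concordant when the high-risk member has the earlier event.
oracle_c_index <- function(time, event, group) {
  hi <- which(group == "high")
  lo <- which(group == "low")
  conc <- 0L; usable <- 0L
  for (i in hi) {
    for (j in lo) {
      if (time[i] == time[j]) next
      if (time[i] < time[j] && event[i] == 1) {
        usable <- usable + 1L; conc <- conc + 1L
      } else if (time[j] < time[i] && event[j] == 1) {
        usable <- usable + 1L
      }
    }
  }
  list(n_concordant = conc, n_usable = usable,
       c_raw = if (usable > 0) conc / usable else NA_real_)
}

# Two-group log-rank chi-square from the observed-minus-expected formula,
# summed over distinct event times.
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Log partial likelihood of a univariate Cox model (no tied event times in
# the fixtures that use it, so Breslow/Efron coincide).
oracle_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Step-up BH by hand: sort, scale by m/i, enforce monotonicity from the top,
# cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Binomial upper tail by direct summation of stats::dbinom terms.
oracle_binom_tail <- function(k, s, p0) {
  if (s == 0) return(1)
  sum(stats::dbinom(s:k, k, p0))
}

# Two-sided Fisher p by hypergeometric enumeration: sum the probabilities of
# all tables (given margins) no more probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
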