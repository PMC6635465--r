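#' Concordance index for a binary risk grouping
#'
#' The C-index of a high/low risk labelling is the proportion of consistent
#' outcomes among all usable high-low sample pairs. A (high, low) pair is
#' usable when the two survival times differ and the earlier time is an
#' observed event (pairs whose earlier time is censored, or with tied times,
#' are not orderable under right censoring and are excluded — the standard
#' Harrell convention for a binary marker). A usable pair is concordant when
#' the high-risk member has the earlier event.
#'
#' The raw proportion `c_raw = n_concordant / n_usable` is reflected to
#' `c_index = max(c_raw, 1 - c_raw)` so the reported value always lies in
#' `[0.5, 1]` (0.5 = no discrimination, 1 = perfect); `c_raw` is retained so
#' a worse-than-chance labelling remains visible.
#'
#' @param data Data frame with one row per sample.
#' @param time,event,group Column names (strings) holding the survival time,
#'   the event flag (1 = event, 0 = censored), and the risk label.
#' @param high,low Values of `group` marking the two risk groups.
#' @return An object of class `cindex_result`: a list with `c_index`,
#'   `c_raw`, `n_concordant`, `n_usable`, `n_high`, `n_low`.
#' @export
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), event = 1,
#'                 group = c("high", "high", "low", "low"))
#' c_index_groups(d)$c_index
c_index_groups <- function(data, time = "time", event = "event", group = "group",
                           high = "high", low = "low") {
  require_columns(data, c(time, event, group), "survival data")
  tm <- as.numeric(data[[time]])
  ev <- as.numeric(data[[event]])
  gr <- as.character(data[[group]])
  keep <- !is.na(tm) & !is.na(ev) & gr %in% c(high, low)
  tm <- tm[keep]; ev <- ev[keep]; gr <- gr[keep]
  check_nonneg_time(tm); check_event_flags(ev)
  is_hi <- gr == high
  n_high <- sum(is_hi); n_low <- sum(!is_hi)
  if (n_high == 0 || n_low == 0) {
    abort("C-index needs at least one sample in each risk group")
  }
  if (sum(ev) == 0) abort("C-index needs at least one observed event")
  t_hi <- tm[is_hi]; e_hi <- ev[is_hi]
  t_lo <- tm[!is_hi]; e_lo <- ev[!is_hi]
  # Counting with sorted opposite-group times: for each event, the number of
  # opposite-group samples with a strictly later time. findInterval on the
  # sorted vector counts values <= t, so ties are excluded automatically.
  s_lo <- sort(t_lo); s_hi <- sort(t_hi)
  conc <- sum(n_low - findInterval(t_hi[e_hi == 1], s_lo))
  disc <- sum(n_high - findInterval(t_lo[e_lo == 1], s_hi))
  usable <- conc + disc
  if (usable == 0) abort("C-index undefined: no usable high-low pair")
  c_raw <- conc / usable
  structure(
    list(c_index = max(c_raw, 1 - c_raw), c_raw = c_raw,
         n_concordant = as.integer(conc), n_usable = as.integer(usable),
         n_high = as.integer(n_high), n_low = as.integer(n_low)),
    class = "cindex_result"
  )
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (raw %.4f; %d concordant / %d usable pairs; %d high, %d low)\n",
              x$c_index, x$c_raw, x$n_concordant, x$n_usable, x$n_high, x$n_low))
  invisible(x)
}

#' @rdname c_index_groups
#' @param x A `cindex_result`.
#' @param ... Unused.
#' @method glance cindex_result
#' @export
glance.cindex_result <- function(x, ...) {
  tibble::tibble(c_index = x$c_index, c_raw = x$c_raw,
                 n_concordant = x$n_concordant, n_usable = x$n_usable,
                 n_high = x$n_high, n_low = x$n_low)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimates per group plus the standard log-rank
#' chi-square comparing them (delegated to [survival::survfit()] and
#' [survival::survdiff()]).
#'
#' @inheritParams c_index_groups
#' @return An object of class `reo_km`: list with the `survfit` object,
#'   `chi2`, `df`, `p_value`, and per-group sizes.
#' @export
km_logrank <- function(data, time = "time", event = "event", group = "group") {
  require_columns(data, c(time, event, group), "survival data")
  d <- data.frame(
    time = as.numeric(data[[time]]),
    event = as.numeric(data[[event]]),
    group = as.character(data[[group]])
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  check_nonneg_time(d$time); check_event_flags(d$event)
  counts <- table(d$group)
  if (length(counts) < 2) abort("log-rank needs >= 2 non-empty groups")
  if (sum(d$event) == 0) abort("log-rank needs at least one observed event")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1
  chi2 <- unname(sd$chisq)
  structure(
    list(fit = fit, survdiff = sd, chi2 = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE),
         n = as.integer(counts), groups = names(counts), data = d),
    class = "reo_km"
  )
}

#' @export
print.reo_km <- function(x, ...) {
  cat(sprintf("Log-rank: chi2 = %.3f on %d df, p = %.3g (groups: %s)\n",
              x$chi2, x$df, x$p_value,
              paste(sprintf("%s n=%d", x$groups, x$n), collapse = ", ")))
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `reo_km` object.
#' @param ... Unused.
#' @method tidy reo_km
#' @export
tidy.reo_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(x$groups[1], length(s$time)) else {
    sub("^group=", "", as.character(s$strata))
  }
  tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv, std_error = s$std.err,
    conf_low = s$lower, conf_high = s$upper
  )
}

#' @rdname km_logrank
#' @method glance reo_km
#' @export
glance.reo_km <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value,
                 n = sum(x$n), n_groups = length(x$n))
}

#' @rdname km_logrank
#' @param object A `reo_km` object.
#' @method autoplot reo_km
#' @export
autoplot.reo_km <- function(object, ...) {
  curves <- tidy(object)
  # prepend time 0 / survival 1 per group so steps start at the origin
  origins <- dplyr::distinct(curves, .data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  cens <- dplyr::filter(curves, .data$n_censor > 0)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$group)) +
    ggplot2::geom_step(data = dplyr::bind_rows(origins, curves)) +
    ggplot2::geom_point(data = cens, shape = 3, size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability", colour = "risk group",
      subtitle = sprintf("log-rank chi2 = %.2f, p = %.2g", object$chi2, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Univariate or multivariate Cox proportional-hazards fit
#'
#' Fits `h(t, x) = h0(t) exp(beta_1 x_1 + ... + beta_n x_n)` by partial
#' likelihood ([survival::coxph()], Efron tie handling) and reports, per
#' covariate, the coefficient, hazard ratio `exp(beta)`, Wald-type 95% CI
#' (`beta +- 1.96 SE` on the log scale) and Wald p-value. In univariate mode
#' each covariate is fitted in its own model; in multivariate mode all enter
#' jointly.
#'
#' Monotone-likelihood fits (complete separation, e.g. a risk group with no
#' events) are not errors: the affected terms are flagged
#' (`flag = "separation"`) and their effectively infinite hazard ratios and
#' unbounded CIs returned as computed, since this regime occurs in real
#' cohorts where one group has no events.
#'
#' @param data Data frame, one row per sample.
#' @param covariates Character vector of covariate column names. Character or
#'   factor columns with two levels are coded 0/1 (first level = reference);
#'   numeric columns enter as-is (ordinal stage can be supplied as integers).
#' @param time,event Column names of survival time and event flag.
#' @param mode `"multivariate"` (one joint model) or `"univariate"`.
#' @return Tibble of class `reo_cox_fit`: `term`, `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `flag`, `model`; attributes `n` and
#'   `n_events`.
#' @export
cox_fit <- function(data, covariates, time = "os_time", event = "os_event",
                    mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  require_columns(data, c(time, event, covariates), "survival data")
  d <- data[, c(time, event, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  names(d)[1:2] <- c(".time", ".event")
  check_nonneg_time(d$.time); check_event_flags(d$.event)
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v)) < 2) {
      abort(sprintf("covariate '%s' is constant after removing incomplete rows", cv))
    }
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2) {
        abort(sprintf("covariate '%s' must be numeric or two-level (found %d levels)",
                      cv, length(lev)))
      }
      d[[cv]] <- as.numeric(as.character(v) == lev[2])
    }
  }
  n_events <- sum(d$.event)
  if (n_events < length(covariates) && mode == "multivariate") {
    warn(sprintf("only %d events for %d covariates; estimates may be unstable",
                 n_events, length(covariates)))
  }
  fit_one <- function(covs, model_label) {
    f <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", covs), collapse = " + ")
    ))
    sep_warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(f, data = d, ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w), ignore.case = TRUE)) {
          sep_warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    sm <- summary(fit)$coefficients
    beta <- sm[, "coef"]; se <- sm[, "se(coef)"]
    sep_term <- sep_warned | abs(beta) > 15 | se > 100
    tibble::tibble(
      term = gsub("`", "", rownames(sm)),
      beta = unname(beta), se = unname(se), hr = unname(exp(beta)),
      ci_low = unname(exp(beta - qnorm(0.975) * se)),
      ci_high = unname(exp(beta + qnorm(0.975) * se)),
      p_value = unname(sm[, "Pr(>|z|)"]),
      flag = ifelse(sep_term, "separation", "ok"),
      model = model_label
    )
  }
  out <- if (mode == "multivariate") {
    fit_one(covariates, "multivariate")
  } else {
    purrr::map_dfr(covariates, function(cv) fit_one(cv, "univariate"))
  }
  class(out) <- c("reo_cox_fit", class(out))
  attr(out, "n") <- nrow(d)
  attr(out, "n_events") <- n_events
  out
}

#' @rdname cox_fit
#' @param x A `reo_cox_fit`.
#' @param ... Unused.
#' @method tidy reo_cox_fit
#' @export
tidy.reo_cox_fit <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname cox_fit
#' @method glance reo_cox_fit
#' @export
glance.reo_cox_fit <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
                 n_terms = nrow(x), any_separation = any(x$flag == "separation"))
}
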