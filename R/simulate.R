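# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sign-preserving power: strictly increasing on all reals for p > 0
signed_power <- function(x, p) sign(x) * abs(x)^p

#' Simulate a cohort with planted prognostic gene pairs
#'
#' Generates the data structure the REO analysis assumes, so every pipeline
#' stage can be exercised without external downloads:
#'
#' 1. Background expression on an arbitrary log-intensity scale: per-gene
#'    Gaussian noise (`noise_sd`) around gene means laid out on a grid with
#'    spacing `6 * noise_sd`, so the orderings of background gene pairs are
#'    stable across samples rather than coin flips: the difference of two
#'    adjacent genes has SD `noise_sd * sqrt(2)`, so the per-sample flip
#'    probability of even the closest background pair is ~1e-5 and a cohort
#'    of hundreds of samples is expected to contain no background flips at
#'    all.
#' 2. Planted pairs: for each of `n_planted_pairs` pairs (A, B), the baseline
#'    means satisfy \eqn{E_A > E_B} (gap `pair_mean_gap`); a per-sample
#'    Bernoulli(`risk_prevalence`) risk state swaps the two means, so the
#'    risk ordering is \eqn{E_A < E_B}. With `shared_risk_state = TRUE` one
#'    latent per-sample state (an occult micro-metastasis surrogate) drives
#'    all pairs instead of independent per-pair states.
#' 3. Survival: proportional hazards with baseline hazard `baseline_hazard`
#'    (exponential by default; `weibull_shape` generalises) scaled by
#'    `exp(pair_log_hazard * number of pairs in the risk state)`; independent
#'    exponential censoring whose rate is solved so the expected censored
#'    fraction equals `censoring_rate`. Disease-free survival uses a
#'    recurrence process with 1.5x the death hazard.
#' 4. Methylation: beta values in `[0, 1]`; `n_methyl_coupled_genes` decoy
#'    genes are shifted by `methyl_shift` between true-risk strata, with the
#'    expression of the same gene shifted by `coupled_expr_shift` in the
#'    opposite direction for a fraction `methyl_direction_concordance` of
#'    them (inverse methylation-expression coupling) and the same direction
#'    otherwise.
#' 5. Optional per-batch strictly increasing distortions (affine plus a mild
#'    signed power) when `n_batches > 1`; batch labels go in the clinical
#'    table.
#'
#' The cohort is a pure function of the arguments including `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param n_samples,n_genes Cohort dimensions (default 400 x 60).
#' @param n_planted_pairs Planted prognostic pairs (default 5); requires
#'   `2 * n_planted_pairs <= n_genes`.
#' @param pair_log_hazard Per-pair log hazard ratio of the risk state
#'   (default 1.2).
#' @param baseline_hazard Baseline event rate per time unit (default 0.05).
#' @param censoring_rate Target censored fraction in `[0, 1)` (default 0.3).
#' @param risk_prevalence Per-sample probability of the risk state (0.5).
#' @param shared_risk_state One latent state drives all pairs (default FALSE).
#' @param noise_sd Within-gene SD on the log-intensity scale (default 0.3).
#' @param pair_mean_gap Mean separation of a planted pair (default 1.2).
#' @param n_methyl_coupled_genes Decoy genes with methylation-expression
#'   coupling (default 30).
#' @param methyl_shift Beta-value shift between risk strata (default 0.2,
#'   clipped to keep beta in `[0, 1]`).
#' @param methyl_direction_concordance Fraction of coupled genes with inverse
#'   coupling (default 0.9).
#' @param coupled_expr_shift Expression shift of coupled genes (default 0.15,
#'   half the noise SD: a clear rank-sum DEG signal at cohort scale, yet far
#'   below the `2 * noise_sd` spacing of the background mean grid, so coupled
#'   genes do not flip between-gene orderings and stay decoys for the pair
#'   screen).
#' @param weibull_shape Shape of the baseline time distribution (1 =
#'   exponential).
#' @param n_batches Number of measurement batches (default 1 = no batch
#'   effects).
#' @param seed Integer seed; the cohort is reproducible from it.
#' @return An object of class `synthetic_cohort`: list with `expression`,
#'   `methylation`, `clinical` tibbles, a `truth` list (planted pairs with
#'   orientations, per-sample risk-state matrix, `true_risk`, coupled genes
#'   with directions) and the resolved `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_samples = 40, n_genes = 12, n_planted_pairs = 2,
#'                        n_methyl_coupled_genes = 4, seed = 7)
#' coh$clinical
simulate_cohort <- function(n_samples = 400, n_genes = 60, n_planted_pairs = 5,
                            pair_log_hazard = 1.2, baseline_hazard = 0.05,
                            censoring_rate = 0.3, risk_prevalence = 0.5,
                            shared_risk_state = FALSE, noise_sd = 0.3,
                            pair_mean_gap = 1.2, n_methyl_coupled_genes = 30,
                            methyl_shift = 0.2,
                            methyl_direction_concordance = 0.9,
                            coupled_expr_shift = 0.15, weibull_shape = 1,
                            n_batches = 1, seed = 1) {
  if (n_samples < 2 || n_genes < 2) abort("need at least 2 samples and 2 genes")
  if (2 * n_planted_pairs > n_genes) {
    abort("infeasible config: planted pairs need 2 genes each (2 * n_planted_pairs <= n_genes)")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) abort("censoring_rate must lie in [0, 1)")
  if (risk_prevalence < 0 || risk_prevalence > 1) abort("risk_prevalence must lie in [0, 1]")
  if (methyl_direction_concordance < 0 || methyl_direction_concordance > 1) {
    abort("methyl_direction_concordance must lie in [0, 1]")
  }
  n_decoys <- n_genes - 2 * n_planted_pairs
  if (n_methyl_coupled_genes > n_decoys) {
    abort("n_methyl_coupled_genes exceeds the number of non-planted genes")
  }
  config <- list(
    n_samples = n_samples, n_genes = n_genes, n_planted_pairs = n_planted_pairs,
    pair_log_hazard = pair_log_hazard, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, risk_prevalence = risk_prevalence,
    shared_risk_state = shared_risk_state, noise_sd = noise_sd,
    pair_mean_gap = pair_mean_gap,
    n_methyl_coupled_genes = n_methyl_coupled_genes,
    methyl_shift = methyl_shift,
    methyl_direction_concordance = methyl_direction_concordance,
    coupled_expr_shift = coupled_expr_shift, weibull_shape = weibull_shape,
    n_batches = n_batches, seed = seed
  )
  with_local_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%04d", seq_len(n_samples))

    # gene means on a grid with spacing 6 * noise_sd; each planted pair takes
    # two adjacent slots and sits at their midpoint +- pair_mean_gap / 2, so
    # no background gene comes close to a planted mean in either risk state
    grid <- (seq_len(n_genes) - 1) * 6 * noise_sd
    planted_genes <- if (n_planted_pairs > 0) sample(genes, 2 * n_planted_pairs) else character()
    pair_a <- planted_genes[seq_len(n_planted_pairs) * 2 - 1]
    pair_b <- planted_genes[seq_len(n_planted_pairs) * 2]
    mu <- setNames(numeric(n_genes), genes)
    if (n_planted_pairs > 0) {
      slot <- floor(seq(1, n_genes - 1, length.out = n_planted_pairs))
      if (n_planted_pairs > 1) {
        for (j in 2:n_planted_pairs) slot[j] <- max(slot[j], slot[j - 1] + 2)
      }
      centres <- (grid[slot] + grid[slot + 1]) / 2
      mu[pair_a] <- centres + pair_mean_gap / 2   # baseline E_A > E_B
      mu[pair_b] <- centres - pair_mean_gap / 2
      free_slots <- setdiff(seq_len(n_genes), c(slot, slot + 1))
      mu[setdiff(genes, planted_genes)] <- sample(grid[free_slots])
    } else {
      mu[] <- sample(grid)
    }

    # per-sample per-pair risk states
    risk_states <- matrix(0L, nrow = max(n_planted_pairs, 1), ncol = n_samples)
    if (n_planted_pairs > 0) {
      if (shared_risk_state) {
        z <- rbinom(n_samples, 1, risk_prevalence)
        risk_states <- matrix(rep(z, each = n_planted_pairs), nrow = n_planted_pairs)
      } else {
        risk_states <- matrix(rbinom(n_planted_pairs * n_samples, 1, risk_prevalence),
                              nrow = n_planted_pairs)
      }
      rownames(risk_states) <- paste(pair_a, pair_b, sep = "|")
      colnames(risk_states) <- samples
    }
    n_risk <- if (n_planted_pairs > 0) colSums(risk_states) else rep(0L, n_samples)
    true_risk <- n_risk >= ceiling(max(n_planted_pairs, 1) / 2) & n_planted_pairs > 0

    # mean matrix: background means, planted-pair swaps, coupled-gene shifts
    mu_mat <- matrix(rep(mu, n_samples), nrow = n_genes,
                     dimnames = list(genes, samples))
    if (n_planted_pairs > 0) {
      for (j in seq_len(n_planted_pairs)) {
        flip <- risk_states[j, ] == 1
        mu_mat[pair_a[j], flip] <- mu[pair_b[j]]
        mu_mat[pair_b[j], flip] <- mu[pair_a[j]]
      }
    }

    decoys <- setdiff(genes, planted_genes)
    coupled <- if (n_methyl_coupled_genes > 0) sample(decoys, n_methyl_coupled_genes) else character()
    meth_dir <- sample(c("up", "down"), length(coupled), replace = TRUE)
    inverse <- runif(length(coupled)) < methyl_direction_concordance
    expr_dir <- ifelse(inverse, ifelse(meth_dir == "up", "down", "up"), meth_dir)
    if (length(coupled) > 0 && any(true_risk)) {
      shift <- ifelse(expr_dir == "up", coupled_expr_shift, -coupled_expr_shift)
      mu_mat[coupled, true_risk] <- mu_mat[coupled, true_risk] + shift
    }

    expr_m <- mu_mat + matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                              nrow = n_genes)

    # survival under proportional hazards
    h <- baseline_hazard * exp(pair_log_hazard * n_risk)
    t_death <- (rexp(n_samples) / h)^(1 / weibull_shape)
    t_recur <- (rexp(n_samples) / (1.5 * h))^(1 / weibull_shape)
    if (censoring_rate > 0) {
      cens_rate <- uniroot(
        function(r) mean(1 - exp(-exp(r) * t_death)) - censoring_rate,
        lower = log(1e-10), upper = log(1e8)
      )$root
      t_cens <- rexp(n_samples, rate = exp(cens_rate))
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    os_time <- pmin(t_death, t_cens)
    os_event <- as.integer(t_death <= t_cens)
    dfs_raw <- pmin(t_recur, t_death)
    dfs_time <- pmin(dfs_raw, t_cens)
    dfs_event <- as.integer(dfs_raw <= t_cens)

    stage <- ifelse(
      true_risk,
      sample(c("I", "II", "III", "IV"), n_samples, replace = TRUE,
             prob = c(0.10, 0.30, 0.35, 0.25)),
      sample(c("I", "II", "III", "IV"), n_samples, replace = TRUE,
             prob = c(0.30, 0.35, 0.25, 0.10))
    )
    grade <- ifelse(
      true_risk,
      sample(paste("grade", 1:3), n_samples, replace = TRUE, prob = c(0.15, 0.35, 0.50)),
      sample(paste("grade", 1:3), n_samples, replace = TRUE, prob = c(0.40, 0.35, 0.25))
    )
    clinical <- tibble::tibble(
      sample_id = samples,
      os_time = os_time, os_event = os_event,
      dfs_time = dfs_time, dfs_event = dfs_event,
      stage = stage, grade = grade,
      age = pmin(pmax(round(rnorm(n_samples, 67, 9)), 35), 90),
      gender = sample(c("male", "female"), n_samples, replace = TRUE,
                      prob = c(0.75, 0.25)),
      batch = paste0("b", rep_len(seq_len(n_batches), n_samples))
    )
    clinical <- harmonize_grade(clinical, "three_level")
    attr(clinical, "time_unit") <- "months"

    # batch effects: strictly increasing per-batch affine + mild signed power
    if (n_batches > 1) {
      for (bi in seq_len(n_batches)) {
        idx <- clinical$batch == paste0("b", bi)
        a <- runif(1, 0.5, 3); b <- runif(1, -2, 6); p <- runif(1, 0.85, 1.15)
        expr_m[, idx] <- b + a * signed_power(expr_m[, idx], p)
      }
    }

    # methylation beta values, coupled genes shifted between risk strata
    beta_base <- runif(n_genes, 0.15, 0.70)
    names(beta_base) <- genes
    meth_m <- matrix(rep(beta_base, n_samples), nrow = n_genes,
                     dimnames = list(genes, samples)) +
      matrix(rnorm(n_genes * n_samples, sd = 0.05), nrow = n_genes)
    if (length(coupled) > 0 && any(true_risk)) {
      mshift <- ifelse(meth_dir == "up", methyl_shift, -methyl_shift)
      meth_m[coupled, true_risk] <- meth_m[coupled, true_risk] + mshift
    }
    meth_m <- pmin(pmax(meth_m, 0), 1)

    truth <- list(
      pairs = tibble::tibble(gene_a = pair_a, gene_b = pair_b,
                             risk_orientation = rep("A_lt_B", n_planted_pairs)),
      risk_states = if (n_planted_pairs > 0) risk_states else NULL,
      true_risk = setNames(true_risk, samples),
      coupled_genes = tibble::tibble(gene = coupled, meth_direction = meth_dir,
                                     expr_direction = expr_dir,
                                     inverse_coupled = inverse)
    )
    structure(
      list(expression = as_assay_tibble(expr_m),
           methylation = as_assay_tibble(meth_m),
           clinical = clinical, truth = truth, config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d samples x %d genes, %d planted pair(s), log-HR %.2f, %.0f%% censoring target, seed %d>\n",
    x$config$n_samples, x$config$n_genes, x$config$n_planted_pairs,
    x$config$pair_log_hazard, 100 * x$config$censoring_rate, x$config$seed
  ))
  invisible(x)
}

#' Apply a measurement distortion to an expression matrix
#'
#' Three distortion families mirror the disturbances a qualitative
#' rank-based classifier is claimed to resist:
#'
#' * `batch_affine` — a strictly increasing per-sample transform
#'   `offset + scale * sign(x) |x|^power` (scale > 0, power > 0): a batch /
#'   normalisation effect. Being monotone within each sample, it provably
#'   leaves every REO call unchanged.
#' * `degradation` — additive Gaussian noise of SD `sigma` on the
#'   (log-intensity) values: partial RNA degradation during storage. Not
#'   monotone; classifier agreement with the clean matrix is the quantity of
#'   interest.
#' * `subsample_cells` — tumour-purity dilution: each sample is mixed toward
#'   the cohort-average profile, `purity * x + (1 - purity) * reference`,
#'   plus small noise — varied tumour-cell proportions in the specimen.
#'
#' @param expr Expression tibble (first column `gene`).
#' @param kind `"batch_affine"`, `"degradation"`, or `"subsample_cells"`.
#' @param params Named list of parameters: `scale`, `offset`, `power`
#'   (batch_affine; scalars or per-sample vectors), `sigma` (degradation,
#'   default 0.2), `purity` or `min_purity` (subsample_cells, default range
#'   0.6-1), `sigma` (subsample_cells noise, default 0.05).
#' @param seed Optional integer seed for the random draws.
#' @return A distorted copy of `expr` (same shape and dimnames).
#' @export
apply_distortion <- function(expr, kind = c("batch_affine", "degradation", "subsample_cells"),
                             params = list(), seed = NULL) {
  kind <- match.arg(kind)
  m <- as_assay_matrix(expr, "expression")
  n <- ncol(m)
  run <- function() {
    if (kind == "batch_affine") {
      scale <- rep_len(params$scale %||% runif(n, 0.5, 5), n)
      offset <- rep_len(params$offset %||% runif(n, -5, 15), n)
      power <- rep_len(params$power %||% 1, n)
      if (any(scale <= 0)) abort("batch_affine scale must be > 0 (monotone transform)")
      if (any(power <= 0)) abort("batch_affine power must be > 0 (monotone transform)")
      out <- m
      for (j in seq_len(n)) out[, j] <- offset[j] + scale[j] * signed_power(m[, j], power[j])
      out
    } else if (kind == "degradation") {
      sigma <- params$sigma %||% 0.2
      if (sigma < 0) abort("degradation sigma must be >= 0")
      m + matrix(rnorm(length(m), sd = sigma), nrow = nrow(m))
    } else {
      purity <- rep_len(params$purity %||% runif(n, params$min_purity %||% 0.6, 1), n)
      if (any(purity < 0 | purity > 1)) abort("purity must lie in [0, 1]")
      sigma <- params$sigma %||% 0.05
      ref <- rowMeans(m, na.rm = TRUE)
      out <- sweep(m, 2, purity, `*`) + outer(ref, 1 - purity)
      out + matrix(rnorm(length(m), sd = sigma), nrow = nrow(m))
    }
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  dimnames(out) <- dimnames(m)
  as_assay_tibble(out)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expr.tsv`, `meth.tsv`, `clinical.tsv` and `truth.json` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$expression, file.path(dir, "expr.tsv"))
  readr::write_tsv(cohort$methylation, file.path(dir, "meth.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$true_risk <- as.list(truth$true_risk)
  truth$risk_states <- if (is.null(truth$risk_states)) NULL else
    as.data.frame(t(truth$risk_states))
  jsonlite::write_json(list(truth = truth, config = cohort$config),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
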