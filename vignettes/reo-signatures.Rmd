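---
title: "Rank-based gene-pair signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The model

`reopair` is built around one qualitative primitive: the **relative
expression ordering (REO)** of two genes A and B within a single sample,
`E_A > E_B` or `E_A < E_B`. The REO is a rank statistic of one sample's own
measurements, so it is invariant to any strictly increasing transform of
that sample — normalisation, log-scaling, batch rescaling, and the
monotone components of degradation and amplification bias all leave it
unchanged. This is the premise that makes REO signatures applicable to a
single patient profiled in any laboratory, and the package treats it as a
testable property rather than a slogan: the test suite checks bit-identity
of risk calls under random per-sample affine and signed-power transforms.

A **gene-pair signature** is an ordered list of pairs, each with a *risk
orientation* — the ordering that votes for high risk. Classification is
majority voting: a sample with `votes_high >= ceiling(n_pairs / 2)` risk
votes is high-risk, otherwise low-risk ("at least half of the pairs"). An
optional second threshold splits the high-risk group into middle-high and
highest tiers; the packaged 12-pair bladder-carcinoma signature uses 6 and
9 of 12. Undefined REOs (a missing value or an exact tie) never vote for
high risk; see "Numerical choices" for the denominator policy.

### Signature discovery

Discovery reproduces the classical three-stage design on any
expression-plus-survival cohort:

1. **Gene filter.** A univariate Cox proportional-hazards model per gene,
   with the continuous expression value as covariate; Benjamini–Hochberg
   adjustment across genes; genes with FDR below `gene_fdr` (default 5%)
   are retained.
2. **Pair screen.** For every unordered pair of retained genes, samples are
   split by the pair's REO pattern and the binary indicator is tested by
   univariate Cox regression; BH across all *tested* pairs (pairs with a
   single pattern across the cohort are untestable and skipped); survivors
   (FDR below `pair_fdr`, default 1%) record the orientation of the
   higher-hazard group, the absolute Cox coefficient, and the individual
   concordance index of their own two-group split.
3. **Forward selection.** Candidates ranked by individual C-index
   (descending; ties broken by smaller Cox p, then gene names, so discovery
   is deterministic without any seed). The top pair seeds the signature;
   each subsequent candidate is tentatively added, the cohort reclassified
   under the majority-vote rule with threshold `ceiling(current_size / 2)`,
   and the pair kept only if the ensemble C-index strictly improves.

The BH step in stage 2 runs over strongly dependent tests (pairs share
genes); this mirrors standard practice for this design and is deliberate.

### Survival machinery

The group-label **concordance index** follows the verbal definition for a
binary marker: among all (high, low) sample pairs, a pair is *usable* when
the two times differ and the earlier time is an observed event; it is
*concordant* when the high-risk member has the earlier event. Pairs whose
earlier time is censored are not orderable under right censoring and are
excluded, as are tied times — the standard Harrell convention. The raw
proportion is reflected, `c = max(c_raw, 1 - c_raw)`, so the reported value
lies on the conventional [0.5, 1] scale; the raw value is kept in the
result so a worse-than-chance labelling remains visible. The fast
implementation counts orderable pairs against sorted opposite-group times;
the tests require exact count agreement with an O(n²) enumeration oracle on
a thousand random censored datasets.

Kaplan–Meier estimation, the log-rank test, and Cox fitting delegate to the
`survival` package (Efron tie handling; Wald-type 95% intervals
`exp(beta ± 1.96 SE)`). Monotone-likelihood fits — e.g. a risk group with no
events, which genuinely occurs in small validation cohorts and produces
astronomical hazard ratios with [0, Inf) intervals — are flagged
(`flag = "separation"`) rather than raised as errors or silently clipped.

### Concordance statistics

Two directional gene lists with `k` overlapping genes of which `s` agree
give a concordance score `s/k`. Agreement is direction-equality for two
differential-expression lists and direction-opposition for methylation
versus expression (hypermethylation pairing with underexpression). The
chance model is Binomial(k, p0) with p0 = 0.5 by default (exposed as a
parameter); the p-value is the exact upper tail
`P(X >= s) = 1 - sum_{i<s} C(k,i) p0^i (1-p0)^(k-i)`.

## Numerical choices

* **Binomial tails in log space.** The tail is summed as
  `logsumexp(lchoose(k, i) + i log p0 + (k-i) log(1-p0))`, never via the
  complement, so `k = 800, s = 797` yields ~1.3e-233 instead of an
  underflown 0 or a complement rounded to 1. `s = 0` returns exactly 1.
* **Score rounding.** Percentages are rounded half-away-from-zero at two
  decimals, computed from the integer ratio (`100·s·10²/k`) so that exact
  halves such as 797/800 → 99.625% round predictably to 99.63%.
* **Expression ties.** Exact ties vote neither orientation. By default they
  stay in the vote denominator (an abstention is conservatively a low
  vote, `undefined_votes = "count_as_low"`); the alternative `"exclude"`
  removes them and flags samples with no defined REO at all as
  unclassifiable. Both policies exist because the original design leaves
  the denominator unstated; the default is documented and conservative
  toward low risk (ties cluster at zero in FPKM data).
* **"At least half" with an even pair count** means `votes_high >= n/2`
  (6 of 12), matching the published rule.
* **Stopping policy.** "Add pairs until no addition improves" admits two
  readings. The default `scan_all` skips a non-improving candidate and
  continues down the ranked list; `stop_at_first_failure` stops at the
  first failure. Both are one flag apart and the chosen policy is recorded
  in the signature metadata. Neither revisits rejected pairs nor removes
  accepted ones.
* **Stage as a covariate.** Ordinal-numeric coding (I..IV → 1..4) in the
  adjusted models, with any numeric or two-level covariate accepted by
  `cox_fit()`; a categorical treatment can be had by passing dummy
  columns. Grade adjustment uses the harmonised binary grade: under a
  three-level system, grade 1 → low, grade 3 → high, grade 2 → excluded
  (the ambiguous middle grade is dropped rather than forced onto either
  anchor).
* **Probe collapsing** averages probes per gene and per sample, ignoring
  missing cells; it is permutation-invariant and idempotent. Missing
  expression is never imputed — a missing value simply abstains at
  classification time.
* **DMG/DEG direction** is the sign of the high-minus-low difference of
  medians (robust for bounded beta values); a mean-difference option is
  provided. Constant rows get p = 1, not an error.
* **Survival-time units** are metadata (`time_unit` attribute), never
  converted; the package does not pool tables with unstated units.

## The synthetic-cohort generator

`simulate_cohort()` generates the joint structure the analysis assumes,
with a recoverable ground truth. Defaults describe the study condition
used throughout the tests: 400 samples, 60 genes of which 5 planted pairs
(10 genes), per-pair log hazard ratio 1.2, exponential baseline hazard
0.05 per month, target censoring fraction 0.30, within-gene noise SD 0.3
on an arbitrary log-intensity scale.

* **Background stability.** Gene means sit on a grid with spacing 6× the
  noise SD. The difference of two adjacent genes has SD `noise_sd·√2`, so
  the closest background pair flips ordering with probability ~1e-5 — a
  400-sample cohort is expected to contain no background flips. This is
  what "sample-stable background REOs" has to mean at this cohort size:
  with narrower spacing, chance flips in a handful of samples produce
  spurious survival associations whose tiny high groups post extreme
  C-indexes and derail forward selection — a hazard of the ranking
  heuristic worth knowing about on real data, but not part of the planted
  recovery experiment.
* **Planted pairs.** Each planted pair occupies two adjacent grid slots
  and its genes sit at the slots' midpoint ± half the pair gap (1.2 =
  4 SD), so the baseline ordering `E_A > E_B` holds with ~99.8%
  fidelity, every background mean stays ≥ 7 SD away from either planted
  mean in either state, and a per-sample Bernoulli(0.5) risk state swaps
  the two means to produce the risk ordering `E_A < E_B`. States are
  independent per pair by default; `shared_risk_state = TRUE` makes one
  latent per-sample state (an occult-micro-metastasis surrogate) drive
  all pairs.
* **Survival.** Proportional hazards: `h = h0 · exp(1.2 · #risk states)`,
  exponential baseline (Weibull shape exposed), independent exponential
  censoring whose rate is solved by `uniroot` so the expected censored
  fraction matches the configured target; recurrence (for the
  disease-free endpoint) runs at 1.5× the death hazard.
* **Methylation coupling.** 30 of the 50 non-planted genes carry a
  beta-value shift of 0.2 between true-risk strata; for 90% of them the
  expression of the same gene shifts in the opposite direction
  (hypermethylated ↔ underexpressed), same direction otherwise. The
  expression shift is 0.15 — half the noise SD: a clear rank-sum
  differential-expression signal at n = 400 (Cohen's d = 0.5), yet far
  below the 1.8-unit grid spacing, so coupled genes never flip
  between-gene orderings and remain decoys for the pair screen. This
  separation is intentional: the coupling exists to exercise the
  DEG–DMG concordance analysis, not to plant additional REO signal.
* **Distortions.** `apply_distortion()` implements a strictly increasing
  per-sample batch transform (affine plus signed power — provably
  REO-preserving, and tested as such), additive log-scale noise
  (degradation), and purity dilution (linear mixing toward the cohort
  average profile — *not* monotone, so classifier agreement with clean
  data is the reported quantity).

### What the generator does and does not show

Passing the planted-recovery and calibration suites shows the pipeline is
*correct*: it finds the signal it is supposed to find, orients it
correctly, controls its false-discovery behaviour on null data, and is
exactly rank-invariant. It does **not** show that real cohorts contain
such signal. The generator makes no attempt to imitate real marginal
expression distributions, gene–gene correlation, shared-pathway
co-regulation, or informative censoring; real background REOs are stable
for most but not all gene pairs, and real effect sizes are smaller and
heterogeneous. Published headline numbers from real cohorts (hazard ratios
in the tens, ensemble C-index ≈ 0.8, specific gene lists) depend on those
data and are not reproduced by simulation.

## Problem sizes used by the test and acceptance suites

Chosen to make the statistical checks sharp while keeping a full run in a
few minutes on one CPU: 1000 random censored datasets (n ≤ 200) for the
C-index oracle sweep; 20 default cohorts for planted recovery (median
recovered pairs and orientation accuracy); 100 random cohorts for rank
invariance; 50 replicates × 1000 null genes at n = 200 (plus 10 × 780
null pairs) for screen calibration, where the raw type-I rate is required
to sit within a factor two of nominal and the BH-filtered fraction is
bounded above — under a global null the BH rejection *rate* is far below
the FDR level (BH controls the false-discovery proportion, not the
rejection rate), so an upper bound is the meaningful calibration check.

## Known limitations

* Discovery assumes the cohort fits in memory and tests all
  `m(m-1)/2` pairs of retained genes; for m in the hundreds this is fine,
  for thousands a pre-filter would be needed.
* The C-index here is the binary-group version; no time-dependent ROC, no
  per-sample risk scores (the method is deliberately qualitative), no
  competing risks, no time-dependent covariates.
* Forward selection is a greedy heuristic with no backtracking; it can
  stop short of the best subset, and its ranking is vulnerable to
  extreme-C-index candidates from heavily unbalanced REO splits (rare on
  stable data, but real); candidate tables expose the group sizes needed
  to audit this.
* The differential-expression screen is a plain rank-sum stand-in;
  dedicated callers (moderated statistics, permutation-based methods) can
  be substituted upstream, and their directional lists consumed directly.
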