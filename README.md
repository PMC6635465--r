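# reopair

Qualitative prognostic classification from **within-sample relative
expression orderings (REOs)** of gene pairs, for survival cohorts profiled
by RNA-seq or microarray.

Quantitative prognostic scores (weighted sums of expression values) are
fragile in the clinic: batch effects, normalisation choices, varying
tumour-cell content and partial RNA degradation all move the score. A
REO-based classifier uses only the *ordering* of two genes measured in the
same sample — is gene A expressed above or below gene B? — which is
unchanged by any strictly increasing transform of that sample's
measurements. `reopair` implements the full life cycle of such signatures:

* **Classification.** A signature is an ordered list of gene pairs, each
  with a risk orientation (which ordering votes "high risk"). A sample with
  at least half the pairs voting high risk is called high-risk; an optional
  second threshold defines a highest-risk tier. The packaged
  [`twelve_gps()`](R/signature.R) bladder-carcinoma signature uses 12 pairs
  with thresholds 6 (high) and 9 (highest): a patient is high-risk when
  Count(E_A < E_B) ≥ 6.
* **Discovery.** From an expression matrix and right-censored survival
  data: (1) univariate Cox proportional-hazards filter per gene
  (Benjamini–Hochberg FDR < 5%); (2) for every pair of retained genes,
  samples are split by the pair's REO pattern and the split is tested by
  univariate Cox regression (FDR < 1%); (3) candidates are ranked by their
  individual concordance index and greedily forward-selected under the
  majority-vote rule, keeping a pair only if the ensemble C-index strictly
  improves.
* **Evaluation.** Kaplan–Meier curves and log-rank tests, univariate and
  covariate-adjusted Cox models h(t,x) = h0(t)·exp(β₁x₁ + … + βₙxₙ), and a
  group-label concordance index: the fraction of usable (high, low) sample
  pairs in which the high-risk patient has the earlier observed event,
  reported on [0.5, 1].
* **Concordance statistics.** For two directional gene lists with k
  overlapping genes of which s agree (same-direction for two
  differential-expression lists, inverse for methylation vs expression),
  the concordance score is s/k with an exact cumulative-binomial p-value
  P(X ≥ s), X ~ Binomial(k, 0.5), computed in log space so that extreme
  tails (k = 800) do not underflow. Wilcoxon rank-sum screens for
  differentially methylated/expressed genes, Fisher's exact test for
  mutation/copy-number frequencies, and conflict-aware list pooling round
  out the module.
* **Synthetic cohorts.** `simulate_cohort()` generates expression,
  methylation, and right-censored survival data with *planted* prognostic
  pairs whose per-sample risk states scale the hazard, so every pipeline
  stage can be validated against a known truth without external data.

## Worked example

```r
library(reopair)

cohort <- simulate_cohort(n_samples = 300, seed = 42)   # 60 genes, 5 planted pairs
signature <- discover_signature(cohort$expression, cohort$clinical)
#> discovery: 27 prognostic gene(s) at FDR < 0.05
#> discovery: 5 candidate pair(s) at FDR < 0.01 (of 5 tested)
#> discovery: final signature has 4 pair(s), ensemble C-index 0.905

signature
#> <gene_pair_signature: 4 pairs, high-risk >= 2 votes>
#> # A tibble: 4 x 5
#>   gene_a gene_b risk_orientation  beta c_index
#> 1 g0024  g0047  A_gt_B           1.04    0.750
#> 2 g0037  g0049  A_gt_B           0.823   0.717
#> 3 g0010  g0036  A_lt_B           0.784   0.691
#> 4 g0001  g0025  A_lt_B           0.586   0.671

calls <- classify_cohort(cohort$expression, signature)
dplyr::count(calls, tier)
#>   tier      n
#> 1 high    195
#> 2 low     105

d <- dplyr::left_join(calls, cohort$clinical, by = "sample_id")
km_logrank(d, time = "os_time", event = "os_event", group = "tier")
#> Log-rank: chi2 = 112.830 on 1 df, p = 2.35e-26 (groups: high n=195, low n=105)
c_index_groups(d, time = "os_time", event = "os_event", group = "tier")
#> C-index 0.9050 (raw 0.9050; 13889 concordant / 15347 usable pairs; 195 high, 105 low)
```

The four discovered pairs are four of the five planted pairs of this
cohort, with their planted risk orientations; the ensemble C-index 0.905 is
the two-group concordance of the majority vote. The risk call stays
significant after adjusting for stage, age and gender:

```r
d <- dplyr::mutate(d,
  risk_high = as.integer(tier == "high"),
  stage_num = as.integer(factor(stage, levels = c("I", "II", "III", "IV"))))
tidy(cox_fit(d, c("risk_high", "stage_num", "age", "gender")))
#>   term          beta      se    hr ci_low ci_high  p_value flag  model
#> 1 risk_high  1.77    0.188   5.86   4.06     8.47 4.21e-21 ok    multivariate
#> 2 stage_num  0.0553  0.0683  1.06   0.924    1.21 4.19e- 1 ok    multivariate
#> 3 age        0.00339 0.00757 1.00   0.989    1.02 6.54e- 1 ok    multivariate
#> 4 gender    -0.0933  0.164   0.911  0.660    1.26 5.70e- 1 ok    multivariate
```

The adjusted hazard ratio of 5.86 (95% CI 4.06–8.47) says the high-risk
call carries prognostic information beyond the clinical covariates — as it
must here, since the simulated hazard is driven by the planted pair states
the signature recovers. `autoplot()` methods draw the Kaplan–Meier curves
(`autoplot(km_logrank(...))`) and the vote distribution
(`autoplot(calls)`), and `run_reo_pipeline(out_dir, seed)` executes the
whole simulate → discover → classify → evaluate → concordance workflow into
a reproducible artifact directory.

Applying a published signature is one call: `classify_cohort(expr,
twelve_gps(), three_tier = TRUE)` on any matrix containing the 24 signature
genes, in any units.

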