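Package: reopair
Title: Rank-Based Gene-Pair Prognostic Signatures from Within-Sample
    Relative Expression Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates qualitative prognostic classifiers based on
    within-sample relative expression orderings (REOs) of gene pairs. A sample
    is classified by majority vote over a signature of ordered gene pairs, so
    the prediction depends only on which of two genes is expressed higher
    within that sample and is invariant to any strictly increasing transform
    of its measurements (normalisation, batch scaling, partial degradation).
    Provides a signature-discovery algorithm (per-gene proportional-hazards
    filter, all-pairs REO screen, concordance-index-driven greedy forward
    selection), survival evaluation (Kaplan-Meier, log-rank, Cox models, a
    group-label concordance index), concordance-score statistics linking
    differential expression and DNA methylation, and a synthetic-cohort
    generator with planted prognostic pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
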