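Package: rnaloopkit
Title: RNA Loop-Motif Dataset Construction and Inverse-Folding Benchmark Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds loop-motif datasets from RNA secondary structures and scores
    inverse-folding (RNA design) tools against them. Parses dot-bracket, BPSEQ, CT
    and Stockholm/WUSS formats; merges multi-annotator base-pair lists into a
    conflict-free consensus with an agreement category; removes pseudoknots by
    maximum nested-subset selection; decomposes nested structures into stems,
    hairpins, internal loops and n-way junctions; emits three design-target
    instances per loop (isolated loop, loop with connecting stems, full
    structure). Provides benchmark metrics (base-pair F1, Zhang-Shasha tree edit
    distance with length normalisation, failure-aware aggregation, pairwise
    one-sided Wilcoxon signed-rank matrices), wrappers for the ViennaRNA
    command-line tools, and a stratified cross-validation harness for
    junction-feature classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    class,
    rpart,
    e1071,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
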