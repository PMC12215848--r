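# rnaloopkit

Build loop-motif datasets from RNA secondary structures and benchmark
inverse-folding (RNA design) tools against them.

RNA secondary structure decomposes into stems (maximal helices), hairpins,
internal loops and *n*-way junctions — loops from which *n* ≥ 3 helices
emanate. Multibranch loops are the regions design algorithms struggle with
most, which makes curated loop-motif collections valuable both as design
benchmarks and as machine-learning training data. `rnaloopkit` is for
computational RNA scientists who need to (a) turn raw structure sources —
Stockholm seed alignments with WUSS consensus lines, or per-chain base-pair
lists from multiple annotation programs — into clean per-loop records with
three design-target instances each, and (b) score design tools against those
targets with standard metrics and statistics.

## What it computes

**Dataset construction.** Two routes converge on the same record schema.
From alignments: consensus pairs are projected onto each ungapped row (a
pair survives iff both columns do), pseudoknots are removed by selecting a
maximum-cardinality nested subset of pairs (dynamic programming, provably
optimal, deterministic tie-breaks), and every loop of order ≥ 2 becomes one
record. From annotator outputs: chains are screened
(multistrand/gapped/empty), then pairs are merged by agreement level — a
pair enters the consensus iff it shares no residue with a pair already
accepted, walking from unanimous support downward — and the record carries
an agreement category (minimum support among retained pairs; with seven
annotators, 7 = unanimous). Each record stores three instances: the isolated
loop, the loop with its connecting stems, and the full structure, with 3-nt
`N` caps spliced over excised subtrees so every fragment stays foldable.

**Benchmark evaluation.** Designs are refolded (ViennaRNA `RNAfold`
wrapper) and compared with the target by base-pair F1 (exact pair identity)
and Zhang–Shasha tree edit distance — native C++, cost table calibrated to
reproduce the reference `RNAdistance` binary — normalised by target length
(d/L). Failures take the worst value (+∞ for distances, 0 for F1) so a
failing tool loses that comparison, and tools are ranked with one-sided
Wilcoxon signed-rank matrices (exact under ties for n ≤ 25, including the
infinity convention). The multi-target selection rule
P<sub>t</sub> = exp((EE − E<sub>t</sub>)/RT), choose max ΣP<sub>t</sub> then
min MFE, is included.

**Classification harness.** 3-way-junction records become feature vectors
(the three per-strand unpaired counts) with a family label; a seeded,
exactly stratified k-fold harness reports macro-F1 for kNN (k = 3), a
decision tree and naive Bayes, with an optional group-aware split that keeps
whole families out of the training fold.

## Worked example

```r
library(rnaloopkit)

ss <- parse_dotbracket("((..((...))..((...))..))",
                       sequence = "GGAAGGAAACCAAGGAAACCAACC")
decompose_loops(ss)[, c("loop_class", "order", "closing_i", "closing_j")]
#> # A tibble: 4 × 4
#>   loop_class order closing_i closing_j
#>   <chr>      <int>     <int>     <int>
#> 1 junction       3         2        23
#> 2 hairpin        1         6        10
#> 3 hairpin        1        15        19
#> 4 exterior      NA        NA        NA
```

One 3-way junction closed by pair (2, 23), two hairpins, an empty exterior.
Its three design-target instances:

```r
loops <- decompose_loops(ss)
make_instances(ss, loops[loops$loop_class == "junction", ])
#>              loop_db            loop_stems_db len_loop len_loop_stems len_full
#> 1 (..(...)..(...)..) ((..((...))..((...))..))       12             18       24
```

The isolated loop keeps the closing pair, each child's outermost pair and
the strands (12 original positions; the two `(...)` hairpins are 3-nt caps
standing in for the excised child subtrees). The loop-with-stems instance
adds the full helices (18 positions — 12 stem + 6 strand); here it coincides
with the full structure because each excised hairpin was exactly 3 nt.

Dataset statistics over a generated corpus, and a tool comparison:

```r
set.seed(1)
recs <- purrr::map_dfr(1:50, function(k) {
  s <- generate_random_structure(sample(40:150, 1), seed = k)
  extract_records(s, "rfam", paste0("s", k), "SYN")
})
summarize_records(recs)
#> # A tibble: 4 × 7
#>   loop_type count percent   min   max  mean   std
#>   <chr>     <int>   <dbl> <int> <int> <dbl> <dbl>
#> 1 internal     45   75        5    69  25.3  16.9
#> 2 3way         11   18.3     14    55  33.5  11.4
#> 3 4way          1    1.67    51    51  51     0
#> 4 5way          3    5       18    82  46.3  32.6

wilcoxon_matrix(tibble::tibble(A = c(1,2,3,4,5), B = c(2,3,4,5,6)), "lower")
#> <comparison_matrix> one-sided signed-rank p-values (row better than column), lower is better
#>    A      B
#> A NA 0.0312
#> B  1     NA
```

Counts and mean/min/max/sd are of `len_loop_stems` (the loop plus its
connecting stems); percentages are of all records. In the comparison matrix,
tool A beats B on every one of five cases, the strongest evidence five pairs
can give: p = 1/2⁵ = 0.03125.

A command-line front end over the same functions lives in
`inst/cli/rnaloopkit.R` (`extract`, `build-rfam`, `stats`, `unify`,
`features`, `cv`).

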