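---
title: "Loop motifs, annotation consensus, and inverse-folding benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop motifs, annotation consensus, and inverse-folding benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaloopkit)
library(dplyr)
```

## The problem

RNA molecules fold into secondary structure - a set of base pairs over the
sequence - and the multibranch regions of that structure (internal loops and
n-way junctions, loops from which *n* helices emanate) are both functionally
important and notoriously hard for design algorithms to get right.
`rnaloopkit` builds loop-motif datasets from secondary structures and scores
inverse-folding (RNA design) tools against them. It covers the whole span of
that workflow:

1. **Structure I/O**: dot-bracket (multi-layer), BPSEQ, CT, FASTA, and
   Stockholm seed alignments with WUSS consensus lines.
2. **Structure transforms**: pseudoknot removal by maximum nested-subset
   selection, projection of an alignment-level consensus onto individual
   sequences, chain-suitability screening.
3. **Annotation consensus**: merging the base-pair lists of several
   annotation programs into one conflict-free structure with an agreement
   category.
4. **Motif decomposition**: stems, hairpins, internal loops, n-way junctions,
   and the three design-target instances stored per loop.
5. **Benchmark metrics**: base-pair F1, tree edit distance with length
   normalisation, failure-aware aggregation, pairwise one-sided Wilcoxon
   signed-rank matrices, and wrappers for the ViennaRNA binaries.
6. **A classification harness**: junction feature tables and stratified
   k-fold cross-validation with macro-F1 reporting.

## Core objects

An `rna_structure` is a residue count, a set of 1-based pairs `(i, j)` with
`i < j`, an optional sequence, and a per-pair bracket-layer label. No
position may sit in two pairs; `is_nested()` tells whether any two pairs
cross. Everything record-shaped - dataset rows, metric tables, feature
tables, summaries - is a tibble, so results compose with dplyr.

```{r}
ss <- parse_dotbracket("((..((...))..((...))..))",
                       sequence = "GGAAGGAAACCAAGGAAACCAACC")
ss
decompose_loops(ss) |> select(loop_class, order, closing_i, closing_j)
```

## Two dataset routes

**The alignment route** starts from a Stockholm seed alignment. The WUSS
`SS_cons` line gives column-level consensus pairs; `project_onto_sequence()`
drops gap columns per row and keeps a pair only when both of its columns
survive in that row (half-gapped pairs are dropped, never re-paired - the
conservative choice, since inventing a partner would fabricate structure).
Letter-layer (pseudoknot) pairs are retained through projection and removed
per sequence afterwards; removing them family-wide before projection is also
available (`knot_removal = "before"`), because for heavily gapped rows the
two orders can keep different pairs and we prefer to decide per sequence by
default, where more information is available.

**The annotator route** starts from per-chain base-pair lists produced by
several annotation programs run on experimentally determined structures.
Chains are screened first: `multistrand` (more than one chain id), `gapped`
(non-contiguous author residue numbering - the only gap evidence annotator
outputs carry), then `empty`; the precedence is exactly that order.
Surviving chains go through `tally_support()` and `unify()`: candidate pairs
are visited from the highest agreement level downward and added when
residue-disjoint from everything already accepted. The category of the
result is the **minimum support among retained pairs**, so category 7 with
seven annotators means unanimity. Two readings of "compatible" are
defensible; we take residue-disjointness and let the downstream pseudoknot
removal restore nestedness, because that mirrors a pipeline in which
pseudoknots are removed as a separate, later step. `strict = TRUE` rejects
crossing pairs at insertion instead. Within one support level the walk is
ascending `(i, j)` - any deterministic rule works; this one is reproducible
and independent of input order.

## Pseudoknot removal

`remove_pseudoknots()` keeps a maximum-cardinality nested subset of the
pairs, computed by dynamic programming over the pair endpoints (a
Nussinov-style recursion restricted to the candidate pair set, quadratic in
the number of endpoints). Maximum cardinality alone does not pin down the
answer, so among equally large subsets pairs on higher-priority layers win
(primary brackets before pseudoknot letter layers), then a greedy
lexicographic sweep decides the rest: each candidate, in priority order, is
kept iff a maximum nested subset containing all pairs kept so far still
exists. The result is deterministic, idempotent, and provably optimal -
the test suite checks cardinality against exhaustive subset enumeration for
every fixture with up to 12 pairs. We chose the DP over "drop all
non-primary layers" because annotator-derived pair sets carry no layer
labels at all.

## Motif decomposition and the three instances

`find_stems()` groups stacked pairs into maximal helices; a lone pair is a
stem of length one (and contributes a full unit to junction order).
`decompose_loops()` walks each stem's inner face: the loop owns its closing
pair and each child helix's outermost pair, strands are the unpaired runs
between helix ends, and the order is one plus the number of children. A
bulge is an internal loop with one empty strand - there is no separate bulge
class. The exterior region is reported as its own motif but is never a
junction, whatever it touches: a junction requires a closing pair. An
independent direct-containment oracle (`brute_force_decompose()`) reproduces
the same loops from pairwise interval arithmetic; the suite compares the two
on 500 seeded random structures of lengths 20-200.

Each loop of order at least 2 yields three design targets
(`make_instances()`):

1. the isolated loop: closing pair, child outermost pairs, and strands;
2. the loop with its connecting stems: the full enclosing helix and full
   child helices plus the strands;
3. the entire structure.

Excising a child's enclosed subtree leaves a discontinuity inside its
innermost pair; we splice in `cap_length` unpaired `N` positions (default 3)
so every emitted dot-bracket is well-formed and foldable, with hairpins no
shorter than the cap. Reported lengths count only original positions, never
caps. The cap is configurable (0 emits the raw fragment) because deposited
datasets differ in how they encode discontinuous fragments.

```{r}
loops <- decompose_loops(ss)
make_instances(ss, loops[loops$loop_class == "junction", ]) |>
  select(loop_db, loop_stems_db, len_loop, len_loop_stems, len_full)
```

## Benchmark metrics

`bp_f1()` compares pair sets by exact identity; both-empty scores 1,
empty-prediction-against-nonempty-target scores 0.

`tree_edit_distance()` is the Zhang-Shasha ordered-tree edit distance on the
full-structure encoding: a virtual root, one internal node per pair, one
leaf per unpaired base (implemented in C++). The cost table - unpaired indel
1, pair indel 2, cross-label substitution priced at delete-plus-insert so it
is never strictly preferred - was fixed by probing the reference
`RNAdistance` binary on a validation set of structure pairs before the
implementation was written; the suite re-checks equality against the binary
on 100 random pairs. Distances are divided by the target sequence length
(`normalize_distance()`) so long targets do not dominate.

Failure handling follows the worst-case rule: a tool that fails a case gets
`+Inf` on distance metrics and `0` on F1 (`aggregate_with_failures()`),
which guarantees it loses that pairwise comparison; the common-solved subset
(cases every tool solved) is returned alongside for headline tables, with
the full-coverage values kept so coverage differences stay visible.

`wilcoxon_matrix()` computes one-sided signed-rank p-values that each tool
beats each other tool. Zero differences are dropped; identical vectors give
p = 1; infinities are handled by rank (any finite value beats `+Inf`). The
p-value is exact for up to 25 non-zero differences - computed by
convolution over the tied-midrank grid, which reproduces full enumeration
of sign assignments even under ties - and a normal approximation with
continuity and tie corrections beyond that. We implemented the statistic
natively because stock signed-rank routines refuse exact p-values under
ties and cannot express the infinity-rank convention; on tie-free data the
suite cross-checks against `stats::wilcox.test`.

For multi-target design, `target_probability()` gives the Boltzmann mass
`exp((EE - E_t)/RT)` of a target (default RT 0.61633 kcal/mol, 37 °C,
matching the folding engine), and `select_candidate()` picks the sequence
with the highest probability sum, ties broken by lowest MFE, then input
order. `rnafold()`, `rnapdist()`, `rna_eval()` and `rnadistance_ref()` shell
out to the ViennaRNA binaries and raise a clear "backend unavailable" error
when the binaries are missing - never silent zeros.

## The classification harness

`build_feature_table()` keeps 3-way-junction records and recomputes, from
each loop instance's dot-bracket, the three counts of unpaired residues in
the strands of the multiloop; the label marks membership of the positive
family. `stratified_kfold_eval()` assigns folds per class by seeded
shuffle-and-deal, so per-fold class counts differ by at most one and the
same seed reproduces the assignment bit for bit. The default classifiers are
k-nearest-neighbours (k = 3), a decision tree and naive Bayes, delegated to
`class`, `rpart` and `e1071` with their default hyperparameters; reporting
is macro-F1 (the unweighted per-class mean, the right summary under heavy
class imbalance) per fold plus min/max/median/mean. A group-aware mode
assigns whole groups (for example, whole families) to single folds to
measure generalisation without leakage, at the cost of exact stratification.

## The synthetic generator

`generate_random_structure()` emulates the raw material of both routes:
nested structures with complementary sequences (GC/AU/GU drawn 0.6/0.3/0.1),
hairpin loops of at least 3 nt, helices capped at 8 bp, and a branching
distribution (weights for 0, 1, 2, 3, 4 children per loop face, default
0.34/0.46/0.12/0.05/0.03, with the no-child weight damped on faces over
25 nt to avoid giant hairpins) that yields a motif mix dominated by internal
loops with a tail of 3- and 4-way junctions, echoing the composition of
natural RNA structure databases. What it does **not** emulate: non-canonical
pairs, pseudoknots (crossing-pair fixtures are built separately in the
tests), modified residues, sequence conservation across a family, and the
energetic plausibility of real helices. Passing tests therefore certify the
combinatorial machinery - decomposition, consensus, metrics - not the
biological fidelity of any particular database.

## Numerical and degenerate-input choices

- Positions are 1-based inclusive everywhere; the dataset CSV stores only
  subsequences, so no coordinate convention leaks out.
- Crossing pairs are written with greedy first-fit layer assignment over
  `()[]{}<>Aa..Zz`; more than 30 mutually crossing layers is an error.
- WUSS unpaired characters are exactly `. : _ - ~ ,`; anything else
  unmatched is an error rather than silently unpaired.
- Summary tables use the sample standard deviation; a single-record group
  reports 0 by convention. Percentages are rounded to two decimals.
- An empty structure decomposes to the exterior motif alone; an empty record
  list writes a header-only CSV; `summarize_records()` on zero records is an
  error.
- Single-annotator unification returns that annotator's pairs verbatim with
  category 1.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic inputs
generated in code: 500 structures (20-200 nt) for the decomposition oracle,
120 crossing-pair fixtures for pseudoknot-removal optimality, 1,000
annotator ensembles for the consensus protocol, 100 structure pairs against
the reference binary, a 250-structure corpus for dataset statistics, a
40-case benchmark with two synthetic designers, and a 2,941-row feature
table (94 positives) for the cross-validation demonstration. These sizes
were chosen to exercise every code path at desk scale; the machinery itself
is size-independent.

## Known limitations

- The seven annotation programs and the design tools themselves are outside
  the package: their outputs are inputs here.
- R-scape/CaCoFold and the ViennaRNA programs are wrapped, not
  re-implemented; features that need them degrade with explicit errors.
- Whether the published agreement categories label structures by minimum,
  mean, or modal support is not documented; we implement the minimum, which
  makes "7 = unanimous" exact, and expose the tally so other summaries can
  be derived.
- Non-canonical pair taxonomies, coaxial stacking, and 3D geometry are out
  of scope.
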