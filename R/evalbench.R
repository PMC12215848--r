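#' Base-pair precision, recall and F1
#'
#' Compares a predicted secondary structure against a target by exact pair
#' identity: a true positive is a pair present in both sets. When both
#' structures are empty the F1 is 1 by convention; a non-empty target with an
#' empty prediction scores 0.
#'
#' @param target,predicted [rna_structure]s of equal length.
#' @return A one-row tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' bp_f1(parse_dotbracket("((...))"), parse_dotbracket("(.....)"))
#' @export
bp_f1 <- function(target, predicted) {
  stopifnot(inherits(target, "rna_structure"), inherits(predicted, "rna_structure"))
  if (target$length != predicted$length) {
    stop("structures have different lengths (", target$length, " vs ",
         predicted$length, ")", call. = FALSE)
  }
  tk <- paste(target$pairs[, 1L], target$pairs[, 2L])
  pk <- paste(predicted$pairs[, 1L], predicted$pairs[, 2L])
  tp <- length(intersect(tk, pk))
  if (!length(tk) && !length(pk)) {
    return(tibble::tibble(precision = 1, recall = 1, f1 = 1))
  }
  precision <- if (length(pk)) tp / length(pk) else 0
  recall <- if (length(tk)) tp / length(tk) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

# Encode a nested structure as a postorder-labelled tree for tree editing:
# virtual root (label 2), one internal node per pair (label 1), one leaf per
# unpaired base (label 0). Returns postorder labels and leftmost-leaf indices.
.structure_tree <- function(ss) {
  partner <- pair_partners(ss)
  n_nodes <- ss$length - nrow(ss$pairs) + 1L  # leaves + pair nodes + root
  labels <- integer(n_nodes); lld <- integer(n_nodes)
  k <- 0L
  visit <- function(from, to, label) {
    first <- k + 1L
    pos <- from
    while (pos <= to) {
      if (partner[pos] > pos) {
        visit(pos + 1L, partner[pos] - 1L, 1L)
        pos <- partner[pos] + 1L
      } else {
        k <<- k + 1L
        labels[k] <<- 0L
        lld[k] <<- k
        pos <- pos + 1L
      }
    }
    k <<- k + 1L
    labels[k] <<- label
    lld[k] <<- if (k > first) lld[first] else k
    invisible()
  }
  visit(1L, ss$length, 2L)
  list(labels = labels, lld = lld)
}

#' Tree edit distance between two nested structures
#'
#' Ordered-labelled-tree edit distance (Zhang-Shasha) on the full-structure
#' tree encoding: a virtual root, an internal node per base pair and a leaf
#' per unpaired base. The default cost table (unpaired indel 1, pair indel 2,
#' cross-label substitution priced as delete + insert) reproduces the default
#' full-structure distance of the reference `RNAdistance` program.
#'
#' @param a,b Nested [rna_structure]s (or dot-bracket strings).
#' @param cost Named numeric vector with elements `unpaired` and `pair`.
#' @return Non-negative number; 0 iff the structures are identical.
#' @examples
#' tree_edit_distance("((...))", ".(...).")
#' @export
tree_edit_distance <- function(a, b, cost = c(unpaired = 1, pair = 2)) {
  if (is.character(a)) a <- parse_dotbracket(a)
  if (is.character(b)) b <- parse_dotbracket(b)
  if (!is_nested(a) || !is_nested(b)) {
    stop("tree edit distance requires nested structures; ",
         "run remove_pseudoknots() first", call. = FALSE)
  }
  ta <- .structure_tree(a); tb <- .structure_tree(b)
  indel <- c(cost[["unpaired"]], cost[["pair"]], cost[["unpaired"]] + cost[["pair"]])
  zs_tree_distance(ta$labels, ta$lld, tb$labels, tb$lld, indel)
}

#' Normalise a structure distance by target length
#'
#' Divides a raw structure-distance value by the length of the corresponding
#' RNA sequence, making distances comparable across targets of different
#' sizes.
#'
#' @param d Non-negative distance (vectorised).
#' @param target_length Positive sequence length.
#' @return `d / target_length`.
#' @export
normalize_distance <- function(d, target_length) {
  if (any(target_length <= 0)) stop("target length must be positive", call. = FALSE)
  d / target_length
}

# Metric direction registry: lower-better distances vs higher-better scores.
.metric_direction <- function(metric) {
  switch(metric,
    rnadistance = , rnadistance_norm = , rnapdist = , tree_edit = "lower",
    f1 = , precision = , recall = "higher",
    stop("unknown metric '", metric, "'", call. = FALSE)
  )
}

#' Substitute failure flags with worst-case metric values
#'
#' Cases a tool failed to solve (timeout or error) are assigned the worst
#' possible value for the metric - positive infinity for distance metrics and
#' 0 for the F1-score - so a failing tool is guaranteed to lose that
#' comparison. Also computes the common-solved mask: the cases solved by
#' every tool, on which headline tables are reported.
#'
#' @param metrics Tibble with columns `tool`, `case_id`, `value` (`NA` =
#'   failed, or use `failed` logical column).
#' @param metric Metric name (`"f1"`, `"rnadistance"`, `"rnadistance_norm"`,
#'   `"rnapdist"`, `"tree_edit"`, `"precision"`, `"recall"`).
#' @return A list: `values`, a tibble with one row per case and one column
#'   per tool (failures substituted); `common`, logical vector marking cases
#'   solved by all tools; `direction`, the metric's direction.
#' @export
aggregate_with_failures <- function(metrics, metric) {
  direction <- .metric_direction(metric)
  metrics <- tibble::as_tibble(metrics)
  if (!"failed" %in% names(metrics)) metrics$failed <- is.na(metrics$value)
  metrics$failed <- metrics$failed | is.na(metrics$value)
  worst <- if (direction == "lower") Inf else 0
  metrics$value[metrics$failed] <- worst
  wide <- tidyr::pivot_wider(metrics[c("case_id", "tool", "value")],
                             names_from = "tool", values_from = "value")
  solved <- tidyr::pivot_wider(metrics[c("case_id", "tool", "failed")],
                               names_from = "tool", values_from = "failed")
  common <- !Reduce(`|`, solved[-1L])
  list(values = wide, common = common, direction = direction)
}

# One-sided Wilcoxon signed-rank p-value that `x` is better than `y`.
# Zero differences are dropped; ties get midranks; pairs where both values
# are infinite count as zero differences; an infinite difference outranks any
# finite one. Exact tied-rank distribution by convolution for n <= exact_max,
# normal approximation with continuity and tie correction above.
.signed_rank_p <- function(x, y, direction, exact_max = 25L) {
  d <- x - y
  d[is.infinite(x) & is.infinite(y)] <- 0
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  # "x better" = differences negative for lower-better metrics, positive for
  # higher-better; express as lower tail of W+ for negative-leaning evidence
  lower_tail <- direction == "lower"
  if (n <= exact_max) {
    # distribution of W+ over the 2^n sign assignments, integer grid via 2r
    r2 <- round(2 * r)
    probs <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(length(probs) - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- round(2 * w_pos)
    p <- if (lower_tail) sum(probs[seq_len(w2 + 1L)])
         else sum(probs[(w2 + 1L):length(probs)])
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  cc <- 0.5
  z <- if (lower_tail) (w_pos - mu + cc) / sqrt(sigma2)
       else (w_pos - mu - cc) / sqrt(sigma2)
  if (lower_tail) stats::pnorm(z) else stats::pnorm(z, lower.tail = FALSE)
}

#' Pairwise one-sided Wilcoxon signed-rank matrix
#'
#' For every ordered pair of tools `(a, b)` computes the one-sided
#' signed-rank p-value that `a`'s per-case metric values are better than
#' `b`'s (direction-aware). Zero differences are dropped, identical vectors
#' give p = 1, and infinities (failure substitutes) are handled by rank: any
#' finite value beats +Inf.
#'
#' @param values Wide tibble/data frame or matrix of per-case metric values,
#'   one column per tool (a `case_id` column is ignored), or the `values`
#'   element of [aggregate_with_failures()].
#' @param direction `"lower"` if smaller values are better, `"higher"`
#'   otherwise.
#' @return An object of class `comparison_matrix`: list with `tools` and `p`
#'   (row tool better than column tool; diagonal `NA`).
#' @examples
#' wilcoxon_matrix(tibble::tibble(A = 1:5, B = 2:6), direction = "lower")
#' @export
wilcoxon_matrix <- function(values, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (is.list(values) && !is.data.frame(values) && !is.null(values$values)) {
    values <- values$values
  }
  if (is.list(values) && !is.data.frame(values) &&
      length(unique(lengths(values))) > 1L) {
    stop("tool vectors have differing lengths", call. = FALSE)
  }
  values <- as.data.frame(values)
  values$case_id <- NULL
  tools <- names(values)
  k <- length(tools)
  p <- matrix(NA_real_, k, k, dimnames = list(tools, tools))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      p[a, b] <- .signed_rank_p(values[[a]], values[[b]], direction)
    }
  }
  structure(list(tools = tools, p = p, direction = direction),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("<comparison_matrix> one-sided signed-rank p-values (row better than column),",
      x$direction, "is better\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Boltzmann probability of a target structure
#'
#' `P_t = exp((EE - E_t) / RT)`: the probability mass of a target structure
#' whose free energy is `E_t` within an ensemble of free energy `EE`.
#'
#' @param E_t Free energy of the sequence folded into the target (kcal/mol).
#' @param EE Ensemble free energy of the sequence (kcal/mol).
#' @param RT Thermal energy, default 0.61633 kcal/mol (37 degrees C).
#' @return Probability in (0, 1] when `E_t >= EE`.
#' @export
target_probability <- function(E_t, EE, RT = 0.61633) {
  if (any(RT <= 0)) stop("RT must be positive", call. = FALSE)
  exp((EE - E_t) / RT)
}

#' Select the final design candidate
#'
#' Implements the multi-target selection rule: the candidate with the highest
#' total target probability `Psum`, ties broken by the lowest minimum free
#' energy, then by input order.
#'
#' @param candidates Tibble with columns `sequence`, `psum`, `mfe`.
#' @return The selected sequence (character scalar).
#' @export
select_candidate <- function(candidates) {
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) stop("empty candidate list", call. = FALSE)
  ord <- order(-candidates$psum, candidates$mfe)
  candidates$sequence[ord[1L]]
}

#' Evaluate designed sequences against their targets
#'
#' Scores one tool's designs: each designed sequence is refolded with
#' [rnafold()], and the refolded structure is compared with the target by
#' tree edit distance (raw and length-normalised) and base-pair F1;
#' optionally the designed and reference sequences are compared with
#' [rnapdist()]. A missing design (`NA`) is recorded as a failure.
#'
#' @param targets Tibble with columns `case_id`, `target_db` (dot-bracket)
#'   and optionally `reference_seq`.
#' @param designs Tibble with columns `case_id` and `sequence` (`NA` for
#'   unsolved cases).
#' @param tool Tool name stored in the output.
#' @param pdist Also compute the ensemble distance to `reference_seq`.
#' @return Tibble with one row per case: `tool`, `case_id`, `failed`,
#'   `rnadistance`, `rnadistance_norm`, `f1`, `precision`, `recall` and
#'   optionally `rnapdist` (all `NA` on failure).
#' @export
evaluate_designs <- function(targets, designs, tool = "tool", pdist = FALSE) {
  targets <- tibble::as_tibble(targets)
  designs <- tibble::as_tibble(designs)
  df <- dplyr::left_join(targets, designs, by = "case_id")
  purrr::map_dfr(seq_len(nrow(df)), function(r) {
    out <- tibble::tibble(tool = tool, case_id = df$case_id[r], failed = TRUE,
                          rnadistance = NA_real_, rnadistance_norm = NA_real_,
                          f1 = NA_real_, precision = NA_real_, recall = NA_real_)
    if (pdist) out$rnapdist <- NA_real_
    seq <- df$sequence[r]
    if (is.na(seq) || !nzchar(seq)) return(out)
    target <- parse_dotbracket(df$target_db[r])
    fold <- rnafold(seq)
    refolded <- parse_dotbracket(fold$structure)
    d <- tree_edit_distance(target, refolded)
    f <- bp_f1(target, refolded)
    out$failed <- FALSE
    out$rnadistance <- d
    out$rnadistance_norm <- normalize_distance(d, target$length)
    out$f1 <- f$f1; out$precision <- f$precision; out$recall <- f$recall
    if (pdist) out$rnapdist <- rnapdist(df$reference_seq[r], seq)
    out
  })
}
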