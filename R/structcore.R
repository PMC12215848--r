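#' Remove pseudoknots by maximum nested-subset selection
#'
#' Selects a maximum-cardinality subset of the input base pairs that is
#' nested (no two pairs cross). Among equally large maxima, pairs on
#' higher-priority layers win, then a greedy lexicographic tie-break
#' (ascending `i`, then `j`); the result is deterministic. The computation is
#' a dynamic programme over pair endpoints (Nussinov-style, restricted to the
#' candidate pair set), followed by a forced-inclusion feasibility sweep that
#' realises the tie-break.
#'
#' @param ss An [rna_structure].
#' @param layer_priority Optional character vector of layer labels in
#'   decreasing priority; defaults to the bracket alphabet order
#'   (`"()", "[]", "{}", "<>", "Aa", ...`). Layers not listed rank last.
#' @return An [rna_structure] with a nested subset of the input pairs (same
#'   length and sequence). Nested inputs are returned unchanged.
#' @examples
#' ss <- parse_dotbracket("..((..[[..))..]]")
#' write_dotbracket(remove_pseudoknots(ss))
#' @export
remove_pseudoknots <- function(ss, layer_priority = NULL) {
  stopifnot(inherits(ss, "rna_structure"))
  if (is_nested(ss)) return(ss)
  p <- ss$pairs
  if (is.null(layer_priority)) layer_priority <- .bracket_layers
  prio <- match(ss$layers, layer_priority)
  prio[is.na(prio)] <- length(layer_priority) + 1L
  ord <- order(prio, p[, 1L], p[, 2L])

  max_size <- .max_nested_size(p, forced = integer(0))
  chosen <- integer(0)
  for (r in ord) {
    trial <- c(chosen, r)
    if (.max_nested_size(p, forced = trial) == max_size) chosen <- trial
    if (length(chosen) == max_size) break
  }
  rna_structure(ss$length, p[chosen, , drop = FALSE],
                sequence = ss$sequence, layers = ss$layers[chosen])
}

# Size of the largest nested subset of `pairs` that contains all pairs indexed
# by `forced` (-Inf ~ -1 when infeasible). DP over compressed endpoints:
# dp[lo, hi] treats window [lo, hi]; an endpoint whose arc is forced must be
# consumed by taking that arc inside the window.
.max_nested_size <- function(pairs, forced = integer(0)) {
  np <- nrow(pairs)
  if (np == 0L) return(0L)
  ends <- sort(c(pairs[, 1L], pairs[, 2L]))
  m <- length(ends)
  # compressed partner and arc id per endpoint
  partner <- integer(m); arc <- integer(m)
  ci <- match(pairs[, 1L], ends); cj <- match(pairs[, 2L], ends)
  partner[ci] <- cj; partner[cj] <- ci
  arc[ci] <- seq_len(np); arc[cj] <- seq_len(np)
  is_forced <- logical(np); is_forced[forced] <- TRUE
  NEG <- -1000000L
  dp <- matrix(0L, nrow = m + 1L, ncol = m + 1L)  # dp[lo, hi+1], hi < lo -> 0
  for (span in 0:(m - 1L)) {
    for (lo in seq_len(m - span)) {
      hi <- lo + span
      k <- partner[lo]
      take <- NEG
      if (k > lo && k <= hi) {
        left <- if (k - 1L >= lo + 1L) dp[lo + 1L, k] else 0L
        right <- if (hi >= k + 1L) dp[k + 1L, hi + 1L] else 0L
        take <- if (left <= NEG || right <= NEG) NEG else 1L + left + right
      }
      if (is_forced[arc[lo]]) {
        # lo must open its forced arc inside this window
        val <- if (k > lo && k <= hi) take else NEG
      } else {
        skip <- if (hi >= lo + 1L) dp[lo + 1L, hi + 1L] else 0L
        val <- max(skip, take)
      }
      dp[lo, hi + 1L] <- val
    }
  }
  v <- dp[1L, m + 1L]
  if (v <= NEG + 1000L) -1L else v
}

#' Project a consensus structure onto one alignment row
#'
#' Gap characters (`-` and `.`) are removed from the row, a column-to-ungapped
#' position map is built, and a consensus pair is retained iff both of its
#' columns map to non-gap positions in this row. Retained pairs are re-indexed
#' to ungapped coordinates and the result carries the ungapped sequence.
#'
#' @param family An [rna_family].
#' @param row_index Row number (1-based) into `family$rows`.
#' @return An [rna_structure] for that sequence.
#' @export
project_onto_sequence <- function(family, row_index) {
  stopifnot(inherits(family, "rna_family"))
  if (row_index < 1L || row_index > nrow(family$rows)) {
    stop("row index ", row_index, " out of range (1..", nrow(family$rows), ")",
         call. = FALSE)
  }
  row <- family$rows$seq[row_index]
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  is_gap <- chars %in% c("-", ".")
  pos_map <- integer(length(chars))        # column -> ungapped position, 0 = gap
  pos_map[!is_gap] <- seq_len(sum(!is_gap))
  cp <- family$consensus_pairs
  keep <- if (nrow(cp)) pos_map[cp$i] > 0L & pos_map[cp$j] > 0L else logical(0)
  seq_out <- paste(chars[!is_gap], collapse = "")
  rna_structure(sum(!is_gap),
                cbind(pos_map[cp$i[keep]], pos_map[cp$j[keep]]),
                sequence = if (nzchar(seq_out)) seq_out else NULL,
                layers = cp$layer[keep])
}

#' Chain metadata for suitability filtering
#'
#' @param chain_ids Character vector of chain identifiers.
#' @param residue_numbers List of integer vectors (author residue numbers,
#'   strictly increasing) parallel to `chain_ids`, or a single vector when
#'   there is one chain.
#' @return An object of class `chain_meta`.
#' @export
chain_meta <- function(chain_ids, residue_numbers) {
  if (!is.list(residue_numbers)) residue_numbers <- list(residue_numbers)
  if (length(chain_ids) < 1L) stop("at least one chain is required", call. = FALSE)
  if (length(residue_numbers) != length(chain_ids)) {
    stop("`residue_numbers` must be parallel to `chain_ids`", call. = FALSE)
  }
  if (any(lengths(residue_numbers) == 0L)) {
    stop("a chain has an empty residue list", call. = FALSE)
  }
  for (r in residue_numbers) {
    if (any(diff(r) <= 0L)) {
      stop("residue numbers must be strictly increasing within a chain",
           call. = FALSE)
    }
  }
  structure(list(chain_ids = chain_ids, residue_numbers = residue_numbers),
            class = "chain_meta")
}

#' Categorise a chain's suitability for design-target extraction
#'
#' Chains are screened before consensus annotation: `multistrand` when more
#' than one chain id is present, else `gapped` when author residue numbers are
#' non-contiguous, else `empty` when the structure has no base pairs, else
#' `ok`. Precedence is exactly that order.
#'
#' @param meta A [chain_meta].
#' @param ss An [rna_structure] for the chain.
#' @return One of `"multistrand"`, `"gapped"`, `"empty"`, `"ok"`.
#' @export
categorize_chain <- function(meta, ss) {
  stopifnot(inherits(meta, "chain_meta"), inherits(ss, "rna_structure"))
  if (length(meta$chain_ids) > 1L) return("multistrand")
  if (any(diff(meta$residue_numbers[[1L]]) != 1L)) return("gapped")
  if (nrow(ss$pairs) == 0L) return("empty")
  "ok"
}

#' Augment a family's consensus pairs with R-scape/CaCoFold output
#'
#' Optional wrapper shelling out to `R-scape --rfam --cacofold`; covarying
#' pairs found by CaCoFold that do not clash with existing consensus columns
#' are added on a lower-priority letter layer before projection. Requires the
#' `R-scape` binary on the PATH; all package functionality works without it.
#'
#' @param family An [rna_family].
#' @param rscape Path to the R-scape executable.
#' @return An [rna_family] with possibly augmented `consensus_pairs`.
#' @export
rscape_cacofold <- function(family, rscape = Sys.which("R-scape")) {
  if (!nzchar(rscape)) {
    stop("R-scape binary not found; CaCoFold augmentation unavailable",
         call. = FALSE)
  }
  dir <- tempfile("rscape"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  sto <- file.path(dir, "family.sto")
  write_stockholm(family, sto)
  status <- system2(rscape, c("--rfam", "--cacofold", "--outdir", dir, sto),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("R-scape exited with status ", status, call. = FALSE)
  out <- list.files(dir, pattern = "\\.cacofold\\.sto$", full.names = TRUE)
  if (!length(out)) stop("R-scape produced no CaCoFold Stockholm output", call. = FALSE)
  cacofold <- read_stockholm(out[1L])
  used <- c(family$consensus_pairs$i, family$consensus_pairs$j)
  add <- cacofold$consensus_pairs
  add <- add[!(add$i %in% used) & !(add$j %in% used), , drop = FALSE]
  if (nrow(add)) {
    add$layer <- "Zz"     # below every SS_cons layer in the default priority
    family$consensus_pairs <- dplyr::bind_rows(family$consensus_pairs, add)
  }
  family
}
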