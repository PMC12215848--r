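#' Extract dataset records from one structure
#'
#' Decomposes a nested structure and emits one record per loop of order >= 2
#' (internal loops and n-way junctions), each with its three design-target
#' instances.
#'
#' @param ss A nested [rna_structure] with a sequence.
#' @param source_db `"rfam"` or `"rnasolo"`.
#' @param source_id Sequence or chain identifier.
#' @param family_or_pdb Family accession or PDB entry id.
#' @param category Agreement category string (`"n/a"` for the Rfam route).
#' @param cap_length Splice-cap length passed to [make_instances()].
#' @return A tibble of dataset records (possibly zero rows).
#' @export
extract_records <- function(ss, source_db, source_id, family_or_pdb,
                            category = "n/a", cap_length = 3L) {
  loops <- decompose_loops(ss, include_exterior = FALSE)
  loops <- loops[!is.na(loops$order) & loops$order >= 2L, , drop = FALSE]
  if (!nrow(loops)) return(.empty_records())
  purrr::map_dfr(seq_len(nrow(loops)), function(r) {
    inst <- make_instances(ss, loops[r, ], cap_length = cap_length)
    n <- loops$order[r]
    dplyr::bind_cols(
      tibble::tibble(
        source_db = source_db, source_id = source_id,
        family_or_pdb = family_or_pdb,
        loop_type = if (n == 2L) "internal" else paste0(n, "way"),
        loop_order = n, category = as.character(category)
      ),
      inst
    )[dataset_columns]
  })
}

.empty_records <- function() {
  tibble::tibble(
    source_db = character(), source_id = character(),
    family_or_pdb = character(), loop_type = character(),
    loop_order = integer(), category = character(),
    loop_seq = character(), loop_db = character(),
    loop_stems_seq = character(), loop_stems_db = character(),
    full_seq = character(), full_db = character(),
    len_loop = integer(), len_loop_stems = integer(), len_full = integer()
  )
}

#' Build dataset records from Rfam-style seed alignments
#'
#' The Rfam route: for every family, (optionally) augment the consensus with
#' CaCoFold covarying pairs, project the consensus onto each seed-alignment
#' row, remove pseudoknots, (optionally) refold the sequence with the
#' projected structure as hard constraints via the external `RNAfold`, then
#' decompose and emit records for every loop of order >= 2. Records from this
#' route carry category `"n/a"`. Malformed family files are skipped with a
#' warning.
#'
#' @param families List of [rna_family] objects and/or Stockholm file paths.
#' @param use_cacofold Call [rscape_cacofold()] on each family first
#'   (requires the R-scape binary).
#' @param refold_constrained Refold each projected sequence with
#'   [rnafold()] under hard structure constraints (requires ViennaRNA).
#' @param cap_length Splice-cap length for instance generation.
#' @param knot_removal Remove pseudoknots `"after"` (default) or `"before"`
#'   projection; `"before"` drops letter-layer consensus pairs family-wide.
#' @return A tibble of dataset records with attribute `skipped` counting
#'   families that failed to parse.
#' @export
build_rfam_records <- function(families, use_cacofold = FALSE,
                               refold_constrained = FALSE, cap_length = 3L,
                               knot_removal = c("after", "before")) {
  knot_removal <- match.arg(knot_removal)
  skipped <- 0L
  out <- purrr::map_dfr(families, function(fam) {
    if (is.character(fam)) {
      fam <- tryCatch(read_stockholm(fam), error = function(e) {
        warning("skipping malformed family file: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(fam)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
    }
    if (use_cacofold) fam <- rscape_cacofold(fam)
    if (knot_removal == "before") {
      keep <- fam$consensus_pairs$layer %in% c("()", "[]", "{}", "<>")
      fam$consensus_pairs <- fam$consensus_pairs[keep, , drop = FALSE]
    }
    purrr::map_dfr(seq_len(nrow(fam$rows)), function(r) {
      ss <- project_onto_sequence(fam, r)
      if (ss$length == 0L) return(NULL)
      ss <- remove_pseudoknots(ss)
      if (refold_constrained) {
        fold <- rnafold(ss$sequence, constraint = write_dotbracket(ss))
        ss <- parse_dotbracket(fold$structure, sequence = ss$sequence)
      }
      extract_records(ss, "rfam", fam$rows$id[r], fam$accession,
                      category = "n/a", cap_length = cap_length)
    })
  })
  attr(out, "skipped") <- skipped
  out
}

#' Build dataset records from per-chain annotator outputs
#'
#' The experimentally-derived route: each chain arrives with the base-pair
#' lists of several annotators plus chain metadata. Chains categorised
#' `empty`, `gapped` or `multistrand` are filtered out; the rest go through
#' support tallying, unification, pseudoknot removal and decomposition, and
#' their records carry the numeric agreement category (minimum annotator
#' support among retained pairs).
#'
#' @param chains List of chain entries; each a list with elements `id`
#'   (chain identifier), `pdb` (entry accession), `sequence`, `meta` (a
#'   [chain_meta]) and `annotations` (non-empty list of pair matrices or
#'   [rna_structure]s).
#' @param n_annotators Number of annotators (defaults to the annotation count
#'   of each chain).
#' @param cap_length Splice-cap length for instance generation.
#' @param strict_unify Passed to [unify()] as `strict`.
#' @return A tibble of dataset records with attribute `filtered`, a named
#'   count of chains dropped per suitability category.
#' @export
build_rnasolo_records <- function(chains, n_annotators = NULL, cap_length = 3L,
                                  strict_unify = FALSE) {
  filtered <- c(empty = 0L, gapped = 0L, multistrand = 0L)
  out <- purrr::map_dfr(chains, function(ch) {
    if (!length(ch$annotations)) stop("chain ", ch$id, " has zero annotators",
                                      call. = FALSE)
    na <- n_annotators %||% length(ch$annotations)
    len <- nchar(ch$sequence)
    tal <- tally_support(ch$annotations, length = len)
    uni <- unify(tal, n_annotators = na, length = len,
                 sequence = ch$sequence, strict = strict_unify)
    cat_ <- categorize_chain(ch$meta, uni$structure)
    if (cat_ != "ok") {
      filtered[cat_] <<- filtered[cat_] + 1L
      return(NULL)
    }
    ss <- remove_pseudoknots(uni$structure)
    extract_records(ss, "rnasolo", ch$id, ch$pdb,
                    category = uni$category, cap_length = cap_length)
  })
  attr(out, "filtered") <- filtered
  out
}

#' Summary statistics of a record set by loop type
#'
#' Groups records by `loop_type` and reports count, percentage of the total
#' (two decimals), and the minimum, maximum, mean and sample standard
#' deviation (`ddof = 1`; reported as 0 for single-record groups) of
#' `len_loop_stems` - the length of the loop together with its connecting
#' stems.
#'
#' @param records Tibble of dataset records.
#' @return A tibble with columns `loop_type`, `count`, `percent`, `min`,
#'   `max`, `mean`, `std`, ordered by loop order, of class `loop_summary`.
#' @export
summarize_records <- function(records) {
  if (!nrow(records)) stop("no records to summarise", call. = FALSE)
  out <- records |>
    dplyr::group_by(.data$loop_type) |>
    dplyr::summarise(
      count = dplyr::n(),
      min = min(.data$len_loop_stems),
      max = max(.data$len_loop_stems),
      mean = mean(.data$len_loop_stems),
      std = if (dplyr::n() > 1L) stats::sd(.data$len_loop_stems) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(percent = round(100 * .data$count / sum(.data$count), 2)) |>
    dplyr::select("loop_type", "count", "percent", "min", "max", "mean", "std")
  ord <- ifelse(out$loop_type == "internal", 2L,
                suppressWarnings(as.integer(sub("way$", "", out$loop_type))))
  out <- out[order(ord), , drop = FALSE]
  class(out) <- c("loop_summary", class(out))
  out
}
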