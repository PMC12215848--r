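#' Tally annotator support for base pairs
#'
#' Each annotator reports a set of base pairs for the same chain; the tally
#' counts, for every distinct pair, how many annotators report it.
#'
#' @param annotations List of annotations over a common length; each element
#'   is an [rna_structure] or a two-column pair matrix.
#' @param length Chain length; required when no element is an
#'   [rna_structure].
#' @return A tibble with integer columns `i`, `j`, `support`, sorted by
#'   decreasing support then ascending `i`, `j`.
#' @examples
#' tally_support(list(cbind(1, 10), cbind(c(1, 2), c(10, 9))), length = 10)
#' @export
tally_support <- function(annotations, length = NULL) {
  if (!length(annotations)) {
    return(tibble::tibble(i = integer(), j = integer(), support = integer()))
  }
  lens <- vapply(annotations, function(a) {
    if (inherits(a, "rna_structure")) a$length else NA_integer_
  }, integer(1))
  known <- lens[!is.na(lens)]
  if (length(unique(known)) > 1L) {
    stop("annotations cover differing lengths: ",
         paste(unique(known), collapse = ", "), call. = FALSE)
  }
  if (is.null(length)) {
    if (!length(known)) stop("`length` is required for raw pair matrices", call. = FALSE)
    length <- known[1L]
  } else if (length(known) && known[1L] != length) {
    stop("annotations cover differing lengths: ",
         paste(unique(c(known, length)), collapse = ", "), call. = FALSE)
  }
  pair_df <- purrr::map_dfr(annotations, function(a) {
    p <- if (inherits(a, "rna_structure")) a$pairs else as.matrix(a)
    if (nrow(p) == 0L) return(tibble::tibble(i = integer(), j = integer()))
    if (any(p < 1L) || any(p > length)) {
      stop("annotation pair positions exceed chain length ", length, call. = FALSE)
    }
    tibble::tibble(i = as.integer(pmin(p[, 1L], p[, 2L])),
                   j = as.integer(pmax(p[, 1L], p[, 2L])))
  })
  out <- dplyr::count(pair_df, .data$i, .data$j, name = "support")
  out$support <- as.integer(out$support)
  dplyr::arrange(out, dplyr::desc(.data$support), .data$i, .data$j)
}

#' Unify supported pairs into a consensus structure
#'
#' The unification protocol walks candidate pairs from the highest agreement
#' level down (support descending, then ascending `i`, `j`) and adds a pair
#' iff it is compatible with the pairs already included. By default
#' "compatible" means residue-disjoint (no shared position); crossing pairs
#' are allowed at this stage and removed downstream by
#' [remove_pseudoknots()]. With `strict = TRUE` crossing pairs are also
#' rejected at insertion. The agreement category of the result is the minimum
#' support among included pairs (so a category of `n_annotators` means
#' unanimous agreement), or `"empty"` when nothing is retained.
#'
#' @param supported Tibble from [tally_support()] (columns `i`, `j`,
#'   `support`).
#' @param n_annotators Number of annotators that produced the tally.
#' @param length Chain length for the output structure; defaults to the
#'   largest position seen.
#' @param sequence Optional chain sequence.
#' @param strict Reject crossing pairs at insertion time.
#' @return A list with elements `structure` (an [rna_structure]) and
#'   `category` (integer as character, or `"empty"`).
#' @export
unify <- function(supported, n_annotators, length = NULL, sequence = NULL,
                  strict = FALSE) {
  supported <- tibble::as_tibble(supported)
  if (nrow(supported) && max(supported$support) > n_annotators) {
    stop("support exceeds the number of annotators", call. = FALSE)
  }
  if (is.null(length)) {
    length <- if (nrow(supported)) max(supported$j) else 0L
  }
  supported <- dplyr::arrange(supported, dplyr::desc(.data$support),
                              .data$i, .data$j)
  used <- logical(length)
  keep <- logical(nrow(supported))
  for (r in seq_len(nrow(supported))) {
    i <- supported$i[r]; j <- supported$j[r]
    if (used[i] || used[j]) next
    if (strict && any(keep)) {
      ki <- supported$i[keep]; kj <- supported$j[keep]
      if (any((ki < i & i < kj & kj < j) | (i < ki & ki < j & j < kj))) next
    }
    keep[r] <- TRUE
    used[c(i, j)] <- TRUE
  }
  ss <- rna_structure(length,
                      cbind(supported$i[keep], supported$j[keep]),
                      sequence = sequence)
  category <- if (any(keep)) as.character(min(supported$support[keep])) else "empty"
  list(structure = ss, category = category)
}

#' Restrict pairs to canonical base pairs
#'
#' Keeps only `AU`, `UA`, `GC`, `CG`, `GU`, `UG` pairs; requires the
#' structure to carry a sequence.
#'
#' @param ss An [rna_structure] with a sequence.
#' @return An [rna_structure] containing only canonical pairs.
#' @export
filter_canonical_pairs <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  if (is.null(ss$sequence)) {
    stop("canonical filtering requires a sequence", call. = FALSE)
  }
  if (!nrow(ss$pairs)) return(ss)
  chars <- strsplit(ss$sequence, "", fixed = TRUE)[[1L]]
  duo <- paste0(chars[ss$pairs[, 1L]], chars[ss$pairs[, 2L]])
  keep <- duo %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rna_structure(ss$length, ss$pairs[keep, , drop = FALSE],
                sequence = ss$sequence, layers = ss$layers[keep])
}
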