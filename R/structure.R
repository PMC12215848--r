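# Bracket alphabet shared by the dot-bracket writer/parser and the WUSS reader.
# Layer names are the two-character open/close strings, e.g. "()", "Aa".
.bracket_layers <- c("()", "[]", "{}", "<>", paste0(LETTERS, letters))
.layer_open  <- substr(.bracket_layers, 1, 1)
.layer_close <- substr(.bracket_layers, 2, 2)

#' RNA secondary structure
#'
#' A secondary structure is a residue count, a set of base pairs `(i, j)` with
#' `1 <= i < j <= length`, and an optional nucleotide sequence. Positions are
#' 1-based and every position belongs to at most one pair. Each pair carries a
#' bracket-layer label (`"()"`, `"[]"`, ..., `"Aa"`, ...) recording which layer
#' of a dot-bracket string it came from; pairs constructed directly default to
#' the primary `"()"` layer.
#'
#' @param length Positive integer, number of residues.
#' @param pairs Two-column integer matrix (or data frame) of base pairs; may
#'   have zero rows. Columns are the 5' and 3' partner.
#' @param sequence Optional string over `A,C,G,U,N` (case-insensitive, `T`
#'   accepted and converted to `U`) of length `length`.
#' @param layers Optional character vector of per-pair layer labels.
#'
#' @return An object of class `rna_structure`: a list with elements `length`,
#'   `pairs` (ordered by 5' position), `layers` and `sequence`.
#' @examples
#' rna_structure(7, cbind(c(1, 2), c(7, 6)), sequence = "GGAAACC")
#' @export
rna_structure <- function(length, pairs = NULL, sequence = NULL, layers = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) {
    stop("`length` must be a non-negative integer", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- matrix(integer(), ncol = 2L)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L && nrow(pairs) > 0L) {
    stop("`pairs` must have two columns", call. = FALSE)
  }
  if (nrow(pairs) == 0L) pairs <- matrix(integer(), ncol = 2L)
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0L) {
    if (anyNA(pairs)) stop("`pairs` contains NA", call. = FALSE)
    if (any(pairs[, 1L] >= pairs[, 2L])) {
      stop("every pair must satisfy i < j", call. = FALSE)
    }
    if (any(pairs < 1L) || any(pairs > length)) {
      stop("pair positions must lie in [1, length]", call. = FALSE)
    }
    all_pos <- c(pairs[, 1L], pairs[, 2L])
    if (anyDuplicated(all_pos)) {
      dup <- all_pos[duplicated(all_pos)][1L]
      stop("position ", dup, " occurs in more than one pair", call. = FALSE)
    }
  }
  if (is.null(layers)) {
    layers <- rep("()", nrow(pairs))
  }
  if (length(layers) != nrow(pairs)) {
    stop("`layers` must have one entry per pair", call. = FALSE)
  }
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  layers <- layers[ord]
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    sequence <- gsub("T", "U", sequence, fixed = TRUE)
    if (nchar(sequence) != length) {
      stop("`sequence` length (", nchar(sequence), ") != structure length (",
           length, ")", call. = FALSE)
    }
    if (grepl("[^ACGUN]", sequence)) {
      stop("`sequence` may only contain A, C, G, U, N", call. = FALSE)
    }
  }
  structure(
    list(length = length, pairs = pairs, layers = layers, sequence = sequence),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> length", x$length, "with", nrow(x$pairs), "pairs",
      if (is_nested(x)) "(nested)" else "(pseudoknotted)", "\n")
  if (!is.null(x$sequence)) cat(" seq:", x$sequence, "\n")
  cat(" db: ", write_dotbracket(x), "\n")
  invisible(x)
}

#' @export
length.rna_structure <- function(x) x$length

#' Test whether a structure's pair set is nested
#'
#' A pair set is nested when no two pairs `(i, j)`, `(k, l)` cross, i.e. no
#' `i < k < j < l`. Pseudoknotted structures fail this test.
#'
#' @param ss An [rna_structure].
#' @return Logical scalar.
#' @export
is_nested <- function(ss) {
  p <- ss$pairs
  n <- nrow(p)
  if (n < 2L) return(TRUE)
  # pairs are sorted by i; scan with a stack of open j's
  open_j <- integer(0)
  k <- 1L
  events <- order(c(p[, 1L], p[, 2L]))   # positions interleaved
  pos <- c(p[, 1L], p[, 2L])[events]
  is_open <- events <= n
  idx <- ifelse(is_open, events, events - n)
  for (e in seq_along(pos)) {
    if (is_open[e]) {
      open_j <- c(open_j, p[idx[e], 2L])
    } else {
      if (open_j[length(open_j)] != pos[e]) return(FALSE)
      open_j <- open_j[-length(open_j)]
    }
  }
  TRUE
}

#' Per-position partner vector
#'
#' @param ss An [rna_structure].
#' @return Integer vector of length `ss$length`; `0` marks unpaired positions,
#'   otherwise the 1-based partner index.
#' @export
pair_partners <- function(ss) {
  partner <- integer(ss$length)
  if (nrow(ss$pairs)) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  partner
}

#' Parse a dot-bracket string
#'
#' Matches brackets per layer with a stack. Supported layers are `()`, `[]`,
#' `{}`, `<>` and the letter layers `Aa` through `Zz` (uppercase opens,
#' lowercase closes); `.` marks unpaired positions. The layer of each pair is
#' retained so that pseudoknot layers can be prioritised later.
#'
#' @param text Dot-bracket string, no whitespace.
#' @param sequence Optional nucleotide sequence of the same length.
#' @return An [rna_structure].
#' @examples
#' parse_dotbracket("((...))")
#' parse_dotbracket("..((..[[..))..]]")   # pseudoknotted, two layers
#' @export
parse_dotbracket <- function(text, sequence = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\\s", text)) stop("dot-bracket string contains whitespace", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stacks <- vector("list", length(.bracket_layers))
  pairs_i <- integer(0); pairs_j <- integer(0); pair_layer <- character(0)
  for (k in seq_len(n)) {
    ch <- chars[k]
    if (ch == ".") next
    li <- match(ch, .layer_open)
    if (!is.na(li)) {
      stacks[[li]] <- c(stacks[[li]], k)
      next
    }
    li <- match(ch, .layer_close)
    if (!is.na(li)) {
      st <- stacks[[li]]
      if (length(st) == 0L) {
        stop("unbalanced '", ch, "' at position ", k, " (layer ",
             .bracket_layers[li], ")", call. = FALSE)
      }
      pairs_i <- c(pairs_i, st[length(st)])
      pairs_j <- c(pairs_j, k)
      pair_layer <- c(pair_layer, .bracket_layers[li])
      stacks[[li]] <- st[-length(st)]
      next
    }
    stop("illegal character '", ch, "' at position ", k, call. = FALSE)
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left)) {
    li <- left[1L]
    stop("unbalanced '", .layer_open[li], "' at position ", stacks[[li]][1L],
         " (layer ", .bracket_layers[li], ")", call. = FALSE)
  }
  rna_structure(n, cbind(pairs_i, pairs_j), sequence = sequence,
                layers = pair_layer)
}

#' Render a structure as a dot-bracket string
#'
#' Nested pairs are written with `()`. Crossing pairs are assigned additional
#' layers (`[]`, `{}`, `<>`, `Aa`, ...) greedily, first-fit in 5'-position
#' order, so that each layer is internally nested. Re-parsing the output
#' recovers the pair set exactly.
#'
#' @param ss An [rna_structure].
#' @return A dot-bracket string of length `ss$length`.
#' @export
write_dotbracket <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  out <- rep(".", ss$length)
  p <- ss$pairs
  if (nrow(p)) {
    layer_of <- integer(nrow(p))
    # pairs already sorted by i; first-fit layer that keeps the layer nested
    for (r in seq_len(nrow(p))) {
      i <- p[r, 1L]; j <- p[r, 2L]
      placed <- FALSE
      for (li in seq_along(.bracket_layers)) {
        prev <- which(layer_of[seq_len(r - 1L)] == li)
        if (length(prev)) {
          pi <- p[prev, 1L]; pj <- p[prev, 2L]
          crossing <- (pi < i & i < pj & pj < j) | (i < pi & pi < j & j < pj)
          if (any(crossing)) next
        }
        layer_of[r] <- li
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("structure needs more crossing layers than the bracket alphabet ",
             "provides (", length(.bracket_layers), ")", call. = FALSE)
      }
    }
    out[p[, 1L]] <- .layer_open[layer_of]
    out[p[, 2L]] <- .layer_close[layer_of]
  }
  paste(out, collapse = "")
}
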