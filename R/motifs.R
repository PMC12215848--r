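#' Find stems (maximal helices)
#'
#' Partitions the base pairs of a nested structure into maximal stacked runs:
#' consecutive pairs `(i, j)`, `(i + 1, j - 1)`, ... belong to one stem; a
#' lone pair is a stem of length one. Stems are numbered in 5'-to-3' order of
#' their outermost pair.
#'
#' @param ss A nested [rna_structure].
#' @return A tibble with one row per pair: columns `stem` (stem id), `i`, `j`.
#' @examples
#' find_stems(parse_dotbracket("(.((...)).)"))
#' @export
find_stems <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  if (!is_nested(ss)) {
    stop("structure contains pseudoknots; run remove_pseudoknots() first",
         call. = FALSE)
  }
  p <- ss$pairs
  if (!nrow(p)) return(tibble::tibble(stem = integer(), i = integer(), j = integer()))
  partner <- pair_partners(ss)
  stem_id <- integer(nrow(p))
  current <- 0L
  # pairs sorted by i; (i, j) continues the previous stem iff (i-1, j+1) paired
  prev_j <- -1L
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    if (r > 1L && p[r - 1L, 1L] == i - 1L && p[r - 1L, 2L] == j + 1L) {
      stem_id[r] <- current
    } else {
      current <- current + 1L
      stem_id[r] <- current
    }
  }
  tibble::tibble(stem = stem_id, i = p[, 1L], j = p[, 2L])
}

#' Decompose a nested structure into loops
#'
#' Walks every stem's inner face to enumerate the loops of the structure:
#' hairpins (order 1), internal loops including bulges (order 2) and n-way
#' junctions (order n >= 3), plus one exterior motif covering the unenclosed
#' region. A loop's order is 1 plus the number of child helices emanating from
#' it; its strands are the runs of unpaired positions between consecutive
#' helix ends (empty runs allowed, so a bulge is an internal loop with one
#' zero-length strand).
#'
#' @param ss A nested [rna_structure].
#' @param include_exterior Emit the exterior motif row (default `TRUE`).
#' @return A tibble with one row per loop: `loop_class`
#'   (`hairpin`/`internal`/`junction`/`exterior`), `order` (NA for exterior),
#'   `closing_i`, `closing_j` (NA for exterior), list-columns `children`
#'   (two-column matrix of child outermost pairs) and `strands` (two-column
#'   matrix of strand start/end, `end = start - 1` for empty strands), and
#'   `strand_lengths` (list of integer vectors).
#' @export
decompose_loops <- function(ss, include_exterior = TRUE) {
  stopifnot(inherits(ss, "rna_structure"))
  stems <- find_stems(ss)
  partner <- pair_partners(ss)

  face <- function(from, to) {
    # scan positions [from, to] at top level: children + strands
    kids_i <- integer(0); kids_j <- integer(0)
    s_start <- integer(0); s_end <- integer(0)
    pos <- from
    run_start <- from
    while (pos <= to) {
      if (partner[pos] > pos) {
        s_start <- c(s_start, run_start); s_end <- c(s_end, pos - 1L)
        kids_i <- c(kids_i, pos); kids_j <- c(kids_j, partner[pos])
        pos <- partner[pos] + 1L
        run_start <- pos
      } else {
        pos <- pos + 1L
      }
    }
    s_start <- c(s_start, run_start); s_end <- c(s_end, to)
    list(children = cbind(i = kids_i, j = kids_j),
         strands = cbind(start = s_start, end = s_end))
  }

  rows <- list()
  if (nrow(stems)) {
    for (sid in unique(stems$stem)) {
      sp <- stems[stems$stem == sid, ]
      a <- max(sp$i); b <- min(sp$j)        # innermost pair of the stem
      f <- face(a + 1L, b - 1L)
      n_child <- nrow(f$children)
      cls <- if (n_child == 0L) "hairpin" else if (n_child == 1L) "internal" else "junction"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        loop_class = cls, order = n_child + 1L,
        closing_i = a, closing_j = b,
        children = list(f$children), strands = list(f$strands),
        strand_lengths = list(as.integer(f$strands[, 2L] - f$strands[, 1L] + 1L))
      )
    }
  }
  if (include_exterior && ss$length > 0L) {
    f <- face(1L, ss$length)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      loop_class = "exterior", order = NA_integer_,
      closing_i = NA_integer_, closing_j = NA_integer_,
      children = list(f$children), strands = list(f$strands),
      strand_lengths = list(as.integer(f$strands[, 2L] - f$strands[, 1L] + 1L))
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(loop_class = character(), order = integer(),
                          closing_i = integer(), closing_j = integer(),
                          children = list(), strands = list(),
                          strand_lengths = list()))
  }
  dplyr::bind_rows(rows)
}

#' Brute-force loop decomposition (independent oracle)
#'
#' Direct-containment enumeration, deliberately independent of
#' [find_stems()]: for each pair, the pairs it directly contains are found by
#' pairwise interval comparison; a pair closes a loop unless it stacks
#' directly onto a single child. Used to cross-check [decompose_loops()].
#'
#' @param ss A nested [rna_structure].
#' @return A tibble with columns `loop_class`, `order` and list-column
#'   `strand_lengths`, comparable to [decompose_loops()] as a multiset.
#' @export
brute_force_decompose <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  if (!is_nested(ss)) {
    stop("structure contains pseudoknots; run remove_pseudoknots() first",
         call. = FALSE)
  }
  p <- ss$pairs
  np <- nrow(p)
  rows <- list()
  direct_children <- function(lo, hi) {
    # pairs strictly inside (lo, hi) and not inside any other pair inside it
    inside <- which(p[, 1L] > lo & p[, 2L] < hi)
    keep <- inside[vapply(inside, function(r) {
      !any(p[inside, 1L] < p[r, 1L] & p[inside, 2L] > p[r, 2L])
    }, logical(1))]
    keep[order(p[keep, 1L])]
  }
  strand_lens <- function(lo, hi, kids) {
    bounds_l <- c(lo, p[kids, 2L])
    bounds_r <- c(p[kids, 1L], hi)
    as.integer(bounds_r - bounds_l - 1L)
  }
  for (r in seq_len(np)) {
    kids <- direct_children(p[r, 1L], p[r, 2L])
    if (length(kids) == 1L && p[kids, 1L] == p[r, 1L] + 1L &&
        p[kids, 2L] == p[r, 2L] - 1L) next   # stacked: interior of a stem
    n_child <- length(kids)
    cls <- if (n_child == 0L) "hairpin" else if (n_child == 1L) "internal" else "junction"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      loop_class = cls, order = n_child + 1L,
      strand_lengths = list(strand_lens(p[r, 1L], p[r, 2L], kids))
    )
  }
  top <- which(!vapply(seq_len(np), function(r) {
    any(p[, 1L] < p[r, 1L] & p[, 2L] > p[r, 2L])
  }, logical(1)))
  if (np) top <- top[order(p[top, 1L])] else top <- integer(0)
  if (ss$length > 0L) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      loop_class = "exterior", order = NA_integer_,
      strand_lengths = list(strand_lens(0L, ss$length + 1L, top))
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(loop_class = character(), order = integer(),
                          strand_lengths = list()))
  }
  dplyr::bind_rows(rows)
}

#' Per-strand unpaired counts of a junction
#'
#' Returns the counts of unpaired residues in each strand of a multiloop, in
#' 5'-to-3' order starting after the closing pair's opening position. These
#' counts are the feature vector used for junction-based classification.
#'
#' @param loop One row of [decompose_loops()] output (or a list with
#'   `loop_class` and `strand_lengths`).
#' @param generalize Allow any closed loop order; when `FALSE` (default) only
#'   3-way junctions are accepted.
#' @return Integer vector of strand lengths (length = loop order).
#' @export
junction_features <- function(loop, generalize = FALSE) {
  if (is.data.frame(loop)) {
    stopifnot(nrow(loop) == 1L)
    loop <- as.list(loop[1L, ])
    loop$strand_lengths <- loop$strand_lengths[[1L]]
  }
  if (identical(loop$loop_class, "exterior")) {
    stop("the exterior region is not a junction", call. = FALSE)
  }
  lens <- as.integer(loop$strand_lengths)
  if (!generalize && length(lens) != 3L) {
    stop("loop has order ", length(lens), ", expected a 3-way junction",
         call. = FALSE)
  }
  lens
}

#' Generate the three design-target instances for a loop
#'
#' For a loop of order >= 2 the dataset stores three instances: (1) the
#' isolated loop (closing pair, child outermost pairs and loop strands),
#' (2) the loop extended with its connecting stems (the full enclosing helix
#' and the full child helices), and (3) the entire structure. Discontinuities
#' created by excising a child helix's enclosed subtree are spliced with
#' `cap_length` unpaired positions (`N` in the sequence, `.` in the
#' structure) so every emitted dot-bracket is well formed with hairpins of at
#' least `cap_length`; the reported lengths count only original positions.
#'
#' @param ss A nested [rna_structure] carrying a sequence.
#' @param loop One row of [decompose_loops()] output for `ss`.
#' @param cap_length Number of spliced-in unpaired positions per excision
#'   (default 3; 0 emits the raw discontinuous fragment).
#' @return A one-row tibble with columns `loop_seq`, `loop_db`,
#'   `loop_stems_seq`, `loop_stems_db`, `full_seq`, `full_db`, `len_loop`,
#'   `len_loop_stems`, `len_full`.
#' @export
make_instances <- function(ss, loop, cap_length = 3L) {
  stopifnot(inherits(ss, "rna_structure"))
  if (is.null(ss$sequence)) stop("`ss` must carry a sequence", call. = FALSE)
  if (is.data.frame(loop)) {
    stopifnot(nrow(loop) == 1L)
    loop <- as.list(loop[1L, ])
    loop$children <- loop$children[[1L]]
    loop$strands <- loop$strands[[1L]]
    loop$strand_lengths <- loop$strand_lengths[[1L]]
  }
  if (identical(loop$loop_class, "exterior") || loop$order < 2L) {
    stop("design-target instances are generated only for loops of order >= 2",
         call. = FALSE)
  }
  partner <- pair_partners(ss)
  kids <- loop$children
  strands <- loop$strands

  strand_pos <- unlist(lapply(seq_len(nrow(strands)), function(r) {
    if (strands[r, 2L] >= strands[r, 1L]) strands[r, 1L]:strands[r, 2L] else integer(0)
  }))

  # instance 1: closing pair + child outermost pairs + strands
  loop_pos <- sort(c(loop$closing_i, loop$closing_j,
                     as.integer(kids), strand_pos))

  # instance 2: whole enclosing helix + whole child helices + strands
  helix_out <- function(i, j) {   # extend outward from (i, j) while stacked
    pos <- c(i, j)
    while (i - 1L >= 1L && j + 1L <= ss$length && partner[i - 1L] == j + 1L) {
      i <- i - 1L; j <- j + 1L
      pos <- c(pos, i, j)
    }
    pos
  }
  helix_in <- function(i, j) {    # extend inward from (i, j) while stacked
    pos <- c(i, j)
    while (i + 1L < j - 1L && partner[i + 1L] == j - 1L) {
      i <- i + 1L; j <- j - 1L
      pos <- c(pos, i, j)
    }
    pos
  }
  stems_pos <- helix_out(loop$closing_i, loop$closing_j)
  for (r in seq_len(nrow(kids))) {
    stems_pos <- c(stems_pos, helix_in(kids[r, 1L], kids[r, 2L]))
  }
  loop_stems_pos <- sort(unique(c(stems_pos, strand_pos)))

  inst1 <- .splice(ss, loop_pos, cap_length)
  inst2 <- .splice(ss, loop_stems_pos, cap_length)
  tibble::tibble(
    loop_seq = inst1$seq,
    loop_db = inst1$db,
    loop_stems_seq = inst2$seq,
    loop_stems_db = inst2$db,
    full_seq = ss$sequence,
    full_db = write_dotbracket(ss),
    len_loop = length(loop_pos),
    len_loop_stems = length(loop_stems_pos),
    len_full = ss$length
  )
}

# Extract the sub-instance at `positions`, splicing `cap` N/. positions into
# every internal discontinuity. Pairs are kept when both partners are present.
.splice <- function(ss, positions, cap) {
  positions <- sort(positions)
  chars <- strsplit(ss$sequence, "", fixed = TRUE)[[1L]]
  partner <- pair_partners(ss)
  n <- length(positions)
  gap_before <- c(FALSE, diff(positions) > 1L)
  emitted_index <- integer(ss$length)
  out_seq <- character(0)
  k <- 0L
  for (r in seq_len(n)) {
    if (gap_before[r]) {
      out_seq <- c(out_seq, rep("N", cap))
      k <- k + cap
    }
    k <- k + 1L
    emitted_index[positions[r]] <- k
    out_seq <- c(out_seq, chars[positions[r]])
  }
  keep <- positions[partner[positions] > positions &
                    partner[positions] %in% positions]
  pairs <- cbind(emitted_index[keep], emitted_index[partner[keep]])
  sub <- rna_structure(k, pairs, sequence = paste(out_seq, collapse = ""))
  list(seq = sub$sequence, db = write_dotbracket(sub))
}

#' Generate a random nested structure with a consistent sequence
#'
#' Recursive sampler for synthetic fixtures: each loop face draws its number
#' of child helices from `branching_weights`, helix lengths and strand
#' allocations are sampled uniformly at random, hairpin loops are at least
#' `min_hairpin` long, and paired positions receive letters drawn from
#' complementary pairs (GC/AU/GU with weights 0.6/0.3/0.1) while unpaired
#' positions are uniform over A, C, G, U. The same seed always reproduces the
#' same structure.
#'
#' @param length Total structure length (>= 1).
#' @param branching_weights Numeric weights for 0, 1, 2, ... child helices at
#'   a loop face; the default gives mostly unbranched faces with a tail of
#'   multibranch loops, echoing the loop-class mix of natural RNA.
#' @param min_hairpin Minimum unpaired run closing a hairpin (default 3).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param pair_density Probability that the exterior face carries helices at
#'   all; also damps recursion depth indirectly.
#' @return An [rna_structure] with a sequence.
#' @export
generate_random_structure <- function(length,
                                      branching_weights = c(0.34, 0.46, 0.12, 0.05, 0.03),
                                      min_hairpin = 3L,
                                      seed = NULL,
                                      pair_density = 0.95) {
  length <- as.integer(length)
  if (length < 1L) stop("`length` must be >= 1", call. = FALSE)
  min_hairpin <- as.integer(min_hairpin)
  min_child <- min_hairpin + 2L   # one pair wrapping a minimal hairpin
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      generate_random_structure(length, branching_weights, min_hairpin,
                                seed = NULL, pair_density = pair_density)))
  }

  pairs_i <- integer(0); pairs_j <- integer(0)

  # fill [from, to] as a loop face with k children drawn from the weights
  fill_face <- function(from, to, exterior = FALSE) {
    n <- to - from + 1L
    if (n <= 0L) return(invisible())
    k_max <- n %/% min_child
    w <- branching_weights[seq_len(min(length(branching_weights), k_max + 1L))]
    if (n >= 25L && length(w) > 1L) w[1L] <- w[1L] * 0.15  # avoid giant hairpins
    if (sum(w) <= 0) return(invisible())
    k <- sample.int(length(w), 1L, prob = w) - 1L
    if (exterior && k == 0L && k_max >= 1L && stats::runif(1) < pair_density) k <- 1L
    if (k == 0L) return(invisible())
    # split n positions into k child blocks (each >= min_child) + k+1 strands
    spare <- n - k * min_child
    cuts <- c(0L, sort(sample.int(spare + 1L, 2L * k, replace = TRUE) - 1L), spare)
    alloc <- diff(cuts)                     # 2k+1 non-negative extents
    pos <- from
    for (child in seq_len(k)) {
      pos <- pos + alloc[2L * child - 1L]   # leading strand
      size <- min_child + alloc[2L * child]
      build_helix(pos, pos + size - 1L)
      pos <- pos + size
    }
    invisible()
  }

  # wrap [from, to] in a helix, then recurse on the interior
  build_helix <- function(from, to) {
    n <- to - from + 1L
    h_max <- (n - min_hairpin) %/% 2L
    h <- sample.int(min(h_max, 8L), 1L)   # natural helices are short
    for (d in seq_len(h) - 1L) {
      pairs_i <<- c(pairs_i, from + d)
      pairs_j <<- c(pairs_j, to - d)
    }
    inner_from <- from + h; inner_to <- to - h
    inner_n <- inner_to - inner_from + 1L
    if (inner_n >= min_child + 0L && inner_n >= min_hairpin) {
      # interior may branch further; if it ends up with no children it is a
      # hairpin of length inner_n >= min_hairpin
      fill_face(inner_from, inner_to)
    }
    invisible()
  }

  fill_face(1L, length, exterior = TRUE)

  partner <- integer(length)
  partner[pairs_i] <- pairs_j
  partner[pairs_j] <- pairs_i
  chars <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
  if (length(pairs_i)) {
    duos <- sample(c("GC", "CG", "AU", "UA", "GU", "UG"), length(pairs_i),
                   replace = TRUE, prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05))
    chars[pairs_i] <- substr(duos, 1L, 1L)
    chars[pairs_j] <- substr(duos, 2L, 2L)
  }
  rna_structure(length, cbind(pairs_i, pairs_j),
                sequence = paste(chars, collapse = ""))
}
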