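# WUSS characters treated as unpaired in SS_cons lines.
.wuss_unpaired <- c(".", ":", "_", "-", "~", ",")

#' Aligned RNA family
#'
#' An aligned family holds a seed multiple sequence alignment and the
#' consensus secondary structure read from its `#=GC SS_cons` line: gapped
#' rows of common width plus consensus base pairs given as column-index pairs,
#' each labelled with its bracket layer (primary brackets vs pseudoknot letter
#' layers).
#'
#' @param accession Family identifier string (e.g. an Rfam accession).
#' @param rows Tibble/data frame with columns `id` and `seq` (gapped, equal
#'   widths).
#' @param consensus_pairs Tibble with integer columns `i`, `j` (1-based
#'   alignment columns, `i < j`) and character column `layer`.
#' @param n_columns Alignment width.
#' @return An object of class `rna_family`.
#' @export
rna_family <- function(accession, rows, consensus_pairs, n_columns) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("id", "seq") %in% names(rows)))
  n_columns <- as.integer(n_columns)
  if (nrow(rows) && any(nchar(rows$seq) != n_columns)) {
    bad <- which(nchar(rows$seq) != n_columns)[1L]
    stop("alignment row ", bad, " ('", rows$id[bad], "') has width ",
         nchar(rows$seq[bad]), ", expected ", n_columns, call. = FALSE)
  }
  cp <- tibble::as_tibble(consensus_pairs)
  if (!nrow(cp)) cp <- tibble::tibble(i = integer(), j = integer(), layer = character())
  stopifnot(all(c("i", "j", "layer") %in% names(cp)))
  if (nrow(cp)) {
    if (any(cp$i >= cp$j) || any(cp$i < 1L) || any(cp$j > n_columns)) {
      stop("consensus pair columns out of range", call. = FALSE)
    }
    cols <- c(cp$i, cp$j)
    if (anyDuplicated(cols)) {
      stop("alignment column ", cols[duplicated(cols)][1L],
           " is used by two consensus pairs", call. = FALSE)
    }
  }
  structure(list(accession = accession, rows = rows,
                 consensus_pairs = cp, n_columns = n_columns),
            class = "rna_family")
}

#' @export
print.rna_family <- function(x, ...) {
  cat("<rna_family>", x$accession, "-", nrow(x$rows), "rows x",
      x$n_columns, "columns,", nrow(x$consensus_pairs), "consensus pairs\n")
  invisible(x)
}

#' Read a Stockholm seed alignment with a WUSS consensus line
#'
#' Parses a (possibly multi-block / wrapped) Stockholm file into an
#' [rna_family]. The `#=GC SS_cons` line is interpreted per WUSS: the bracket
#' layers `<>`, `()`, `[]`, `{}` are primary-compatible; uppercase/lowercase
#' letter pairs (`Aa`...) are pseudoknot layers; all of `. : _ - ~ ,` are
#' unpaired. Any other character, an unbalanced bracket, or a column claimed by
#' two pairs is an error.
#'
#' @param x Path to a Stockholm file, or a character vector of lines.
#' @param accession Optional family accession; defaults to the `#=GF AC` tag
#'   when present, else `"unknown"`.
#' @return An [rna_family].
#' @export
read_stockholm <- function(x, accession = NULL) {
  lines <- .as_lines(x)
  seq_ids <- character(0)
  seqs <- list()
  ss_cons <- ""
  gf_ac <- NULL
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || ln == "//" || grepl("^# STOCKHOLM", ln)) next
    if (grepl("^#=GF\\s+AC\\s+", ln)) {
      gf_ac <- sub("^#=GF\\s+AC\\s+(\\S+).*$", "\\1", ln)
      next
    }
    if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
      ss_cons <- paste0(ss_cons, sub("^#=GC\\s+SS_cons\\s+(\\S+).*$", "\\1", ln))
      next
    }
    if (grepl("^#", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) != 2L) stop("malformed Stockholm line: ", ln, call. = FALSE)
    id <- f[1L]
    if (!id %in% seq_ids) {
      seq_ids <- c(seq_ids, id)
      seqs[[id]] <- f[2L]
    } else {
      seqs[[id]] <- paste0(seqs[[id]], f[2L])   # wrapped block continuation
    }
  }
  if (!nzchar(ss_cons)) stop("Stockholm input has no #=GC SS_cons line", call. = FALSE)
  widths <- nchar(unlist(seqs, use.names = FALSE))
  n_col <- nchar(ss_cons)
  if (length(widths) && any(widths != n_col)) {
    stop("row width mismatch: SS_cons has ", n_col, " columns but row '",
         seq_ids[which(widths != n_col)[1L]], "' has ",
         widths[widths != n_col][1L], call. = FALSE)
  }
  cp <- parse_wuss(ss_cons)
  if (is.null(accession)) accession <- gf_ac %||% "unknown"
  rna_family(accession,
             tibble::tibble(id = seq_ids,
                            seq = unlist(seqs, use.names = FALSE)),
             cp, n_col)
}

#' Parse a WUSS consensus-structure line into column pairs
#'
#' @param ss WUSS string (one line, no whitespace).
#' @return Tibble with columns `i`, `j`, `layer`.
#' @export
parse_wuss <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  stacks <- vector("list", length(.bracket_layers))
  pi <- integer(0); pj <- integer(0); pl <- character(0)
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% .wuss_unpaired) next
    li <- match(ch, .layer_open)
    if (!is.na(li)) { stacks[[li]] <- c(stacks[[li]], k); next }
    li <- match(ch, .layer_close)
    if (!is.na(li)) {
      st <- stacks[[li]]
      if (length(st) == 0L) {
        stop("WUSS: unbalanced '", ch, "' at column ", k, call. = FALSE)
      }
      pi <- c(pi, st[length(st)]); pj <- c(pj, k)
      pl <- c(pl, .bracket_layers[li])
      stacks[[li]] <- st[-length(st)]
      next
    }
    stop("WUSS: unexpected character '", ch, "' at column ", k, call. = FALSE)
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left)) {
    stop("WUSS: unbalanced '", .layer_open[left[1L]], "' at column ",
         stacks[[left[1L]]][1L], call. = FALSE)
  }
  cols <- c(pi, pj)
  if (anyDuplicated(cols)) {
    stop("WUSS: column ", cols[duplicated(cols)][1L],
         " is claimed by two layers", call. = FALSE)
  }
  tibble::tibble(i = pi, j = pj, layer = pl)
}

#' Write an aligned family as a Stockholm file
#'
#' @param family An [rna_family].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_stockholm <- function(family, path = NULL) {
  stopifnot(inherits(family, "rna_family"))
  ss <- rep(".", family$n_columns)
  cp <- family$consensus_pairs
  if (nrow(cp)) {
    li <- match(cp$layer, .bracket_layers)
    ss[cp$i] <- .layer_open[li]
    ss[cp$j] <- .layer_close[li]
  }
  w <- max(nchar(c(family$rows$id, "#=GC SS_cons")))
  lines <- c("# STOCKHOLM 1.0",
             paste("#=GF AC", family$accession),
             sprintf("%-*s %s", w, family$rows$id, family$rows$seq),
             sprintf("%-*s %s", w, "#=GC SS_cons", paste(ss, collapse = "")),
             "//")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
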