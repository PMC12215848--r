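#' Read a BPSEQ structure
#'
#' BPSEQ is the per-residue format `index base partner`, one line per residue,
#' with partner `0` for unpaired positions. Indices must run 1..L without gaps
#' and partner references must be reciprocal.
#'
#' @param x Path to a BPSEQ file, or a character vector of lines.
#' @return An [rna_structure] carrying the sequence.
#' @export
read_bpseq <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("BPSEQ input is empty", call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("BPSEQ line ", bad[1L], ": expected 'index base partner'", call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  base <- vapply(fields, `[`, "", 2L)
  partner <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(idx) || anyNA(partner)) {
    stop("BPSEQ line ", which(is.na(idx) | is.na(partner))[1L],
         ": non-numeric index or partner", call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("BPSEQ: duplicate index ", idx[duplicated(idx)][1L], call. = FALSE)
  }
  n <- length(idx)
  if (!setequal(idx, seq_len(n))) {
    missing <- setdiff(seq_len(n), idx)[1L]
    stop("BPSEQ: index sequence has a gap (missing ", missing, ")", call. = FALSE)
  }
  ord <- order(idx)
  base <- base[ord]; partner <- partner[ord]
  if (any(partner < 0L | partner > n)) {
    stop("BPSEQ: partner out of range at line ",
         which(partner < 0L | partner > n)[1L], call. = FALSE)
  }
  paired <- which(partner > 0L)
  nonrec <- paired[partner[partner[paired]] != paired | partner[paired] == paired]
  if (length(nonrec)) {
    stop("BPSEQ line ", nonrec[1L], ": non-reciprocal partner (", nonrec[1L],
         " -> ", partner[nonrec[1L]], ")", call. = FALSE)
  }
  i <- paired[paired < partner[paired]]
  rna_structure(n, cbind(i, partner[i]),
                sequence = paste(base, collapse = ""))
}

#' Write a structure as BPSEQ lines
#'
#' @param ss An [rna_structure]; positions without sequence are written as `N`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_bpseq <- function(ss, path = NULL) {
  stopifnot(inherits(ss, "rna_structure"))
  partner <- pair_partners(ss)
  bases <- if (is.null(ss$sequence)) rep("N", ss$length)
           else strsplit(ss$sequence, "")[[1L]]
  lines <- paste(seq_len(ss$length), bases, partner)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a CT structure
#'
#' Connectivity-table format: a header line whose first field is the residue
#' count, then six-column rows `index base prev next partner index`.
#'
#' @param x Path to a CT file, or a character vector of lines.
#' @return An [rna_structure] carrying the sequence.
#' @export
read_ct <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 1L) stop("CT input is empty", call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
  if (is.na(n) || n < 0L) stop("CT header: residue count missing", call. = FALSE)
  body <- lines[-1L]
  if (length(body) != n) {
    stop("CT header says ", n, " rows but ", length(body), " present", call. = FALSE)
  }
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) stop("CT row ", bad[1L], ": expected 6 columns", call. = FALSE)
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  base <- vapply(fields, `[`, "", 2L)
  partner <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  if (anyNA(idx) || anyNA(partner)) stop("CT: non-numeric field", call. = FALSE)
  if (anyDuplicated(idx)) {
    stop("CT: duplicate index ", idx[duplicated(idx)][1L], call. = FALSE)
  }
  if (!setequal(idx, seq_len(n))) stop("CT: index sequence has a gap", call. = FALSE)
  ord <- order(idx)
  base <- base[ord]; partner <- partner[ord]
  if (any(partner < 0L | partner > n)) stop("CT: partner out of range", call. = FALSE)
  paired <- which(partner > 0L)
  nonrec <- paired[partner[partner[paired]] != paired | partner[paired] == paired]
  if (length(nonrec)) {
    stop("CT row ", nonrec[1L], ": non-reciprocal partner", call. = FALSE)
  }
  i <- paired[paired < partner[paired]]
  rna_structure(n, cbind(i, partner[i]), sequence = paste(base, collapse = ""))
}

#' Write a structure as CT lines
#'
#' @inheritParams write_bpseq
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_ct <- function(ss, path = NULL) {
  stopifnot(inherits(ss, "rna_structure"))
  partner <- pair_partners(ss)
  n <- ss$length
  bases <- if (is.null(ss$sequence)) rep("N", n) else strsplit(ss$sequence, "")[[1L]]
  idx <- seq_len(n)
  lines <- c(paste(n, "rnaloopkit"),
             paste(idx, bases, idx - 1L, ifelse(idx == n, 0L, idx + 1L),
                   partner, idx))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a tibble; `T` is
#' converted to `U`.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  tibble::tibble(id = names(set), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble/data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(stats::setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Columns of the loop-motif dataset CSV, in order.
dataset_columns <- c(
  "source_db", "source_id", "family_or_pdb", "loop_type", "loop_order",
  "category", "loop_seq", "loop_db", "loop_stems_seq", "loop_stems_db",
  "full_seq", "full_db", "len_loop", "len_loop_stems", "len_full"
)

#' Read a loop-motif dataset CSV
#'
#' The dataset CSV has exactly the columns `source_db, source_id,
#' family_or_pdb, loop_type, loop_order, category, loop_seq, loop_db,
#' loop_stems_seq, loop_stems_db, full_seq, full_db, len_loop, len_loop_stems,
#' len_full` (comma-separated, header row, UTF-8). Each row is one loop with
#' its three design-target instances.
#'
#' @param path CSV file path.
#' @return A tibble of dataset records.
#' @export
read_dataset_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          loop_order = readr::col_integer(),
                          len_loop = readr::col_integer(),
                          len_loop_stems = readr::col_integer(),
                          len_full = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  miss <- setdiff(dataset_columns, names(df))
  if (length(miss)) {
    stop("dataset CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[dataset_columns]
  bad <- which(nchar(df$loop_seq) != nchar(df$loop_db) |
               nchar(df$loop_stems_seq) != nchar(df$loop_stems_db) |
               nchar(df$full_seq) != nchar(df$full_db))
  if (length(bad)) {
    stop("dataset CSV row ", bad[1L],
         ": sequence/structure length mismatch", call. = FALSE)
  }
  df
}

#' Write a loop-motif dataset CSV
#'
#' @param records Tibble of dataset records (see [read_dataset_csv()] for the
#'   schema). An empty tibble yields a header-only file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(records, path) {
  miss <- setdiff(dataset_columns, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(records[dataset_columns], path)
  invisible(path)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(readLines(x))
  if (length(x) == 1L && grepl("\n", x)) return(strsplit(x, "\n")[[1L]])
  x
}
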