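#' Check that the ViennaRNA command-line tools are available
#'
#' @param tool Binary name (`RNAfold`, `RNApdist`, `RNAdistance`, `RNAeval`).
#' @return Full path to the binary; errors when absent.
#' @keywords internal
.vienna_bin <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop("ViennaRNA backend unavailable: '", tool, "' not found on PATH",
         call. = FALSE)
  }
  path
}

#' Is the ViennaRNA backend available?
#'
#' @return Logical scalar.
#' @export
vienna_available <- function() {
  all(nzchar(Sys.which(c("RNAfold", "RNApdist", "RNAdistance", "RNAeval"))))
}

#' Fold a sequence with RNAfold
#'
#' Runs the external `RNAfold -p` and parses the minimum-free-energy
#' structure, its energy and the ensemble free energy from the
#' partition-function run. With a `constraint` dot-bracket the given pairs
#' are enforced as hard constraints.
#'
#' @param sequence RNA sequence (non-empty).
#' @param constraint Optional dot-bracket hard-constraint string of the same
#'   length.
#' @return List with `structure` (dot-bracket), `mfe` and `ensemble_energy`
#'   (kcal/mol).
#' @export
rnafold <- function(sequence, constraint = NULL) {
  if (!nzchar(sequence %||% "")) stop("empty sequence", call. = FALSE)
  bin <- .vienna_bin("RNAfold")
  args <- c("-p", "--noPS", "--noDP")
  input <- sequence
  if (!is.null(constraint)) {
    if (nchar(constraint) != nchar(sequence)) {
      stop("constraint length differs from sequence length", call. = FALSE)
    }
    args <- c(args, "-C")
    input <- c(sequence, constraint)
  }
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, input = input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAfold exited with status ", status, call. = FALSE)
  }
  mfe_line <- grep("^[.()]+\\s+\\(\\s*-?[0-9.]+\\)", out, value = TRUE)
  if (!length(mfe_line)) stop("could not parse RNAfold output", call. = FALSE)
  structure_db <- sub("\\s.*$", "", mfe_line[1L])
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", mfe_line[1L]))
  # partition-function run prints the ensemble free energy either in square
  # brackets after the pairing-probability string or in a prose line
  ee_line <- grep("free energy of ensemble", out, value = TRUE)
  ee <- if (length(ee_line)) {
    as.numeric(sub("^.*ensemble\\s*=?\\s*(-?[0-9.]+).*$", "\\1", ee_line[1L]))
  } else {
    br <- grep("\\[\\s*-?[0-9.]+\\s*\\]", out, value = TRUE)
    if (length(br)) {
      as.numeric(sub("^.*\\[\\s*(-?[0-9.]+)\\s*\\].*$", "\\1", br[1L]))
    } else NA_real_
  }
  list(structure = structure_db, mfe = mfe, ensemble_energy = ee)
}

#' Ensemble distance between two sequences with RNApdist
#'
#' Compares the thermodynamic base-pairing-probability ensembles of two
#' sequences with the external `RNApdist`.
#'
#' @param seq_a,seq_b RNA sequences.
#' @return Non-negative number; 0 for identical sequences.
#' @export
rnapdist <- function(seq_a, seq_b) {
  if (!nzchar(seq_a %||% "") || !nzchar(seq_b %||% "")) {
    stop("empty sequence", call. = FALSE)
  }
  bin <- .vienna_bin("RNApdist")
  out <- suppressWarnings(system2(bin, "--compare=p", stdout = TRUE,
                                  input = c(seq_a, seq_b)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNApdist exited with status ", status, call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(sub("^.*\\s", "", out[nzchar(out)])))
  val <- val[!is.na(val)]
  if (!length(val)) stop("could not parse RNApdist output", call. = FALSE)
  val[1L]
}

#' Structure distance via the reference RNAdistance binary
#'
#' Used as the external oracle for [tree_edit_distance()].
#'
#' @param db_a,db_b Dot-bracket strings.
#' @return The reference full-structure distance.
#' @export
rnadistance_ref <- function(db_a, db_b) {
  bin <- .vienna_bin("RNAdistance")
  out <- suppressWarnings(system2(bin, stdout = TRUE, input = c(db_a, db_b)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAdistance exited with status ", status, call. = FALSE)
  }
  line <- grep("^f:", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAdistance output", call. = FALSE)
  as.numeric(sub("^f:\\s*([0-9.]+).*$", "\\1", line[1L]))
}

#' Free energy of a sequence in a fixed structure with RNAeval
#'
#' @param sequence RNA sequence.
#' @param structure_db Dot-bracket structure of the same length.
#' @return Energy in kcal/mol.
#' @export
rna_eval <- function(sequence, structure_db) {
  if (!nzchar(sequence %||% "")) stop("empty sequence", call. = FALSE)
  if (nchar(sequence) != nchar(structure_db)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  bin <- .vienna_bin("RNAeval")
  out <- suppressWarnings(system2(bin, stdout = TRUE,
                                  input = c(sequence, structure_db)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAeval exited with status ", status, call. = FALSE)
  }
  line <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAeval output", call. = FALSE)
  as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line[length(line)]))
}

#' Candidate energetics for multi-target selection
#'
#' Computes, for one candidate sequence, the MFE and ensemble energy (via
#' [rnafold()]), each target's energy (via [rna_eval()]) and Boltzmann
#' probability, and their sum `psum`.
#'
#' @param sequence Candidate sequence.
#' @param target_dbs Character vector of target dot-bracket structures.
#' @param RT Thermal energy (kcal/mol).
#' @return One-row tibble with `sequence`, `mfe`, `ensemble_energy`, `psum`.
#' @export
candidate_energetics <- function(sequence, target_dbs, RT = 0.61633) {
  fold <- rnafold(sequence)
  e_t <- vapply(target_dbs, function(db) rna_eval(sequence, db), numeric(1))
  p_t <- target_probability(e_t, fold$ensemble_energy, RT)
  tibble::tibble(sequence = sequence, mfe = fold$mfe,
                 ensemble_energy = fold$ensemble_energy, psum = sum(p_t))
}
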