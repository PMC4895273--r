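#' Read a single protein sequence from FASTA
#'
#' Thin wrapper over `seqinr::read.fasta` returning the first sequence as an
#' uppercase one-letter character vector.
#'
#' @param path Path to a FASTA file.
#' @return Character vector of residue letters, with the FASTA id as
#'   attribute `id`.
#' @export
read_fasta_seq <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                           forceDNAtolower = FALSE)
  if (length(fa) == 0L) stop("no sequences in FASTA file: ", path)
  s <- toupper(as.character(fa[[1]]))
  attr(s, "id") <- names(fa)[1]
  s
}

pssm_data_row <- function(tokens) {
  length(tokens) >= 2L && grepl("^[0-9]+$", tokens[1]) &&
    grepl("^[A-Za-z]$", tokens[2])
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-Q` ASCII dialect: header lines, then one row per residue with
#' the residue index and letter, 20 integer log-odds scores, 20 weighted
#' percentages, the information per position and the relative weight. Only
#' the log-odds block and the information column are kept.
#'
#' @param path Path to the PSSM file.
#' @param sequence Optional residue letters to cross-check row letters and
#'   length against.
#' @return List with `scores` (n x 20 integer matrix, columns named by the
#'   file's amino-acid header order), `info` (numeric vector of information
#'   per position) and `residues` (letters from the file).
#' @export
read_pssm <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  aa_order <- NULL
  scores <- list(); info <- numeric(0); residues <- character(0)
  last_good <- 0L
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tokens) == 0L) next
    if (is.null(aa_order) && length(tokens) >= 40L &&
        all(grepl("^[A-Z]$", tokens))) {
      aa_order <- tokens[1:20]
      next
    }
    if (!pssm_data_row(tokens)) next
    if (length(tokens) < 43L) {
      stop("truncated PSSM row at line ", i, " of ", path,
           " (last good line: ", last_good, ")")
    }
    sc <- suppressWarnings(as.integer(tokens[3:22]))
    inf <- suppressWarnings(as.numeric(tokens[43]))
    if (anyNA(sc) || is.na(inf)) {
      stop("non-numeric PSSM cell at line ", i, " of ", path)
    }
    scores[[length(scores) + 1L]] <- sc
    info <- c(info, inf)
    residues <- c(residues, toupper(tokens[2]))
    last_good <- i
  }
  if (length(scores) == 0L) stop("no PSSM rows found in ", path)
  scores <- do.call(rbind, scores)
  if (!is.null(aa_order)) colnames(scores) <- aa_order
  if (!is.null(sequence)) {
    if (nrow(scores) != length(sequence)) {
      stop("PSSM length (", nrow(scores), ") != sequence length (",
           length(sequence), ") for ", path)
    }
    mism <- which(residues != sequence & sequence != "X")
    if (length(mism) > 0L) {
      stop("PSSM residue letters disagree with FASTA at position(s) ",
           paste(utils::head(mism, 5), collapse = ", "), " in ", path)
    }
  }
  list(scores = scores, info = info, residues = residues)
}

parse_numeric_track <- function(path, value_cols, what) {
  lines <- readLines(path, warn = FALSE)
  rows <- list(); residues <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tokens <- strsplit(ln, "[[:space:]]+")[[1]]
    if (!grepl("^[0-9]+$", tokens[1])) next
    if (length(tokens) < max(value_cols)) {
      stop("truncated ", what, " row at line ", i, " of ", path)
    }
    vals <- suppressWarnings(as.numeric(tokens[value_cols]))
    if (anyNA(vals)) stop("non-numeric ", what, " cell at line ", i,
                          " of ", path)
    rows[[length(rows) + 1L]] <- vals
    residues <- c(residues, toupper(tokens[2]))
  }
  if (length(rows) == 0L) stop("no ", what, " rows found in ", path)
  list(values = do.call(rbind, rows), residues = residues)
}

check_track_length <- function(n, sequence, path, what) {
  if (!is.null(sequence) && n != length(sequence)) {
    stop(what, " length (", n, ") != sequence length (", length(sequence),
         ") for ", path)
  }
}

#' Parse PSIPRED `.ss2` secondary-structure probabilities
#'
#' Data rows are `index letter state pC pH pE`; the three class
#' probabilities (coil, helix, strand) are returned. Header/comment lines
#' are skipped.
#'
#' @param path Path to the `.ss2` file.
#' @param sequence Optional residue letters for a length check.
#' @return Numeric matrix (n x 3, columns `C`, `H`, `E`).
#' @export
read_ss2 <- function(path, sequence = NULL) {
  p <- parse_numeric_track(path, value_cols = 4:6, what = ".ss2")
  check_track_length(nrow(p$values), sequence, path, ".ss2")
  colnames(p$values) <- c("C", "H", "E")
  p$values
}

#' Parse DISOPRED per-residue disorder output
#'
#' Data rows are `index letter p_disordered p_ordered`; comment lines begin
#' with `#`.
#'
#' @param path Path to the disorder file.
#' @param sequence Optional residue letters for a length check.
#' @return Numeric matrix (n x 2, columns `diso`, `ord`).
#' @export
read_diso <- function(path, sequence = NULL) {
  p <- parse_numeric_track(path, value_cols = 3:4, what = "disorder")
  check_track_length(nrow(p$values), sequence, path, "disorder")
  colnames(p$values) <- c("diso", "ord")
  p$values
}

#' Read a polar-fraction sidecar table
#'
#' The polar fraction F (fraction of side-chain area covered by polar atoms)
#' comes from structure and is supplied as a tab-separated sidecar with
#' columns `id`, `index`, `F`.
#'
#' @param path Path to the TSV file.
#' @param sequence Optional residue letters for a length check.
#' @return Numeric vector of F values ordered by `index`.
#' @export
read_polar <- function(path, sequence = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "index", "F")
  if (!all(need %in% names(d))) {
    stop("polar-fraction table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  d <- d[order(d$index), ]
  check_track_length(nrow(d), sequence, path, "polar fraction")
  as.numeric(d$F)
}
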