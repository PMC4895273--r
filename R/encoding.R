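FEATURE_FAMILIES <- c("PSSM", "SS", "DISO", "SCE", "CS")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SCE_CLASSES <- c("B1", "B2", "B3", "P1", "P2", "E")

#' Per-residue record of a protein
#'
#' Bundles a protein's sequence with its aligned per-residue feature tracks
#' and optional structure-derived labels. All present tracks must have one
#' row/value per residue.
#'
#' @param id Protein identifier.
#' @param sequence Character vector of one-letter residue codes (20
#'   canonical letters; nonstandard residues as `X`).
#' @param pssm n x 20 matrix of PSI-BLAST log-odds scores.
#' @param info Numeric vector, PSSM information per position.
#' @param ss n x 3 matrix of secondary-structure probabilities (C, H, E).
#' @param diso n x 2 matrix of disorder probabilities (disordered, ordered).
#' @param rsa Optional RSA labels in `[0, 1]` (`NA` allowed for unlabelled
#'   residues).
#' @param polar Optional polar fraction F in `[0, 1]`.
#' @param asa Optional absolute accessibilities (\eqn{\AA^2}).
#' @return A `protein_record`.
#' @export
protein_record <- function(id, sequence, pssm = NULL, info = NULL, ss = NULL,
                           diso = NULL, rsa = NULL, polar = NULL,
                           asa = NULL) {
  n <- length(sequence)
  if (n == 0L) stop("empty sequence for protein ", id)
  chk <- function(x, what, ncol_need = NULL) {
    if (is.null(x)) return(invisible())
    rows <- if (is.matrix(x)) nrow(x) else length(x)
    if (rows != n) {
      stop(what, " track of protein ", id, " has length ", rows,
           " but the sequence has ", n, " residues")
    }
    if (!is.null(ncol_need) && ncol(x) != ncol_need) {
      stop(what, " track of protein ", id, " must have ", ncol_need,
           " columns")
    }
    if (!all(is.finite(x) | is.na(x))) {
      stop("non-finite values in ", what, " track of protein ", id)
    }
  }
  chk(pssm, "PSSM", 20L); chk(info, "information"); chk(ss, "SS", 3L)
  chk(diso, "disorder", 2L); chk(rsa, "RSA"); chk(polar, "polar fraction")
  chk(asa, "ASA")
  for (nm in c("ss", "diso")) {
    x <- get(nm)
    if (!is.null(x) && (any(x < 0, na.rm = TRUE) || any(x > 1, na.rm = TRUE))) {
      stop(nm, " probabilities of protein ", id, " outside [0, 1]")
    }
  }
  structure(list(id = id, sequence = toupper(sequence), pssm = pssm,
                 info = info, ss = ss, diso = diso, rsa = rsa, polar = polar,
                 asa = asa),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("protein_record", x$id, "-", length(x$sequence), "residues; tracks:",
      paste(c("pssm", "ss", "diso", "rsa", "polar")[
        !vapply(x[c("pssm", "ss", "diso", "rsa", "polar")], is.null,
                logical(1))], collapse = ", "), "\n")
  invisible(x)
}

#' Logistic normalisation of profile scores
#'
#' Maps a PSSM log-odds score onto `(0, 1)` with the standard logistic
#' function \eqn{x' = 1 / (1 + e^{-x})}.
#'
#' @param x Numeric vector (finite).
#' @return Values in `(0, 1)`.
#' @examples
#' logistic_normalize(c(-2, 0, 2))
#' @export
logistic_normalize <- function(x) 1 / (1 + exp(-x))

#' Number of encoded feature columns
#'
#' Closed form for the encoded width at window length `L = 2l + 1`:
#' `20L` (PSSM) + `3L` (SS) + `2L` (disorder) + `6` (side-chain environment)
#' + `L` (conservation), summed over the enabled families.
#'
#' @param half_width Window half width `l` (>= 0).
#' @param families Subset of `c("PSSM", "SS", "DISO", "SCE", "CS")`.
#' @return Integer column count.
#' @examples
#' n_feature_columns(3) # L = 7 -> 188
#' @export
n_feature_columns <- function(half_width, families = FEATURE_FAMILIES) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  L <- 2L * as.integer(half_width) + 1L
  per <- c(PSSM = 20L * L, SS = 3L * L, DISO = 2L * L, SCE = 6L, CS = L)
  sum(per[families])
}

#' Min-max bounds of the conservation score
#'
#' The conservation score is the PSSM information-per-position column,
#' rescaled to `[0, 1]` by min-max over the *training* residues. The bounds
#' are estimated once on training data and stored with the model so that
#' test-time values are scaled identically (and clipped into `[0, 1]`).
#'
#' @param info Numeric vector of information values (pooled training
#'   residues).
#' @return Numeric length-2 vector `c(min, max)`.
#' @export
conservation_bounds <- function(info) {
  if (length(info) == 0L) stop("empty information vector")
  range(info)
}

#' Apply conservation-score scaling
#'
#' @param info Numeric vector of information values.
#' @param bounds Training bounds from [conservation_bounds()]. Degenerate
#'   bounds (zero range) map every value to 0.5.
#' @return Values in `[0, 1]`.
#' @export
conservation_track <- function(info, bounds) {
  span <- bounds[2] - bounds[1]
  if (span <= 0) return(rep(0.5, length(info)))
  pmin(pmax((info - bounds[1]) / span, 0), 1)
}

#' Six-class side-chain environment of a residue
#'
#' Classifies burial from RSA and, within the buried/partially-buried
#' levels, the polar fraction F of the side-chain area covered by polar
#' atoms: `B` (buried) when RSA < 0.09, `P` (partially buried) when
#' 0.09 <= RSA < 0.36, `E` (exposed) when RSA >= 0.36; within `B`,
#' `B1` F < 0.45, `B2` 0.45 <= F < 0.58, `B3` F >= 0.58; within `P`,
#' `P1` F < 0.67, `P2` F >= 0.67.
#'
#' @param rsa,polar_fraction Numeric vectors in `[0, 1]` (equal length).
#' @return Factor with levels `B1 B2 B3 P1 P2 E`.
#' @examples
#' side_chain_class(c(0.05, 0.36, 0.20), c(0.50, 0.99, 0.70))
#' @export
side_chain_class <- function(rsa, polar_fraction) {
  stopifnot(length(rsa) == length(polar_fraction))
  if (any(rsa < 0 | rsa > 1 | polar_fraction < 0 | polar_fraction > 1,
          na.rm = TRUE)) {
    stop("'rsa' and 'polar_fraction' must lie in [0, 1]")
  }
  f <- polar_fraction
  cls <- ifelse(rsa >= 0.36, "E",
         ifelse(rsa >= 0.09,
                ifelse(f < 0.67, "P1", "P2"),
                ifelse(f < 0.45, "B1", ifelse(f < 0.58, "B2", "B3"))))
  factor(cls, levels = SCE_CLASSES)
}

#' Estimate the side-chain environment propensity table
#'
#' The six-class environment needs structure (RSA and polar fraction), which
#' is unknown at prediction time. The table therefore stores, per amino-acid
#' type, the relative frequency of the six classes among labelled training
#' residues (add-one smoothing, rows sum to 1); at encoding time each
#' residue receives its type's 6-vector, making the feature sequence-only.
#'
#' @param records List of `protein_record`s with `rsa` and `polar` tracks.
#' @return 20 x 6 matrix (rows = amino acids, columns = classes).
#' @export
sce_propensity <- function(records) {
  counts <- matrix(0, length(AA20), length(SCE_CLASSES),
                   dimnames = list(AA20, SCE_CLASSES))
  for (rec in records) {
    if (is.null(rec$rsa) || is.null(rec$polar)) {
      stop("protein ", rec$id,
           " lacks the rsa/polar tracks needed for propensity estimation")
    }
    ok <- !is.na(rec$rsa) & !is.na(rec$polar) & rec$sequence %in% AA20
    if (!any(ok)) next
    cls <- side_chain_class(rec$rsa[ok], rec$polar[ok])
    tab <- table(factor(rec$sequence[ok], levels = AA20), cls)
    counts <- counts + as.matrix(tab)
  }
  prop <- counts + 1 # add-one smoothing
  prop <- prop / rowSums(prop)
  matrix(as.numeric(prop), nrow(prop), ncol(prop),
         dimnames = dimnames(counts))
}

sce_rows <- function(sequence, propensity) {
  out <- matrix(1 / 6, length(sequence), length(SCE_CLASSES))
  known <- sequence %in% rownames(propensity)
  out[known, ] <- propensity[sequence[known], , drop = FALSE]
  colnames(out) <- SCE_CLASSES
  out
}

# Slides an n x k per-residue track into an n x (k * L) window matrix;
# positions beyond the termini are filled with the family's neutral pad.
window_track <- function(M, half_width, pad) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M); l <- half_width
  out <- matrix(NA_real_, n, k * (2L * l + 1L))
  for (w in -l:l) {
    src <- seq_len(n) + w
    ok <- src >= 1L & src <= n
    block <- matrix(pad, n, k, byrow = TRUE)
    block[ok, ] <- M[src[ok], , drop = FALSE]
    out[, ((w + l) * k + 1L):((w + l + 1L) * k)] <- block
  }
  out
}

window_labels <- function(family, half_width, channels) {
  unlist(lapply(-half_width:half_width, function(w) {
    paste0(family, ".", w, ".", channels)
  }))
}

#' Encode one protein into per-residue feature vectors
#'
#' Builds the design-matrix rows of a protein: for each residue, the
#' logistic-normalised PSSM window (20L columns), the secondary-structure
#' window (3L), the disorder window (2L), the six side-chain-environment
#' propensities and the conservation window (L), for the enabled families.
#' Window slots beyond the termini carry neutral pads: 0.5 for normalised
#' PSSM, 1/3 for SS, 0.5 for disorder and 0.5 for conservation.
#'
#' @param record A [protein_record()] with the tracks of the enabled
#'   families.
#' @param half_width Window half width `l`; window length `L = 2l + 1`.
#' @param families Feature families to include.
#' @param propensity Side-chain environment table from [sce_propensity()]
#'   (required when `SCE` is enabled).
#' @param cs_bounds Conservation bounds from [conservation_bounds()]
#'   (default: the record's own information range).
#' @return Numeric matrix, one row per residue, with `colnames` giving
#'   family, window offset and channel of every column.
#' @export
encode_protein <- function(record, half_width = 3L,
                           families = FEATURE_FAMILIES, propensity = NULL,
                           cs_bounds = NULL) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  l <- as.integer(half_width)
  if (l < 0L) stop("'half_width' must be >= 0")
  blocks <- list(); labels <- character(0)
  need <- function(track, what) {
    if (is.null(track)) {
      stop("protein ", record$id, " is missing the ", what,
           " track required by the enabled feature families")
    }
    track
  }
  if ("PSSM" %in% families) {
    p <- logistic_normalize(need(record$pssm, "PSSM"))
    blocks$PSSM <- window_track(p, l, rep(0.5, 20L))
    labels <- c(labels, window_labels("PSSM", l, AA20))
  }
  if ("SS" %in% families) {
    blocks$SS <- window_track(need(record$ss, "SS"), l, rep(1 / 3, 3L))
    labels <- c(labels, window_labels("SS", l, c("C", "H", "E")))
  }
  if ("DISO" %in% families) {
    blocks$DISO <- window_track(need(record$diso, "disorder"), l,
                                rep(0.5, 2L))
    labels <- c(labels, window_labels("DISO", l, c("diso", "ord")))
  }
  if ("SCE" %in% families) {
    if (is.null(propensity)) {
      stop("SCE family enabled but no propensity table supplied")
    }
    blocks$SCE <- sce_rows(record$sequence, propensity)
    labels <- c(labels, paste0("SCE.", SCE_CLASSES))
  }
  if ("CS" %in% families) {
    info <- need(record$info, "information (conservation)")
    if (is.null(cs_bounds)) cs_bounds <- conservation_bounds(info)
    cs <- conservation_track(info, cs_bounds)
    blocks$CS <- window_track(matrix(cs, ncol = 1L), l, 0.5)
    labels <- c(labels, paste0("CS.", -l:l))
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- labels
  X
}

#' Encode a set of proteins into one flat dataset
#'
#' Stacks [encode_protein()] rows over a list of records, keeping the RSA
#' targets (where present), the protein id of every row (for protein-level
#' cross-validation splitting) and the residue letters.
#'
#' @inheritParams encode_protein
#' @param records List of `protein_record`s.
#' @return An `encoded_dataset`: list with `X`, `y` (`NA` where unlabelled),
#'   `groups`, `residues`, `column_labels`, `half_width`, `families`.
#' @export
encode_dataset <- function(records, half_width = 3L,
                           families = FEATURE_FAMILIES, propensity = NULL,
                           cs_bounds = NULL) {
  if (length(records) == 0L) stop("empty record list")
  Xs <- lapply(records, encode_protein, half_width = half_width,
               families = families, propensity = propensity,
               cs_bounds = cs_bounds)
  X <- do.call(rbind, Xs)
  if (anyNA(X)) stop("NaN/NA produced during encoding")
  y <- unlist(lapply(records, function(r) {
    if (is.null(r$rsa)) rep(NA_real_, length(r$sequence)) else r$rsa
  }))
  structure(list(X = X, y = y,
                 groups = rep(vapply(records, `[[`, "", "id"),
                              vapply(records, function(r) length(r$sequence),
                                     integer(1))),
                 residues = unlist(lapply(records, `[[`, "sequence")),
                 column_labels = colnames(X),
                 half_width = as.integer(half_width), families = families),
            class = "encoded_dataset")
}

#' Write an encoded dataset as TSV
#'
#' @param dataset An `encoded_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoded_tsv <- function(dataset, path) {
  df <- data.frame(id = dataset$groups, residue = dataset$residues,
                   rsa = dataset$y, check.names = FALSE)
  df <- cbind(df, as.data.frame(dataset$X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
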