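#' Maximum solvent accessibility table
#'
#' Per-residue-type maximum accessible surface area (\eqn{\AA^2}) in an
#' extended Gly-X-Gly tripeptide, used to normalise DSSP absolute
#' accessibilities into relative solvent accessibility. Published tables
#' differ by a few \eqn{\AA^2}; a higher maximum lowers every RSA value and
#' with it the apparent error, so the table identity is recorded on the
#' returned object (and propagated into model bundles) and a custom table
#' can be supplied wherever one is accepted.
#'
#' The shipped default is the Miller et al. (1987) Gly-X-Gly table.
#'
#' @param name Table name; currently `"miller1987"`.
#' @return Named numeric vector (one-letter residue codes), with attribute
#'   `table_name`.
#' @examples
#' max_asa_table()[["G"]]
#' @export
max_asa_table <- function(name = "miller1987") {
  tables <- list(
    miller1987 = c(A = 113, R = 241, N = 158, D = 151, C = 140,
                   Q = 189, E = 183, G = 85,  H = 194, I = 182,
                   L = 180, K = 211, M = 204, F = 218, P = 143,
                   S = 122, T = 146, W = 259, Y = 229, V = 160))
  if (!name %in% names(tables)) {
    stop("unknown max-ASA table: ", name, " (available: ",
         paste(names(tables), collapse = ", "), ")")
  }
  structure(tables[[name]], table_name = name)
}

#' Convert absolute to relative solvent accessibility
#'
#' RSA = ASA divided by the residue type's maximum accessibility, clamped to
#' `[0, 1]` (real structures occasionally exceed the tripeptide maximum).
#'
#' @param asa Numeric vector of DSSP accessibilities (\eqn{\AA^2}, >= 0).
#' @param residue Character vector of one-letter residue codes (recycled
#'   rules: same length as `asa`).
#' @param table A [max_asa_table()].
#' @param permissive If `TRUE`, residues missing from the table yield `NA`
#'   with a warning instead of an error.
#' @return Numeric vector of RSA fractions in `[0, 1]`.
#' @examples
#' asa_to_rsa(c(50, 120), c("A", "A"))
#' @export
asa_to_rsa <- function(asa, residue, table = max_asa_table(),
                       permissive = FALSE) {
  stopifnot(length(asa) == length(residue))
  if (any(asa < 0, na.rm = TRUE)) stop("negative ASA value")
  mx <- unname(table[residue])
  if (anyNA(mx)) {
    bad <- unique(residue[is.na(mx)])
    if (!permissive) {
      stop("residue type(s) not in max-ASA table: ",
           paste(bad, collapse = ", "))
    }
    warning("skipping residue type(s) not in max-ASA table: ",
            paste(bad, collapse = ", "))
  }
  pmin(pmax(asa / mx, 0), 1)
}

#' Two-state burial call
#'
#' A residue is buried when its RSA is strictly below the threshold
#' (given in percent), exposed otherwise.
#'
#' @param rsa Numeric vector of RSA fractions in `[0, 1]`.
#' @param threshold Burial threshold in percent, in `(0, 100)`.
#' @return Factor with levels `buried`, `exposed`.
#' @examples
#' two_state(c(0.04, 0.05), threshold = 5)
#' @export
two_state <- function(rsa, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 100) {
    stop("'threshold' must be a percentage in (0, 100)")
  }
  factor(ifelse(rsa < threshold / 100, "buried", "exposed"),
         levels = c("buried", "exposed"))
}

#' Read per-residue accessibility from a DSSP file
#'
#' Parses the classic fixed-column DSSP text format: data rows follow the
#' `  #  RESIDUE ...` header, the chain id is at column 12, the one-letter
#' residue code at column 14 and the ACC field at columns 35-38. Chain-break
#' rows (`!` residue code) are skipped; lowercase residue codes (DSSP's
#' convention for half-cystines) are mapped to `C`.
#'
#' @param path Path to a DSSP file.
#' @return `data.frame` with columns `chain`, `residue`, `acc`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("malformed DSSP file (no '  #  RESIDUE' header): ", path)
  }
  out <- list(chain = character(0), residue = character(0), acc = numeric(0))
  for (i in seq(hdr[1] + 1L, length.out = length(lines) - hdr[1])) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 38L) {
      stop("DSSP data line too short at line ", i, " of ", path)
    }
    aa <- substr(ln, 14, 14)
    if (aa == "!") next
    if (aa >= "a" && aa <= "z") aa <- "C"
    acc <- suppressWarnings(as.numeric(substr(ln, 35, 38)))
    if (is.na(acc)) stop("unreadable ACC field at line ", i, " of ", path)
    out$chain <- c(out$chain, substr(ln, 12, 12))
    out$residue <- c(out$residue, aa)
    out$acc <- c(out$acc, acc)
  }
  data.frame(chain = out$chain, residue = out$residue, acc = out$acc)
}

#' RSA label track from a DSSP file
#'
#' Convenience wrapper: [read_dssp()] then [asa_to_rsa()], returning one
#' labelled row per residue together with the max-ASA value used. The table
#' identity is attached as attribute `table_name`.
#'
#' @inheritParams read_dssp
#' @inheritParams asa_to_rsa
#' @return `data.frame` with columns `index`, `residue`, `asa`, `max_asa`,
#'   `rsa`.
#' @export
rsa_from_dssp <- function(path, table = max_asa_table(), permissive = FALSE) {
  d <- read_dssp(path)
  rsa <- asa_to_rsa(d$acc, d$residue, table, permissive = permissive)
  structure(data.frame(index = seq_len(nrow(d)), residue = d$residue,
                       asa = d$acc, max_asa = unname(table[d$residue]),
                       rsa = rsa),
            table_name = attr(table, "table_name"))
}
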