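#' Scoring scheme for frameshift-aware CDS alignment
#'
#' Collects every parameter of the alignment scoring model: an amino-acid
#' substitution matrix (BLOSUM62 by default), nucleotide match/mismatch
#' scores, penalties for frameshift initiation and extension, codon gap
#' penalties (linear or affine), and the score given to codon pairs in which
#' exactly one side translates to a stop.
#'
#' All penalties must be non-positive; \code{fs_extend_cost = 0} is the
#' variant that does not penalize frameshift extension length.  The
#' amino-acid and nucleotide scoring functions must be symmetric.
#'
#' @param s_aa symmetric amino-acid substitution matrix with single-letter
#'   row/column names; a \code{*} row/column, if present, is overridden by
#'   \code{stop_cost}/\code{stop_match} below.  Default: BLOSUM62 (from
#'   Biostrings).
#' @param s_an_match,s_an_mismatch nucleotide match / mismatch scores
#'   (defaults +1 / -1).
#' @param fs_open_cost penalty per frameshift-initiation codon (default -30).
#' @param fs_extend_cost penalty per frameshift-extension codon (default -1).
#' @param gap_cost penalty per inserted/deleted codon (default -1).
#' @param gap_open_cost penalty per codon-gap run, affine mode only
#'   (default -11).
#' @param stop_cost score for an amino-acid pairing in which exactly one side
#'   is a stop (default -100).
#' @param stop_match score for a stop/stop pairing (default +1).
#' @param gap_mode \code{"affine"} (default) or \code{"linear"} codon gap
#'   penalties.
#' @return An object of class \code{"scoring_scheme"} with precomputed
#'   codon-level lookup tables.
#' @examples
#' sc <- scoring_scheme(gap_mode = "linear")
#' aa_score(sc, "ATG", "ATG")  # 5, the BLOSUM62 M/M score
#' @export
scoring_scheme <- function(s_aa = NULL,
                           s_an_match = 1, s_an_mismatch = -1,
                           fs_open_cost = -30, fs_extend_cost = -1,
                           gap_cost = -1, gap_open_cost = -11,
                           stop_cost = -100, stop_match = 1,
                           gap_mode = c("affine", "linear")) {
  gap_mode <- match.arg(gap_mode)
  if (is.null(s_aa)) s_aa <- blosum62()
  stopifnot(is.matrix(s_aa), !is.null(rownames(s_aa)),
            identical(rownames(s_aa), colnames(s_aa)))
  if (!isTRUE(all.equal(s_aa, t(s_aa))))
    stop("amino-acid substitution matrix must be symmetric")
  for (p in c(fs_open_cost, fs_extend_cost, gap_cost, gap_open_cost))
    if (!is.finite(p) || p > 0) stop("penalty costs must be <= 0")

  aas <- sort(unique(unname(.codon_table)))      # 20 AAs + '*'
  missing_aa <- setdiff(setdiff(aas, "*"), rownames(s_aa))
  if (length(missing_aa))
    stop("substitution matrix lacks amino acid(s): ",
         paste(missing_aa, collapse = ", "))
  saa <- matrix(0, length(aas), length(aas), dimnames = list(aas, aas))
  plain <- setdiff(aas, "*")
  saa[plain, plain] <- s_aa[plain, plain]
  saa["*", ] <- stop_cost
  saa[, "*"] <- stop_cost
  saa["*", "*"] <- stop_match

  san <- matrix(s_an_mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(san) <- s_an_match

  structure(list(
    s_aa = saa, s_an = san,
    s_an_match = s_an_match, s_an_mismatch = s_an_mismatch,
    fs_open_cost = fs_open_cost, fs_extend_cost = fs_extend_cost,
    gap_cost = gap_cost, gap_open_cost = gap_open_cost,
    stop_cost = stop_cost, stop_match = stop_match,
    gap_mode = gap_mode), class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Frameshift-aware CDS alignment scoring scheme\n")
  cat(sprintf("  s_an (match/mismatch): %+g / %+g\n",
              x$s_an_match, x$s_an_mismatch))
  cat(sprintf("  fs_open_cost: %g   fs_extend_cost: %g\n",
              x$fs_open_cost, x$fs_extend_cost))
  cat(sprintf("  gap_cost: %g   gap_open_cost: %g   gap mode: %s\n",
              x$gap_cost, x$gap_open_cost, x$gap_mode))
  cat(sprintf("  stop pairing: %g (mixed), %g (stop/stop)\n",
              x$stop_cost, x$stop_match))
  invisible(x)
}

#' BLOSUM62 substitution matrix
#'
#' The BLOSUM62 matrix shipped with Biostrings, restricted to the 20 standard
#' amino acids plus the stop symbol.
#' @return A symmetric integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V", "*")
  e$BLOSUM62[keep, keep]
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text scoring matrix format used to distribute BLOSUM and
#' PAM matrices: \code{#} comment lines, a header row of residue letters, and
#' one labelled row of integers per residue.  A \code{*} column, if present,
#' is kept.
#'
#' @param path file path.
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a scoring matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(rows, `[`, "", 1L)
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(m) <- list(labs, header)
  if (!isTRUE(all.equal(m, t(m)))) stop("matrix in ", path, " is not symmetric")
  m
}

#' Amino-acid score of two codons
#'
#' Scores a pair of gap-free codons through their translations, so synonymous
#' codons score identically to identical codons.  Pairings in which exactly
#' one codon is a stop take \code{stop_cost}; stop/stop takes
#' \code{stop_match}.
#'
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param codon_a,codon_b length-3 nucleotide strings.
#' @return A numeric score.
#' @export
aa_score <- function(scheme, codon_a, codon_b) {
  stopifnot(nchar(codon_a) == 3L, nchar(codon_b) == 3L)
  a <- .codon_table[[toupper(codon_a)]]
  b <- .codon_table[[toupper(codon_b)]]
  scheme$s_aa[a, b]
}

#' Nucleotide score of two bases
#'
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param x,y single nucleotides in \code{A,C,G,T}; gaps are never scored.
#' @return \code{s_an_match} if equal, else \code{s_an_mismatch}.
#' @export
an_score <- function(scheme, x, y) {
  x <- toupper(x); y <- toupper(y)
  if (!x %in% rownames(scheme$s_an) || !y %in% rownames(scheme$s_an))
    stop("an_score is defined on nucleotides only, got '", x, "', '", y, "'")
  scheme$s_an[x, y]
}
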