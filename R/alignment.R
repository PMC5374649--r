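#' Construct a pairwise CDS alignment
#'
#' Two equal-length gapped rows over \code{A,C,G,T,-}, 1-based columns.  No
#' column may hold a gap in both rows, and each row must degap to a valid CDS
#' (length a multiple of 3).
#'
#' @param a_gapped,b_gapped gapped row strings.
#' @param ids character(2) sequence labels.
#' @param check_cds require degapped rows to be valid CDS (default TRUE;
#'   disabled internally when enumerating alignments of arbitrary DNA).
#' @return An object of class \code{"alignment_pair"} with elements
#'   \code{a_gapped}, \code{b_gapped}, \code{L}, \code{ids}.
#' @examples
#' alignment_pair("ATG---", "---ATG")
#' @export
alignment_pair <- function(a_gapped, b_gapped, ids = c("A", "B"),
                           check_cds = TRUE) {
  a_gapped <- toupper(a_gapped); b_gapped <- toupper(b_gapped)
  L <- nchar(a_gapped)
  if (nchar(b_gapped) != L)
    stop("alignment rows have different lengths (", L, " vs ",
         nchar(b_gapped), ")")
  if (grepl("[^ACGT-]", a_gapped) || grepl("[^ACGT-]", b_gapped))
    stop("alignment rows may contain only A, C, G, T and '-'")
  ca <- strsplit(a_gapped, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b_gapped, "", fixed = TRUE)[[1L]]
  if (any(ca == "-" & cb == "-"))
    stop("alignment has a column with gaps in both rows")
  if (check_cds)
    for (s in c(a = sum(ca != "-"), b = sum(cb != "-")))
      if (s %% 3L != 0L)
        stop("degapped row length ", s, " is not a multiple of 3")
  structure(list(a_gapped = a_gapped, b_gapped = b_gapped, L = L, ids = ids),
            class = "alignment_pair")
}

#' @export
print.alignment_pair <- function(x, width = 60L, ...) {
  cat(sprintf("CDS alignment (%s / %s), %d columns\n",
              x$ids[1L], x$ids[2L], x$L))
  for (s in seq(1L, max(x$L, 1L), by = width)) {
    e <- min(s + width - 1L, x$L)
    cat(" ", substr(x$a_gapped, s, e), "\n ", substr(x$b_gapped, s, e), "\n")
  }
  invisible(x)
}

#' Count non-gap letters in a span of a gapped row
#'
#' @param row gapped row string.
#' @param k,l 1-based inclusive column bounds, \code{1 <= k <= l <= nchar(row)}.
#' @return Number of non-gap symbols in columns \code{k..l}.
#' @examples
#' nongap_count("ACCAT--GTAG", 4, 8)  # 3
#' @export
nongap_count <- function(row, k, l) {
  L <- nchar(row)
  if (!(k >= 1L && k <= l && l <= L))
    stop("column span out of range: k=", k, ", l=", l, ", L=", L)
  nchar(gsub("-", "", substr(row, k, l), fixed = TRUE))
}

# classification of one direction: codons of the row `pos` (columns of its
# nucleotides, in order) against the other row's non-gap mask
.classify_dir <- function(pos, other_nongap) {
  nc <- length(pos) %/% 3L
  out <- list(im = integer(0), fsext = integer(0), indel = integer(0),
              fsinit = integer(0), mfs = integer(0))
  if (nc == 0L) return(out)
  cum0 <- c(0L, cumsum(other_nongap))   # cum0[k + 1] = nts in columns 1..k
  endi <- 3L * seq_len(nc)
  end_col <- pos[endi]
  start_col <- pos[endi - 2L]
  grouped <- (end_col - start_col) == 2L
  nt_facing <- cum0[end_col + 1L] - cum0[start_col]
  im    <- grouped & nt_facing == 3L & cum0[end_col + 1L] %% 3L == 0L
  fsext <- grouped & nt_facing == 3L & cum0[end_col + 1L] %% 3L != 0L
  indel <- grouped & nt_facing == 0L
  fsinit <- !(im | fsext | indel)
  out$im     <- end_col[im]
  out$fsext  <- end_col[fsext]
  out$indel  <- end_col[indel]
  out$fsinit <- end_col[fsinit]
  if (any(fsinit)) {
    cols <- pos[rep(endi[fsinit], each = 3L) - c(2L, 1L, 0L)]
    out$mfs <- sort(cols[other_nongap[cols]])
  }
  out
}

#' Partition aligned codons into IM / FSext / InDel / FSinit classes
#'
#' For each sequence, every codon is assigned exactly one class, identified by
#' the alignment column of its last nucleotide: \emph{IM} (in-frame match) if
#' the codon is grouped (3 consecutive columns) and faces a grouped codon of
#' the other sequence; \emph{FSext} (frameshift extension) if grouped and
#' facing three nucleotides that straddle a codon boundary of the other
#' sequence; \emph{InDel} if grouped and facing three gaps; \emph{FSinit}
#' (frameshift initiation) otherwise.  \emph{MFS} columns are the nucleotides
#' of FSinit codons that face a nucleotide.
#'
#' @param aln an \code{\link{alignment_pair}}.
#' @return An object of class \code{"codon_classification"}: a list with
#'   components \code{a} and \code{b}, each holding integer column sets
#'   \code{im}, \code{fsext}, \code{indel}, \code{fsinit}, \code{mfs}.
#' @export
classify_codons <- function(aln) {
  ca <- strsplit(aln$a_gapped, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$b_gapped, "", fixed = TRUE)[[1L]]
  na_ <- ca != "-"; nb_ <- cb != "-"
  structure(list(a = .classify_dir(which(na_), nb_),
                 b = .classify_dir(which(nb_), na_),
                 chars_a = ca, chars_b = cb),
            class = "codon_classification")
}

#' @export
print.codon_classification <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  cat("Codon classification (columns of codon-end / MFS nucleotides)\n")
  for (d in c("a", "b")) {
    s <- x[[d]]
    cat(sprintf("  %s: IM {%s}  FSext {%s}  InDel {%s}  FSinit {%s}  MFS {%s}\n",
                toupper(d), fmt(s$im), fmt(s$fsext), fmt(s$indel),
                fmt(s$fsinit), fmt(s$mfs)))
  }
  invisible(x)
}

# amino acid of the 3 characters at columns e-2..e of a character row
.aa_at <- function(chars, e) .codon_table[[paste(chars[(e - 2L):e], collapse = "")]]

# gap_open charges: number of maximal column-contiguous runs of InDel codons
.indel_runs <- function(ends) {
  if (!length(ends)) return(0L)
  ends <- sort(ends)
  1L + sum(diff(ends) != 3L)
}

#' Score a given alignment under the frameshift-aware model
#'
#' Direct evaluation of the scoring definition on an explicit alignment,
#' independent of the dynamic program: full amino-acid score per IM codon
#' pair; half amino-acid score plus \code{fs_extend_cost} per FSext codon (per
#' direction); \code{gap_cost} per InDel codon (plus, in affine mode, one
#' \code{gap_open_cost} per maximal column-contiguous run of InDel codons of
#' the same sequence); \code{fs_open_cost} per FSinit codon; and half the
#' nucleotide score per MFS nucleotide, per direction.
#'
#' @param aln an \code{\link{alignment_pair}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param cls optional precomputed \code{\link{classify_codons}} result.
#' @return The numeric alignment score (half-integer scores are exact).
#' @export
score_alignment <- function(aln, scheme, cls = NULL) {
  if (is.null(cls)) cls <- classify_codons(aln)
  ca <- cls$chars_a; cb <- cls$chars_b
  saa <- scheme$s_aa; san <- scheme$s_an
  total <- 0
  for (d in c("a", "b")) {
    s <- cls[[d]]
    self <- if (d == "a") ca else cb
    other <- if (d == "a") cb else ca
    if (d == "a")  # IM pairs are shared; charge the full AA score once
      for (e in s$im)
        total <- total + saa[.aa_at(ca, e), .aa_at(cb, e)]
    for (e in s$fsext)
      total <- total + saa[.aa_at(self, e), .aa_at(other, e)] / 2 +
        scheme$fs_extend_cost
    total <- total + length(s$indel) * scheme$gap_cost
    if (scheme$gap_mode == "affine")
      total <- total + .indel_runs(s$indel) * scheme$gap_open_cost
    total <- total + length(s$fsinit) * scheme$fs_open_cost
    if (length(s$mfs))
      total <- total + sum(san[cbind(self[s$mfs], other[s$mfs])]) / 2
  }
  total
}
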