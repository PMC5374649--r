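#' Frameshift-segment column ranges of an alignment
#'
#' A frameshift translation segment is a maximal run of alignment columns
#' intersecting at least one FSext codon of either sequence.  The number of
#' segments is the FS_init criterion; the total number of covered columns is
#' FS_length.
#'
#' @param cls a \code{\link{classify_codons}} result.
#' @param L alignment length in columns.
#' @return Integer matrix with columns \code{start}, \code{end}, one row per
#'   segment.
#' @export
fs_segments <- function(cls, L) {
  covered <- logical(L)
  for (d in c("a", "b"))
    for (e in cls[[d]]$fsext) covered[(e - 2L):e] <- TRUE
  if (!any(covered)) return(matrix(integer(0), 0L, 2L,
                                   dimnames = list(NULL, c("start", "end"))))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# column types for the gap-initiation criterion: 0 gap-free, 1 gap in A,
# 2 gap in B; a gap-containing column opens a run when the previous column
# has a different type (column 1 always opens)
.gap_inits <- function(ca, cb) {
  type <- ifelse(ca == "-", 1L, ifelse(cb == "-", 2L, 0L))
  gapped <- type != 0L
  prev <- c(-1L, type[-length(type)])
  which(gapped & type != prev)
}

#' Six composition criteria of a CDS pairwise alignment
#'
#' Computes, independently of any scoring scheme:
#' \describe{
#'   \item{identity_nt}{gap-free columns containing a nucleotide match;}
#'   \item{identity_aa}{IM and FSext codons (of both sequences) aligned with
#'     a nucleotide triplet yielding the same amino acid;}
#'   \item{gap_init}{gap-containing columns whose preceding column is of a
#'     different type (insertion vs deletion vs gap-free);}
#'   \item{gap_length}{gap-containing columns;}
#'   \item{fs_init}{frameshift translation segments (see
#'     \code{\link{fs_segments}});}
#'   \item{fs_length}{columns intersecting an FSext codon.}
#' }
#'
#' @param aln an \code{\link{alignment_pair}}.
#' @param cls optional precomputed \code{\link{classify_codons}} result.
#' @return An object of class \code{"criteria_report"} (a named list of the
#'   six counts plus \code{gap_init_columns} and \code{fs_segment_starts}).
#' @export
compute_criteria <- function(aln, cls = NULL) {
  if (is.null(cls)) cls <- classify_codons(aln)
  ca <- cls$chars_a; cb <- cls$chars_b
  gapped <- ca == "-" | cb == "-"
  identity_nt <- sum(!gapped & ca == cb)
  identity_aa <- 0L
  for (d in c("a", "b")) {
    self <- if (d == "a") ca else cb
    other <- if (d == "a") cb else ca
    for (e in c(cls[[d]]$im, cls[[d]]$fsext))
      if (.aa_at(self, e) == .aa_at(other, e))
        identity_aa <- identity_aa + 1L
  }
  inits <- .gap_inits(ca, cb)
  seg <- fs_segments(cls, aln$L)
  structure(list(
    identity_nt = identity_nt,
    identity_aa = identity_aa,
    gap_init = length(inits),
    gap_length = sum(gapped),
    fs_init = nrow(seg),
    fs_length = if (nrow(seg)) sum(seg[, "end"] - seg[, "start"] + 1L) else 0L,
    gap_init_columns = inits,
    fs_segment_starts = unname(seg[, "start"])),
    class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf(paste0("Identity_NT %d  Identity_AA %d  Gap_init %d  ",
                     "Gap_length %d  FS_init %d  FS_length %d\n"),
              x$identity_nt, x$identity_aa, x$gap_init,
              x$gap_length, x$fs_init, x$fs_length))
  invisible(x)
}

#' Length-normalized similarity score
#'
#' @param score raw alignment score.
#' @param L alignment length in columns (> 0).
#' @return \code{score / L}.
#' @export
normalized_score <- function(score, L) {
  if (L <= 0) stop("alignment length must be positive")
  score / L
}
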