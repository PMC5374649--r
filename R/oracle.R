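# Brute-force reference for the aligner: enumerate the complete space of
# pairwise alignments (every monotone interleaving with no all-gap column)
# and maximize the directly evaluated alignment score.  Shares no code with
# the dynamic program; used to certify it on small inputs.

#' Delannoy number
#'
#' Number of distinct pairwise alignments of sequences of lengths n and m:
#' d(i,j) = d(i-1,j) + d(i,j-1) + d(i-1,j-1), d(i,0) = d(0,j) = 1.
#'
#' @param n,m non-negative integers.
#' @return A numeric count.
#' @export
delannoy <- function(n, m) {
  d <- matrix(1, n + 1L, m + 1L)
  if (n >= 1L && m >= 1L)
    for (i in 2:(n + 1L)) for (j in 2:(m + 1L))
      d[i, j] <- d[i - 1L, j] + d[i, j - 1L] + d[i - 1L, j - 1L]
  d[n + 1L, m + 1L]
}

#' Enumerate all alignments of two sequences
#'
#' Generates every alignment of the two degapped sequences exactly once, in
#' lexicographic order of the per-column moves (align-pair, then consume A
#' against a gap, then consume B against a gap).  Refuses inputs whose
#' Delannoy count exceeds the budget.  Arbitrary DNA lengths are accepted
#' (the alignment space is defined for any DNA sequences); scoring the
#' enumerated alignments additionally requires both inputs to be CDS.
#'
#' @param a,b \code{\link{cds}} objects or nucleotide strings.
#' @param max_alignments enumeration cap (default 2e5).
#' @return A list of \code{\link{alignment_pair}} objects.
#' @export
enumerate_alignments <- function(a, b, max_alignments = 2e5) {
  a <- .as_seq(a, "A"); b <- .as_seq(b, "B")
  n <- a$n; m <- b$n
  cds_ok <- n %% 3L == 0L && m %% 3L == 0L
  cnt <- delannoy(n, m)
  if (cnt > max_alignments)
    stop(sprintf("alignment space too large: Delannoy(%d,%d) = %.0f > %g",
                 n, m, cnt, max_alignments))
  ach <- strsplit(a$nucleotides, "")[[1L]]
  bch <- strsplit(b$nucleotides, "")[[1L]]
  out <- vector("list", cnt)
  k <- 0L
  arow <- character(n + m); brow <- character(n + m)
  rec <- function(i, j, len) {
    if (i == n && j == m) {
      k <<- k + 1L
      out[[k]] <<- alignment_pair(
        paste(arow[seq_len(len)], collapse = ""),
        paste(brow[seq_len(len)], collapse = ""),
        ids = c(a$id, b$id), check_cds = cds_ok)
      return(invisible(NULL))
    }
    if (i < n && j < m) {
      arow[len + 1L] <<- ach[i + 1L]; brow[len + 1L] <<- bch[j + 1L]
      rec(i + 1L, j + 1L, len + 1L)
    }
    if (i < n) {
      arow[len + 1L] <<- ach[i + 1L]; brow[len + 1L] <<- "-"
      rec(i + 1L, j, len + 1L)
    }
    if (j < m) {
      arow[len + 1L] <<- "-"; brow[len + 1L] <<- bch[j + 1L]
      rec(i, j + 1L, len + 1L)
    }
    invisible(NULL)
  }
  if (n + m == 0L) return(list(alignment_pair("", "", ids = c(a$id, b$id))))
  rec(0L, 0L, 0L)
  out
}

#' Exhaustive-maximization alignment oracle
#'
#' Scores every enumerated alignment with the direct scorer
#' (\code{\link{score_alignment}}) and returns the maximum; the argmax is the
#' first encountered in enumeration order, so the result is deterministic.
#'
#' @param a,b \code{\link{cds}} objects or nucleotide strings (lengths
#'   multiples of 3).
#' @param scheme a \code{\link{scoring_scheme}} (or a list of schemes, in
#'   which case the per-scheme maxima are returned as a numeric vector and
#'   the alignments as a list).
#' @param max_alignments enumeration cap.
#' @return A list with \code{score} and \code{alignment} (for one scheme), or
#'   \code{scores} and \code{alignments} (for several).
#' @export
brute_force_best <- function(a, b, scheme, max_alignments = 2e5) {
  alns <- enumerate_alignments(a, b, max_alignments)
  single <- inherits(scheme, "scoring_scheme")
  schemes <- if (single) list(scheme) else scheme
  best <- rep(-Inf, length(schemes))
  arg <- vector("list", length(schemes))
  for (al in alns) {
    cls <- classify_codons(al)
    for (s in seq_along(schemes)) {
      sc <- score_alignment(al, schemes[[s]], cls)
      if (sc > best[s]) { best[s] <- sc; arg[[s]] <- al }
    }
  }
  if (single) list(score = best[1L], alignment = arg[[1L]])
  else list(scores = best, alignments = arg)
}
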