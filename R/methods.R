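#' @export
print.cds_align <- function(x, ...) {
  cat(sprintf("Frameshift-aware CDS alignment (%s / %s)\n",
              x$alignment$ids[1L], x$alignment$ids[2L]))
  cat(sprintf("  score: %g   normalized: %s   columns: %d\n",
              x$score,
              if (is.na(x$normalized)) "NA" else sprintf("%.4f", x$normalized),
              x$alignment$L))
  invisible(x)
}

#' Summary of a CDS alignment fit
#'
#' Prints the score, the codon-class composition of both sequences and the
#' six composition criteria.
#'
#' @param object a \code{\link{cds_align}} result.
#' @param ... unused.
#' @export
summary.cds_align <- function(object, ...) {
  print(object)
  cls <- object$classification
  for (d in c("a", "b")) {
    s <- cls[[d]]
    cat(sprintf("  %s codons: %d IM, %d FSext, %d InDel, %d FSinit (%d MFS nt)\n",
                object$alignment$ids[if (d == "a") 1L else 2L],
                length(s$im), length(s$fsext), length(s$indel),
                length(s$fsinit), length(s$mfs)))
  }
  cat("  criteria: "); print(object$criteria)
  print(object$alignment)
  invisible(object)
}

#' Plot the codon-class composition of an alignment
#'
#' Draws each row of the alignment as a horizontal band over the alignment
#' columns, colored by codon class (IM, FSext, InDel, FSinit) with gaps left
#' blank, and marks frameshift segments underneath.
#'
#' @param x a \code{\link{cds_align}} result (or a list with
#'   \code{alignment} and \code{classification}, e.g. the reference fixture).
#' @param ... passed to \code{plot.default}.
#' @export
plot.cds_align <- function(x, ...) {
  aln <- x$alignment; cls <- x$classification
  L <- aln$L
  cols <- c(IM = "#4477AA", FSext = "#CC4444", InDel = "#44AA77",
            FSinit = "#333333")
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, 3),
                 xlab = "alignment column", ylab = "", yaxt = "n",
                 bty = "n", ...)
  graphics::axis(2, at = c(2.25, 1.25), labels = aln$ids, las = 1,
                 tick = FALSE)
  y0 <- c(a = 2, b = 1)
  for (d in c("a", "b")) {
    s <- cls[[d]]
    for (cl in c("im", "fsext", "indel", "fsinit")) {
      nm <- c(im = "IM", fsext = "FSext", indel = "InDel",
              fsinit = "FSinit")[[cl]]
      for (e in s[[cl]]) {
        span <- if (cl == "fsinit") {
          pos <- which((if (d == "a") cls$chars_a else cls$chars_b) != "-")
          k <- which(pos == e)
          range(pos[(k - 2L):k])
        } else c(e - 2L, e)
        graphics::rect(span[1L] - 0.5, y0[[d]], span[2L] + 0.5,
                       y0[[d]] + 0.5, col = cols[[nm]], border = "white")
      }
    }
  }
  seg <- fs_segments(cls, L)
  if (nrow(seg))
    graphics::segments(seg[, "start"] - 0.5, 0.5, seg[, "end"] + 0.5, 0.5,
                       lwd = 3, col = cols[["FSext"]])
  graphics::legend("top", horiz = TRUE, bty = "n", fill = cols,
                   legend = names(cols), border = NA)
  invisible(x)
}
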