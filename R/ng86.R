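# NG86 pairwise dN/dS: synonymous/nonsynonymous site counting with
# stop-excluded site fractions, multi-difference codons resolved by averaging
# over minimal substitution paths, and Jukes-Cantor correction.

#' NG86 pairwise dN/dS
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence (averaged
#' over the pair, so `N + S = 3 * nCodons`), counts synonymous and
#' nonsynonymous differences (multi-difference codons averaged over all
#' minimal substitution paths avoiding stop codons) and applies the
#' Jukes-Cantor correction to the proportions.
#'
#' @param seq1,seq2 equal-length in-frame coding sequences (character), or a
#'   [CodonAlignment-class] plus two taxon names/indices.
#' @return a list of class `Ng86Result` with `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS`, `omega` (NA with `omegaDefined = FALSE` when `dS` is
#'   0) and `nCodons`.
#' @export
ng86 <- function(seq1, seq2) {
  if (is(seq1, "CodonAlignment")) {
    rows <- as.character(alignmentSeqs(seq1))
    if (length(seq2) != 2L)
      stop("when given an alignment, the second argument names two taxa")
    seq1 <- rows[[seq2[[1]]]]
    seq2 <- rows[[seq2[[2]]]]
  }
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be equal length")
  c1 <- .splitCodons(toupper(seq1))
  c2 <- .splitCodons(toupper(seq2))
  keep <- c1 %in% .codons() & c2 %in% .codons()
  c1 <- c1[keep]; c2 <- c2[keep]
  n <- length(c1)
  if (n == 0L) stop("no comparable codons")
  sSites <- .rf$sSites
  S <- (sum(sSites[c1]) + sum(sSites[c2])) / 2
  N <- 3 * n - S
  diffs <- vapply(seq_len(n), function(i) .pairDiffs(c1[i], c2[i]),
                  numeric(2))
  Nd <- sum(diffs["nd", ])
  Sd <- sum(diffs["sd", ])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN); dS <- jc(pS)
  defined <- !is.na(dS) && dS > 0 && !is.na(dN)
  omega <- if (defined) dN / dS else NA_real_
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, omega = omega, omegaDefined = defined,
                 nCodons = n), class = "Ng86Result")
}

#' @export
print.Ng86Result <- function(x, ...) {
  cat(sprintf("NG86: N = %.2f S = %.2f  Nd = %.2f Sd = %.2f\n",
              x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("      dN = %.4f dS = %.4f  omega = %s\n", x$dN, x$dS,
              if (x$omegaDefined) sprintf("%.4f", x$omega) else
                "undefined (dS = 0)"))
  invisible(x)
}

#' Classify substitutions between an ancestral and a descendant sequence
#'
#' Codons differing at one position are classified directly from the genetic
#' code; multi-difference codons are averaged over all minimal substitution
#' paths that avoid stop codons, giving fractional counts (reported to 2 dp;
#' rounding to integers is left to display code).
#'
#' @param seqAnc,seqDesc equal-length in-frame codon sequences.
#' @return named numeric vector `c(nonsynonymous =, synonymous =)`.
#' @export
classifySubstitutions <- function(seqAnc, seqDesc) {
  if (nchar(seqAnc) != nchar(seqDesc) || nchar(seqAnc) %% 3L != 0L)
    stop("sequences must be equal length and in frame")
  c1 <- .splitCodons(toupper(seqAnc))
  c2 <- .splitCodons(toupper(seqDesc))
  keep <- c1 %in% .codons() & c2 %in% .codons()
  diffs <- vapply(which(keep), function(i) .pairDiffs(c1[i], c2[i]),
                  numeric(2))
  if (length(diffs) == 0L) return(c(nonsynonymous = 0, synonymous = 0))
  c(nonsynonymous = round(sum(diffs["nd", ]), 2),
    synonymous = round(sum(diffs["sd", ]), 2))
}
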