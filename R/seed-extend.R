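# Seed-and-extend local search: exact k-mer seeds located with Biostrings,
# chained by diagonal clustering, and extended with the package's own
# affine-gap Smith-Waterman kernel on a bounded window. Desk-scale genomes
# (tens of Mb) only; no index is persisted.

#' Seed-and-extend search of a query against a genome
#'
#' Finds local alignments of `query` on both strands of every chromosome in
#' `genome`. Exact `k`-mer matches are clustered by diagonal into candidate
#' windows, each window is aligned with an affine-gap local aligner
#' (defaults: match +1, mismatch -2, gap open -4, gap extend -1), and hits
#' below the identity or length floor are dropped.
#'
#' @param query query sequence (character or `DNAString`), e.g. an mRNA.
#' @param genome named `DNAStringSet`.
#' @param k seed length, in `[8, 16]`.
#' @param minIdentity minimum fraction of matching columns.
#' @param minLen minimum aligned query length in bp.
#' @param scoring named list overriding `match`, `mismatch`, `gapOpen`,
#'   `gapExt`.
#' @param minSeeds minimum seeds per cluster before extension is attempted.
#' @param maxDiagGap diagonal drift allowed within one cluster.
#' @return data.frame of hits sorted by score (descending): `chrom`,
#'   `strand`, `qstart`, `qend`, `tstart`, `tend`, `score`, `identity`
#'   (matching bases over the aligned query span; target-side gaps such as
#'   bridged introns do not dilute it - they are judged by the intronless
#'   criterion instead), `length`, plus a `blocks` list-column of gapless
#'   block tables
#'   (target coordinates are genomic; for `-` hits the query coordinates
#'   refer to the reverse-complemented query).
#' @export
seedAndExtend <- function(query, genome, k = 12, minIdentity = 0.8,
                          minLen = 100, scoring = list(), minSeeds = 2,
                          maxDiagGap = 60) {
  sc <- modifyList(list(match = 1, mismatch = -2, gapOpen = 4, gapExt = 1),
                   scoring)
  query <- toupper(as.character(query))
  if (nchar(query) < k) stop("query shorter than seed length k")
  if (k < 8 || k > 16) stop("k must lie in [8, 16]")
  hits <- list()
  for (chrom in names(genome)) {
    tseq <- as.character(genome[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else .revcomp(query)
      clusters <- .seedClusters(q, tseq, k, minSeeds, maxDiagGap)
      for (cl in clusters) {
        win <- .extendWindow(cl, nchar(q), nchar(tseq))
        sub <- substr(tseq, win[1], win[2])
        al <- .rfSwAlign(q, sub, sc$match, sc$mismatch, sc$gapOpen, sc$gapExt)
        if (is.na(al$qstart)) next
        bl <- al$blocks
        bl$tstart <- bl$tstart + win[1] - 1L
        bl$tend <- bl$tend + win[1] - 1L
        qlen <- al$qend - al$qstart + 1L
        ident <- sum(bl$nmatch) / qlen
        if (ident < minIdentity || qlen < minLen) next
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, qstart = al$qstart,
          qend = al$qend, tstart = bl$tstart[1], tend = bl$tend[nrow(bl)],
          score = al$score, identity = ident, length = qlen,
          stringsAsFactors = FALSE, blocks = I(list(bl)))
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      qstart = integer(0), qend = integer(0),
                      tstart = integer(0), tend = integer(0),
                      score = numeric(0), identity = numeric(0),
                      length = integer(0), blocks = I(list())))
  out <- do.call(rbind, hits)
  out <- out[order(-out$score), , drop = FALSE]
  # drop duplicate/contained hits from overlapping windows
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      same <- out$chrom[j] == out$chrom[i] & out$strand[j] == out$strand[i]
      ov <- min(out$tend[i], out$tend[j]) - max(out$tstart[i], out$tstart[j])
      if (same && ov > 0.5 * (out$tend[j] - out$tstart[j])) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact k-mer seeds via matchPDict, clustered by diagonal
.seedClusters <- function(q, tseq, k, minSeeds, maxDiagGap) {
  qlen <- nchar(q)
  starts <- seq(1L, qlen - k + 1L, by = max(1L, k %/% 2L))
  kmers <- substring(q, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  if (!any(ok)) return(list())
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[ok]))
  m <- Biostrings::matchPDict(dict, Biostrings::DNAString(tseq))
  qpos <- rep(starts[ok], S4Vectors::elementNROWS(m))
  tpos <- BiocGenerics::unlist(BiocGenerics::start(m))
  if (length(tpos) == 0L) return(list())
  diag <- tpos - qpos
  o <- order(diag, tpos)
  diag <- diag[o]; tpos <- tpos[o]; qpos <- qpos[o]
  brk <- c(TRUE, diff(diag) > maxDiagGap | diff(tpos) > qlen + 200L)
  grp <- cumsum(brk)
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < minSeeds) next
    out[[length(out) + 1L]] <- list(tmin = min(tpos[sel]),
                                    tmax = max(tpos[sel]),
                                    qmin = min(qpos[sel]),
                                    qmax = max(qpos[sel]))
  }
  # merge clusters whose target extents overlap (same locus, drifting diagonal)
  if (length(out) > 1L) {
    o <- order(vapply(out, `[[`, numeric(1), "tmin"))
    out <- out[o]
    merged <- list(out[[1]])
    for (i in seq_along(out)[-1]) {
      last <- merged[[length(merged)]]
      cur <- out[[i]]
      if (cur$tmin <= last$tmax + 100L) {
        merged[[length(merged)]] <- list(tmin = last$tmin,
                                         tmax = max(last$tmax, cur$tmax),
                                         qmin = min(last$qmin, cur$qmin),
                                         qmax = max(last$qmax, cur$qmax))
      } else merged[[length(merged) + 1L]] <- cur
    }
    out <- merged
  }
  out
}

.extendWindow <- function(cl, qlen, tlen) {
  margin <- 250L
  left <- max(1L, cl$tmin - cl$qmin - margin)
  right <- min(tlen, cl$tmax + (qlen - cl$qmax) + margin)
  c(left, right)
}
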