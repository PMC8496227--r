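# Truth-tracked synthetic genomes: multi-exon parent genes, LINE-1-style
# retrocopy insertions (5' truncation, poly-A tail, target-site duplication),
# and post-insertion mutational decay. Every event is recorded so detection
# can be scored against ground truth.

.randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.setChrom <- function(genome, chrom, seq) {
  chars <- as.character(genome)
  chars[[chrom]] <- seq
  Biostrings::DNAStringSet(chars)
}

#' Simulate a multi-exon parent gene on a genome segment
#'
#' Generates a random chromosome carrying one protein-coding gene whose CDS
#' begins with ATG, ends with a stop codon and contains no internal stops.
#' The spliced mRNA is the concatenation of the exon sequences in transcript
#' order (reverse-complemented for minus-strand genes).
#'
#' @param nExons number of exons (>= 1).
#' @param exonLenRange exon length range in bp; lengths are drawn uniformly
#'   and trimmed so the total CDS length is a multiple of 3.
#' @param intronLenRange intron length range in bp.
#' @param strand `"+"` or `"-"`.
#' @param flank flanking sequence added on each side of the gene.
#' @param chrom chromosome name for the annotation.
#' @param geneId gene identifier.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `genome` (named `DNAStringSet`), `annot`
#'   ([GenomeAnnotation-class]) and `mrna` (spliced transcript, character).
#' @export
makeParentGene <- function(nExons = 3, exonLenRange = c(120, 400),
                           intronLenRange = c(200, 1200), strand = "+",
                           flank = 2000, chrom = "chrP", geneId = "parent",
                           seed = 1) {
  if (nExons < 1) stop("nExons must be >= 1")
  if (exonLenRange[1] > exonLenRange[2] || exonLenRange[1] < 3 ||
      (nExons > 1 && intronLenRange[1] > intronLenRange[2]))
    stop("infeasible length ranges")
  set.seed(seed)
  exLen <- sample(seq(exonLenRange[1], exonLenRange[2]), nExons,
                  replace = TRUE)
  total <- sum(exLen)
  exLen[nExons] <- exLen[nExons] - (total %% 3L)
  if (exLen[nExons] < 1) stop("infeasible length ranges")
  total <- sum(exLen)

  # CDS in transcript orientation: ATG + sense codons + stop
  nCod <- total / 3L - 2L
  if (nCod < 1) stop("infeasible length ranges: CDS too short")
  .codonTables()
  body <- paste(sample(.rf$codons[.rf$aa != "M"], nCod, replace = TRUE),
                collapse = "")
  cdsSeq <- paste0("ATG", body, sample(.rf$stops, 1))
  mrna <- cdsSeq

  pieces <- substring(cdsSeq, cumsum(c(1, head(exLen, -1))),
                      cumsum(exLen))
  intLen <- if (nExons > 1)
    sample(seq(intronLenRange[1], intronLenRange[2]), nExons - 1,
           replace = TRUE) else integer(0)
  # genomic exon order: transcript order on +, reversed on -
  genomicPieces <- if (strand == "+") pieces else rev(vapply(pieces, .revcomp,
                                                             character(1)))
  geneParts <- character(0)
  starts <- integer(nExons); ends <- integer(nExons)
  pos <- flank + 1L
  for (i in seq_len(nExons)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(genomicPieces[i]) - 1L
    geneParts <- c(geneParts, genomicPieces[i])
    pos <- ends[i] + 1L
    if (i < nExons) {
      geneParts <- c(geneParts, .randDna(intLen[i]))
      pos <- pos + intLen[i]
    }
  }
  genomeSeq <- paste0(.randDna(flank), paste(geneParts, collapse = ""),
                      .randDna(flank))
  genome <- Biostrings::DNAStringSet(setNames(genomeSeq, chrom))
  annot <- GenomeAnnotation(geneId, chrom, strand,
                            IRanges::IRanges(starts, ends))
  list(genome = genome, annot = annot, mrna = mrna)
}

#' Insert a retrocopy into a genome
#'
#' Splices `[TSD][truncated mRNA (or its reverse complement)][poly-A][TSD]`
#' into the chromosome at `site`, the TSD being a copy of the `tsdLen` bases
#' at the site (so the genome grows by the insert length plus `tsdLen`).
#' The poly-A tail carries a configurable fraction of non-A contamination.
#'
#' @param genome named `DNAStringSet` with one chromosome, or the list
#'   returned by [makeParentGene()].
#' @param mrna parent mRNA (character).
#' @param site 1-based position before which the insert is placed; the TSD is
#'   copied from `site .. site + tsdLen - 1`.
#' @param chrom chromosome to insert into (default first).
#' @param tsdLen target-site duplication length (0 disables).
#' @param polyALen poly-A tail length in nt.
#' @param polyAImpurity fraction of non-A bases in the tail.
#' @param polyASeq optional explicit tail sequence; overrides `polyALen` and
#'   `polyAImpurity` (used when the caller needs the exact insert string).
#' @param truncation number of nt removed from the 5' end of the mRNA.
#' @param strand orientation of the inserted copy.
#' @param forbid optional `IRanges` of coordinates (e.g. the parent locus)
#'   the site must not fall in.
#' @param seed integer seed.
#' @return list with `genome` (modified) and `truth` (a one-row data.frame:
#'   parent/chrom/insert interval of the full mRNA+poly-A insert, TSD
#'   sequence and length, poly-A length, truncation, strand).
#' @export
plantRetrocopy <- function(genome, mrna, site, chrom = NULL, tsdLen = 12,
                           polyALen = 30, polyAImpurity = 0, polyASeq = NULL,
                           truncation = 0, strand = "+", forbid = NULL,
                           seed = 1) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (is.null(chrom)) chrom <- names(genome)[1]
  chromSeq <- as.character(genome[[chrom]])
  L <- nchar(chromSeq)
  if (site < 1 || site + tsdLen - 1 > L) stop("site outside chromosome")
  if (tsdLen < 0) stop("tsdLen must be >= 0")
  if (truncation >= nchar(mrna)) stop("truncation must leave some mRNA")
  if (!is.null(forbid) &&
      any(site >= IRanges::start(forbid) & site <= IRanges::end(forbid)))
    stop("site falls inside a forbidden interval")
  set.seed(seed)
  tsd <- if (tsdLen > 0) substr(chromSeq, site, site + tsdLen - 1) else ""
  body <- substr(mrna, truncation + 1, nchar(mrna))
  if (is.null(polyASeq)) {
    tail <- rep("A", polyALen)
    if (polyAImpurity > 0 && polyALen > 0) {
      k <- rbinom(1, polyALen, polyAImpurity)
      if (k > 0) tail[sample(polyALen, k)] <- sample(c("C", "G", "T"), k,
                                                     replace = TRUE)
    }
    polyASeq <- paste(tail, collapse = "")
  }
  polyALen <- nchar(polyASeq)
  insert <- paste0(body, polyASeq)
  if (strand == "-") insert <- .revcomp(insert)
  # pre-insertion: [.. site-1][T][site+tsdLen ..]; post: [.. T][insert][T ..]
  left <- substr(chromSeq, 1, site + tsdLen - 1)
  right <- substr(chromSeq, site + tsdLen, L)
  newSeq <- paste0(left, insert, tsd, right)
  genome <- .setChrom(genome, chrom, newSeq)
  truth <- data.frame(
    parent_id = "parent", chrom = chrom,
    insert_start = site + tsdLen, insert_end = site + tsdLen +
      nchar(insert) - 1L,
    tsd_seq = tsd, tsd_len = tsdLen, polyA_len = polyALen,
    truncation = truncation, strand = strand, stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Mutational decay of a sequence
#'
#' Applies random substitutions and short indels at the given per-base rates
#' and returns the decayed sequence together with an event log that
#' deterministically reproduces it. Optionally inserts fixed-size cassettes
#' (Alu-like blocks) at random positions.
#'
#' @param seq input sequence (character).
#' @param subRate per-base substitution probability, in `[0, 0.5]`.
#' @param indelRate per-base probability of starting a 1-6 bp indel.
#' @param cassettes number of 300 bp cassette insertions.
#' @param cassetteLen cassette length in bp.
#' @param seed integer seed.
#' @return list with `seq` (decayed) and `events` (data.frame of type,
#'   position, original and replacement strings).
#' @export
decaySequence <- function(seq, subRate = 0.05, indelRate = 0, cassettes = 0,
                          cassetteLen = 300, seed = 1) {
  if (subRate < 0 || subRate > 0.5 || indelRate < 0 || indelRate > 0.5)
    stop("rates must lie in [0, 0.5]")
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  events <- list()
  subs <- which(runif(n) < subRate)
  for (i in subs) {
    old <- chars[i]
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    events[[length(events) + 1L]] <- data.frame(
      type = "sub", pos = i, from = old, to = chars[i])
  }
  out <- chars
  if (indelRate > 0) {
    idx <- which(runif(n) < indelRate)
    # apply right-to-left so earlier positions stay valid
    for (i in rev(idx)) {
      len <- sample(1:6, 1)
      if (runif(1) < 0.5) {  # deletion
        to <- min(n, i + len - 1L)
        events[[length(events) + 1L]] <- data.frame(
          type = "del", pos = i, from = paste(out[i:to], collapse = ""),
          to = "")
        out <- out[-(i:to)]
      } else {
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        events[[length(events) + 1L]] <- data.frame(
          type = "ins", pos = i, from = "", to = paste(ins, collapse = ""))
        out <- append(out, ins, after = i - 1L)
      }
      n <- length(out)
    }
  }
  if (cassettes > 0) {
    for (k in seq_len(cassettes)) {
      cas <- .randDna(cassetteLen)
      at <- sample(length(out) - 1L, 1)
      events[[length(events) + 1L]] <- data.frame(
        type = "cassette", pos = at, from = "", to = cas)
      out <- append(out, strsplit(cas, "")[[1]], after = at)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), pos = integer(0), from = character(0),
               to = character(0))
  list(seq = paste(out, collapse = ""), events = ev)
}

#' Simulate a genome with planted retrocopies and a duplication decoy
#'
#' Builds one multi-exon parent gene on its own chromosome plus a target
#' chromosome carrying `nRetro` decayed retrocopy insertions (each with its
#' own TSD, poly-A tail and 5' truncation) and, optionally, one
#' intron-containing segmental-duplication decoy (a copy of the parent locus
#' including introns). TSDs are re-sited until they are pairwise distinct and
#' unambiguous (no accidental single-base extension), so exact recovery is
#' well defined.
#'
#' @param nRetro number of retrocopy insertions.
#' @param targetLen length of the target chromosome in bp.
#' @param identityRange per-copy identity range vs the parent mRNA; the decay
#'   substitution rate is drawn as `1 - identity`.
#' @param tsdRange TSD length range (uniform draw), bp.
#' @param polyARange poly-A length range (uniform draw), nt.
#' @param truncFracRange range of the 5' truncation as a fraction of the mRNA.
#' @param decoy plant an intron-containing duplication decoy.
#' @param nExons,exonLenRange,intronLenRange passed to [makeParentGene()].
#' @param seed integer seed.
#' @return list with `genome` (parent + target chromosomes), `annot`,
#'   `mrna`, `truth` (data.frame of planted inserts, decayed coordinates) and
#'   `preInsertionGenome` (the target chromosome before any insertion).
#' @export
simulateRetrocopyGenome <- function(nRetro = 5, targetLen = 1e6,
                                    identityRange = c(0.85, 0.97),
                                    tsdRange = c(5, 25),
                                    polyARange = c(10, 40),
                                    truncFracRange = c(0, 0.3),
                                    decoy = TRUE, nExons = 4,
                                    exonLenRange = c(150, 350),
                                    intronLenRange = c(150, 600),
                                    seed = 1) {
  set.seed(seed)
  par <- makeParentGene(nExons = nExons, exonLenRange = exonLenRange,
                        intronLenRange = intronLenRange,
                        seed = sample.int(1e8, 1))
  target <- .randDna(targetLen)
  genome <- c(par$genome, Biostrings::DNAStringSet(setNames(target, "chrT")))
  pre <- Biostrings::DNAStringSet(setNames(target, "chrT"))
  mlen <- nchar(par$mrna)

  truths <- list()
  usedTsd <- character(0)
  occupied <- IRanges::IRanges()
  for (i in seq_len(nRetro)) {
    found <- FALSE
    while (!found) {
      subRate <- 1 - runif(1, identityRange[1], identityRange[2])
      trunc <- floor(runif(1, truncFracRange[1], truncFracRange[2]) * mlen)
      trunc <- trunc - (trunc %% 3L)
      dec <- decaySequence(substr(par$mrna, trunc + 1, mlen),
                           subRate = subRate, seed = sample.int(1e8, 1))
      strand <- sample(c("+", "-"), 1)
      polyALen <- sample(seq(polyARange[1], polyARange[2]), 1)
      tail <- rep("A", polyALen)
      # 5% non-A contamination, kept out of the 2 nt abutting the TSD so the
      # junction stays unambiguous for exact-recovery scoring
      k <- rbinom(1, polyALen, 0.05)
      if (k > 0 && polyALen > 2) {
        at <- sample(polyALen - 2L, min(k, polyALen - 2L))
        tail[at] <- sample(c("C", "G", "T"), length(at), replace = TRUE)
      }
      tailSeq <- paste(tail, collapse = "")
      insStr <- paste0(dec$seq, tailSeq)
      if (strand == "-") insStr <- .revcomp(insStr)
      insFirst <- substr(insStr, 1, 1)
      insLast <- substr(insStr, nchar(insStr), nchar(insStr))
      cur <- as.character(genome[["chrT"]])
      for (try in seq_len(60L)) {
        site <- sample(seq(2000L, targetLen - 2000L), 1)
        tsdLen <- sample(seq(tsdRange[1], tsdRange[2]), 1)
        tsd <- substr(cur, site, site + tsdLen - 1)
        ov <- IRanges::countOverlaps(
          IRanges::IRanges(site - 50L, site + tsdLen + 50L), occupied)
        # the site is accepted when: it is clear of earlier inserts; the TSD
        # is unique across plantings; the TSD does not begin/end on A/T the
        # adjacent poly-A (or poly-T) tail could swallow; and the flank bases
        # just outside the two TSD copies do not match the first/last base of
        # the insert (which would extend the apparent repeat by chance)
        okFlanks <- ov == 0 && !tsd %in% usedTsd &&
          !substr(tsd, 1, 1) %in% c("A", "T") &&
          !substr(tsd, tsdLen, tsdLen) %in% c("A", "T") &&
          !insLast %in% strsplit(substr(cur, site - 2, site - 1), "")[[1]] &&
          !insFirst %in% strsplit(substr(cur, site + tsdLen,
                                         site + tsdLen + 1), "")[[1]]
        if (!okFlanks) next
        # the planted junction must be unambiguous: detection on the exact
        # local context has to return precisely this TSD, otherwise the site
        # genuinely contains a competing direct repeat and is re-drawn
        # the local context must cover the scanner's full search margin
        # (maxLen + slop + maxTail) on both sides
        local <- paste0(substr(cur, site - 150L, site + tsdLen - 1L),
                        insStr, tsd,
                        substr(cur, site + tsdLen, site + tsdLen + 149L))
        bodyLen <- nchar(dec$seq)
        tailLen <- nchar(tailSeq)
        bodyInt <- if (strand == "+")
          c(151L + tsdLen, 150L + tsdLen + bodyLen) else
          c(151L + tsdLen + tailLen, 150L + tsdLen + tailLen + bodyLen)
        fnd <- .findTsdAnchored(
          Biostrings::DNAStringSet(setNames(local, "x")), "x", bodyInt,
          strand, slop = 20)
        if (!is.null(fnd) && identical(fnd$seq, tsd) &&
            fnd$len == tsdLen) { found <- TRUE; break }
      }
    }
    pl <- plantRetrocopy(genome, dec$seq, site = site, chrom = "chrT",
                         tsdLen = tsdLen, polyASeq = tailSeq,
                         truncation = 0,
                         strand = strand, seed = sample.int(1e8, 1))
    genome <- pl$genome
    tr <- pl$truth
    tr$truncation <- trunc
    tr$sub_rate <- subRate
    truths[[i]] <- tr
    usedTsd <- c(usedTsd, tr$tsd_seq)
    ins <- nchar(dec$seq) + tr$polyA_len + tsdLen
    # shift previously recorded truth intervals right of the new site
    if (length(truths) > 1L) for (j in seq_len(i - 1L)) {
      if (truths[[j]]$insert_start > site) {
        truths[[j]]$insert_start <- truths[[j]]$insert_start + ins
        truths[[j]]$insert_end <- truths[[j]]$insert_end + ins
      }
    }
    occupied <- IRanges::IRanges(
      vapply(truths, function(t) t$insert_start - t$tsd_len - 5L, numeric(1)),
      vapply(truths, function(t) t$insert_end + t$tsd_len + 5L, numeric(1)))
  }
  truth <- do.call(rbind, truths)

  decoyTruth <- NULL
  if (decoy) {
    locus <- range(exonRanges(par$annot))
    locusSeq <- substr(as.character(par$genome[[1]]),
                       IRanges::start(locus), IRanges::end(locus))
    dec <- decaySequence(locusSeq, subRate = 0.05, seed = sample.int(1e8, 1))
    repeat {
      site <- sample(seq(2000L, targetLen - 2000L), 1)
      if (IRanges::countOverlaps(
        IRanges::IRanges(site - 50L, site + nchar(dec$seq) + 50L),
        IRanges::IRanges(truth$insert_start - truth$tsd_len - 5L,
                         truth$insert_end + truth$tsd_len + 5L)) == 0) break
    }
    cur <- as.character(genome[["chrT"]])
    genome <- .setChrom(genome, "chrT",
                        paste0(substr(cur, 1, site - 1), dec$seq,
                               substr(cur, site, nchar(cur))))
    shift <- nchar(dec$seq)
    moved <- truth$insert_start >= site
    truth$insert_start[moved] <- truth$insert_start[moved] + shift
    truth$insert_end[moved] <- truth$insert_end[moved] + shift
    decoyTruth <- data.frame(chrom = "chrT", start = site,
                             end = site + shift - 1L)
  }
  list(genome = genome, annot = par$annot, mrna = par$mrna, truth = truth,
       decoy = decoyTruth, preInsertionGenome = pre)
}
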