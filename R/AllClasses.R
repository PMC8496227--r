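#' Exon/intron structure of a gene on a genome
#'
#' Holds the coordinates of one parent gene: its chromosome, strand, exon
#' ranges and CDS ranges, using the 1-based inclusive [IRanges::IRanges]
#' convention throughout (the convention of the GFF3 files the object
#' round-trips with).
#'
#' @slot geneId single gene identifier.
#' @slot chrom chromosome/contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exons, sorted, non-overlapping.
#' @slot cds [IRanges::IRanges] of coding ranges, contained in the exon union.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(geneId = "character", chrom = "character",
                 strand = "character", exons = "IRanges", cds = "IRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    if (any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (length(object@cds)) {
    cov <- IRanges::setdiff(object@cds, ex)
    if (length(cov)) msg <- c(msg, "cds must lie within the exon union")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] of exon coordinates (1-based inclusive).
#' @param cds [IRanges::IRanges] of CDS coordinates; defaults to the exons.
#' @return a [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(geneId, chrom, strand, exons, cds = exons) {
  new("GenomeAnnotation", geneId = geneId, chrom = chrom, strand = strand,
      exons = exons, cds = cds)
}

#' @describeIn GenomeAnnotation gene identifier accessor
#' @param x a `GenomeAnnotation`.
#' @export
geneId <- function(x) x@geneId

#' @describeIn GenomeAnnotation exon ranges accessor
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GenomeAnnotation CDS ranges accessor
#' @export
cdsRanges <- function(x) x@cds

#' @describeIn GenomeAnnotation chromosome accessor
#' @export
annotChrom <- function(x) x@chrom

#' @describeIn GenomeAnnotation strand accessor
#' @export
annotStrand <- function(x) x@strand

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", object@geneId, "on", object@chrom,
      paste0("(", object@strand, ")"), "with", length(object@exons),
      "exon(s)\n")
})

#' In-frame codon alignment
#'
#' A gapless, in-frame alignment of coding sequences, the substrate of all
#' codon-model analyses. Constructed with [codonAlignment()], which can clean
#' gap/ambiguity columns first.
#'
#' @slot seqs a [Biostrings::DNAStringSet], equal widths divisible by 3.
#' @slot removedColumns integer count of codon columns removed by cleaning.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(seqs = "DNAStringSet", removedColumns = "integer"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character(0)
  if (length(w) < 2L) msg <- c(msg, "need at least 2 sequences")
  if (length(unique(w)) > 1L) msg <- c(msg, "all rows must have equal length")
  if (length(w) && w[1] %% 3L != 0L)
    msg <- c(msg, "alignment length must be divisible by 3")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "sequences must carry unique taxon names")
  if (length(msg)) msg else TRUE
})

#' Construct a codon alignment
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of aligned
#'   coding sequences.
#' @param clean remove codon columns containing gaps or ambiguity codes
#'   (the usual `cleandata` policy); the number removed is recorded.
#' @return a [CodonAlignment-class].
#' @export
codonAlignment <- function(seqs, clean = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  removed <- 0L
  if (clean) {
    m <- .codonMatrixFromSeqs(seqs)
    bad <- apply(m, 2, function(col) any(grepl("[^ACGT]", col)))
    removed <- sum(bad)
    if (removed) {
      keep <- which(!bad)
      seqs <- Biostrings::DNAStringSet(vapply(seq_along(seqs), function(i)
        paste(m[i, keep], collapse = ""), character(1)))
      names(seqs) <- rownames(m)
    }
  }
  new("CodonAlignment", seqs = seqs, removedColumns = removed)
}

.codonMatrixFromSeqs <- function(seqs) {
  m <- t(vapply(as.character(seqs), .splitCodons,
                character(Biostrings::width(seqs)[1] / 3)))
  rownames(m) <- names(seqs)
  m
}

#' @describeIn codonAlignment taxon names
#' @param x a `CodonAlignment`.
#' @export
taxa <- function(x) names(x@seqs)

#' @describeIn codonAlignment number of codon columns
#' @export
nCodons <- function(x) Biostrings::width(x@seqs)[1] %/% 3L

#' @describeIn codonAlignment codon matrix (taxa x sites)
#' @export
codonMatrix <- function(x) .codonMatrixFromSeqs(x@seqs)

#' @describeIn codonAlignment underlying sequences
#' @export
alignmentSeqs <- function(x) x@seqs

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@seqs), "taxa x", nCodons(object),
      "codons")
  if (object@removedColumns)
    cat(" (", object@removedColumns, " columns removed by cleaning)", sep = "")
  cat("\n")
})

#' Phylogeny with foreground branch labels
#'
#' Wraps an [ape::read.tree] phylogeny together with a logical flag per edge
#' marking the foreground clade of branch-site analyses. In newick input the
#' foreground is marked with the conventional `#1` suffix on tip or internal
#' node labels.
#'
#' @slot tree an [ape] `phylo` object.
#' @slot foreground logical vector, one entry per row of `tree$edge`.
#' @exportClass LabeledTree
setClass("LabeledTree",
  representation(tree = "ANY", foreground = "logical"))

setValidity("LabeledTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (length(object@foreground) != nrow(object@tree$edge))
    return("foreground must have one flag per edge")
  TRUE
})

#' Construct a LabeledTree
#' @param tree an `ape` phylo object.
#' @param foreground logical per edge of `tree$edge`; default all background.
#' @return a [LabeledTree-class].
#' @export
labeledTree <- function(tree, foreground = rep(FALSE, nrow(tree$edge))) {
  new("LabeledTree", tree = tree, foreground = foreground)
}

#' @describeIn labeledTree the underlying phylo object
#' @param x a `LabeledTree`.
#' @export
treePhylo <- function(x) x@tree

#' @describeIn labeledTree logical foreground flag per edge
#' @export
foregroundEdges <- function(x) x@foreground

setMethod("show", "LabeledTree", function(object) {
  cat("LabeledTree:", length(object@tree$tip.label), "tips,",
      sum(object@foreground), "foreground edge(s)\n")
})

#' Branch-site model fit
#'
#' Parameter estimates and log-likelihood of branch-site Model A (or its null
#' with the positive-selection ratio fixed at 1): site-class proportions
#' `p0`, `p1` and the combined positively selected proportion `p2 + p3`,
#' ratios `omega0` (0 <= omega0 <= 1), `omega1 = 1` and `omega2`, plus the
#' transition/transversion ratio `kappa` and re-optimized branch lengths.
#'
#' @exportClass BranchSiteFit
setClass("BranchSiteFit",
  representation(model = "character", p0 = "numeric", p1 = "numeric",
                 p2plus3 = "numeric", omega0 = "numeric", omega1 = "numeric",
                 omega2 = "numeric", kappa = "numeric", logL = "numeric",
                 tree = "ANY", convergence = "list", details = "list"))

setValidity("BranchSiteFit", function(object) {
  p <- c(object@p0, object@p1, object@p2plus3)
  msg <- character(0)
  if (any(p < -1e-8) || abs(sum(p) - 1) > 1e-6)
    msg <- c(msg, "class proportions must lie in [0,1] and sum to 1")
  if (object@omega0 < 0 || object@omega0 > 1 + 1e-8)
    msg <- c(msg, "omega0 must lie in [0,1]")
  if (object@omega1 != 1) msg <- c(msg, "omega1 is fixed at 1")
  if (object@model == "ModelA_null" && abs(object@omega2 - 1) > 1e-8)
    msg <- c(msg, "the null model fixes omega2 = 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BranchSiteFit", function(object) {
  cat(sprintf("BranchSiteFit [%s]  logL = %.2f\n", object@model, object@logL))
  cat(sprintf("  p0 = %.3f  p1 = %.3f  p2+p3 = %.3f\n",
              object@p0, object@p1, object@p2plus3))
  cat(sprintf("  omega0 = %.3f  omega1 = 1.000  omega2 = %.3f  kappa = %.2f\n",
              object@omega0, object@omega2, object@kappa))
})

#' @describeIn BranchSiteFit log-likelihood accessor
#' @param x a `BranchSiteFit`.
#' @export
fitLogL <- function(x) x@logL

#' @describeIn BranchSiteFit named vector of the headline parameters
#' @export
fitParams <- function(x)
  c(p0 = x@p0, p1 = x@p1, p2plus3 = x@p2plus3, omega0 = x@omega0,
    omega1 = x@omega1, omega2 = x@omega2, kappa = x@kappa)

#' Likelihood ratio test result
#'
#' @slot twoDeltaL twice the log-likelihood difference of the nested models.
#' @slot df degrees of freedom.
#' @slot pValue upper-tail chi-square probability.
#' @exportClass LRTResult
setClass("LRTResult",
  representation(twoDeltaL = "numeric", df = "numeric", pValue = "numeric"))

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT: 2*deltaL = %.3f on %d df, P = %.4g\n",
              object@twoDeltaL, as.integer(object@df), object@pValue))
})

#' Monte-Carlo neutral null result
#'
#' @slot observedOmega observed pairwise NG86 dN/dS.
#' @slot nullSamples vector of dN/dS draws under neutral resimulation.
#' @slot pValue continuity-corrected upper-tail Monte-Carlo p.
#' @slot quantiles summary quantiles of the null.
#' @exportClass NeutralNullResult
setClass("NeutralNullResult",
  representation(observedOmega = "numeric", nullSamples = "numeric",
                 pValue = "numeric", quantiles = "numeric"))

setMethod("show", "NeutralNullResult", function(object) {
  cat(sprintf(
    "NeutralNullResult: observed omega = %.3f, P = %.4g (%d null draws)\n",
    object@observedOmega, object@pValue, length(object@nullSamples)))
})

#' @describeIn NeutralNullResult Monte-Carlo p-value accessor
#' @param x a `NeutralNullResult`.
#' @export
nullPValue <- function(x) x@pValue
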