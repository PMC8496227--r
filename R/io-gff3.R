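# GFF3 gene-model import/export via rtracklayer, mapped onto the package's
# GenomeAnnotation container. Coordinates stay in the 1-based inclusive
# convention that GFF3 and IRanges share, so there is no conversion layer to
# get wrong.

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS features and assembles one [GenomeAnnotation]
#' per gene. Exon/CDS features must be linked to their gene through `Parent`
#' attributes (directly or via an mRNA).
#'
#' @param path path to a GFF3 file.
#' @param genome optional named sequence set; when given, features beyond the
#'   end of their chromosome raise an error.
#' @return a list of [GenomeAnnotation-class] objects, one per gene.
#' @export
readGff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  idOf <- function(x) as.character(x$ID)
  parentOf <- function(x) vapply(x$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))

  mrna <- gr[typ == "mRNA"]
  mrnaGene <- setNames(parentOf(mrna), idOf(mrna))
  sub <- gr[typ %in% c("exon", "CDS")]
  if (length(sub)) {
    if (is.null(sub$Parent) || all(S4Vectors::elementNROWS(sub$Parent) == 0))
      stop("exon/CDS feature(s) missing a Parent attribute")
    par <- parentOf(sub)
    if (anyNA(par)) stop("exon/CDS feature(s) missing a Parent attribute")
    # resolve mRNA parents to their gene
    viaMrna <- par %in% names(mrnaGene)
    par[viaMrna] <- mrnaGene[par[viaMrna]]
    if (!all(par %in% idOf(genes)))
      stop("Parent attribute(s) do not resolve to a gene: ",
           paste(unique(par[!par %in% idOf(genes)]), collapse = ", "))
  } else par <- character(0)

  lapply(seq_along(genes), function(i) {
    gid <- idOf(genes)[i]
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    strand <- as.character(BiocGenerics::strand(genes))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    mine <- sub[par == gid]
    take <- function(what) {
      r <- IRanges::ranges(mine[as.character(mine$type) == what])
      IRanges::reduce(BiocGenerics::sort(r))
    }
    ex <- take("exon")
    cds <- take("CDS")
    if (length(ex) == 0L) ex <- IRanges::ranges(genes[i])
    if (length(cds) == 0L) cds <- ex
    if (!is.null(genome)) {
      lim <- Biostrings::width(genome)[match(chrom, names(genome))]
      if (!is.na(lim) && max(IRanges::end(ex)) > lim)
        stop("exon beyond end of ", chrom, " for gene ", gid)
    }
    GenomeAnnotation(gid, chrom, strand, ex, cds)
  })
}

#' Write gene models to GFF3
#'
#' @param annots a list of [GenomeAnnotation-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(annots, path) {
  if (is(annots, "GenomeAnnotation")) annots <- list(annots)
  rows <- lapply(annots, function(a) {
    ex <- exonRanges(a); cds <- cdsRanges(a)
    gid <- geneId(a)
    mid <- paste0(gid, ".t1")
    c(.gffLine(a, min(IRanges::start(ex)), max(IRanges::end(ex)), "gene",
               paste0("ID=", gid)),
      .gffLine(a, min(IRanges::start(ex)), max(IRanges::end(ex)), "mRNA",
               paste0("ID=", mid, ";Parent=", gid)),
      vapply(seq_along(ex), function(i)
        .gffLine(a, IRanges::start(ex)[i], IRanges::end(ex)[i], "exon",
                 paste0("ID=", mid, ".exon", i, ";Parent=", mid)),
        character(1)),
      vapply(seq_along(cds), function(i)
        .gffLine(a, IRanges::start(cds)[i], IRanges::end(cds)[i], "CDS",
                 paste0("ID=", mid, ".cds", i, ";Parent=", mid)),
        character(1)))
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

.gffLine <- function(a, start, end, type, attrs) {
  paste(annotChrom(a), "retroforge", type, start, end, ".", annotStrand(a),
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}

#' Spliced transcript sequence of an annotated gene
#'
#' Concatenates the exon sequences in transcript order (reverse-complemented
#' exons in reverse order for minus-strand genes).
#'
#' @param annot a [GenomeAnnotation-class].
#' @param genome named `DNAStringSet` containing `annotChrom(annot)`.
#' @param what `"exons"` or `"cds"`.
#' @return the spliced sequence as a character scalar.
#' @export
splicedSeq <- function(annot, genome, what = c("exons", "cds")) {
  what <- match.arg(what)
  chrom <- genome[[annotChrom(annot)]]
  r <- if (what == "exons") exonRanges(annot) else cdsRanges(annot)
  parts <- vapply(seq_along(r), function(i)
    as.character(Biostrings::subseq(chrom, IRanges::start(r)[i],
                                    IRanges::end(r)[i])), character(1))
  s <- paste(parts, collapse = "")
  if (annotStrand(annot) == "-") s <- .revcomp(s)
  s
}
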