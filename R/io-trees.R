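# Newick trees with foreground branch labels, plus the two tabular readers
# (per-mutation free-energy tables and fixed-column ATOM coordinate records).

#' Read a newick tree with foreground labels
#'
#' Parses newick via [ape::read.tree]. Tip or internal-node labels carrying
#' the conventional `#1` suffix mark their leading branch as foreground (the
#' convention of mainstream codon-model software); an internal `#1` label
#' marks the branch above that node only, so label every branch of a clade
#' explicitly if the whole clade is foreground.
#'
#' @param path path to a newick file (or a newick string when `text = TRUE`).
#' @param text interpret `path` as newick text rather than a file name.
#' @return a [LabeledTree-class] with `#1` tags stripped from labels.
#' @export
readLabeledTree <- function(path, text = FALSE) {
  nwk <- if (text) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  .checkNewick(nwk)
  tr <- tryCatch(ape::read.tree(text = nwk),
                 error = function(e) stop("unparsable newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparsable newick at character 1")
  fgTip <- grepl("#1$", tr$tip.label)
  tr$tip.label <- sub("\\s*#1$", "", tr$tip.label)
  fgNode <- rep(FALSE, tr$Nnode)
  if (!is.null(tr$node.label)) {
    fgNode <- grepl("#1$", tr$node.label)
    tr$node.label <- sub("\\s*#1$", "", tr$node.label)
  }
  ntip <- length(tr$tip.label)
  childFg <- c(fgTip, fgNode)
  fgEdge <- childFg[tr$edge[, 2]]
  labeledTree(tr, fgEdge)
}

# minimal structural check so malformed newick is reported with a position
.checkNewick <- function(nwk) {
  chars <- strsplit(nwk, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unparsable newick: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("unparsable newick: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";\\s*$", nwk))
    stop("unparsable newick: missing terminal ';' at character ", nchar(nwk))
}

#' Write a labeled tree to newick
#'
#' Foreground edges are emitted as `#1` suffixes on their child labels.
#'
#' @param ltree a [LabeledTree-class].
#' @param path output path, or `NULL` to return the newick string.
#' @export
writeLabeledTree <- function(ltree, path = NULL) {
  tr <- treePhylo(ltree)
  fg <- foregroundEdges(ltree)
  ntip <- length(tr$tip.label)
  childFg <- rep(FALSE, ntip + tr$Nnode)
  childFg[tr$edge[fg, 2]] <- TRUE
  tr$tip.label <- paste0(tr$tip.label, ifelse(childFg[seq_len(ntip)], "#1", ""))
  nl <- tr$node.label
  if (is.null(nl)) nl <- rep("", tr$Nnode)
  tr$node.label <- paste0(nl, ifelse(childFg[ntip + seq_len(tr$Nnode)],
                                     "#1", ""))
  nwk <- ape::write.tree(tr, digits = 10)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Read a per-substitution free-energy table
#'
#' Reads a UTF-8 tab-delimited table with header columns `site`, `wt_aa`,
#' `mut_aa`, `ddg_bind`, `ddg_fold` (kcal/mol) and validates every row.
#'
#' @param path path to the TSV file.
#' @return a data.frame with the five validated columns (and any extras).
#' @export
readDdgTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c("site", "wt_aa", "mut_aa", "ddg_bind", "ddg_fold")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  badAa <- which(!(d$wt_aa %in% aa & d$mut_aa %in% aa))
  if (length(badAa))
    stop("illegal amino-acid code at row(s): ", paste(badAa, collapse = ", "))
  for (col in c("ddg_bind", "ddg_fold")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric ", col, " at row(s): ", paste(bad, collapse = ", "))
    d[[col]] <- v
  }
  d$site <- as.integer(d$site)
  if (anyNA(d$site)) stop("non-integer site value(s)")
  d
}

#' Read ATOM coordinates for selected chains
#'
#' Parses standard fixed-column ATOM records (via [bio3d::read.pdb]) and
#' returns one coordinate table per requested chain.
#'
#' @param path path to a coordinate file.
#' @param chains character vector of chain identifiers to load.
#' @return named list of data.frames with columns `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
readCoords <- function(path, chains) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  out <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, c("resno", "resid", "elety", "x", "y", "z"),
            drop = FALSE]
    if (nrow(a) == 0L) stop("no ATOM records for chain ", ch)
    if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
      stop("non-finite coordinates in chain ", ch)
    rownames(a) <- NULL
    a
  })
  names(out) <- chains
  out
}
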