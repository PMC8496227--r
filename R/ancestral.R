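# Marginal ancestral sequence reconstruction under a fitted single-class
# GY94 model: per-node, per-site posteriors over the 61 sense codons via an
# up-down (inside-outside) pass, reporting the maximum-posterior codon.

#' Marginal ancestral reconstruction
#'
#' Computes, for every internal node, the marginal posterior distribution
#' over the 61 sense codons at each site given a fitted model (kappa,
#' per-branch dN/dS and branch lengths), and reports the maximum-posterior
#' sequence. Posteriors at each site sum to 1.
#'
#' @param aln a [CodonAlignment-class].
#' @param fit a `FreeRatioFit` (from [fitFreeRatio()]), or a list with
#'   `tree` (phylo with fitted branch lengths), `kappa`, `omega` (scalar or
#'   per edge) and `codonFreqs`.
#' @return list with `sequences` (named character, one per internal node;
#'   names are node labels when present, else `"node<k>"` in ape numbering)
#'   and `posteriors` (list of 61 x nSites matrices).
#' @export
ancestralReconstruct <- function(aln, fit) {
  tree <- fit$tree
  kappa <- fit$kappa
  omega <- fit$omega
  if (is.null(omega)) stop("fit must provide per-branch omega")
  omega[!is.finite(omega)] <- 1  # unidentifiable (zero-length) branches
  pi <- fit$codonFreqs
  if (is.null(pi)) pi <- codonFrequencies(aln)
  .codonTables()
  type <- .codonType()
  st <- .treeStructure(tree)
  dat <- .codonData(aln, tree)
  E <- nrow(st$edge)
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  omPo <- if (length(omega) == 1L) rep(omega, E) else omega[idx]
  S <- ncol(dat$patterns)
  ntip <- st$ntip
  nnode <- max(st$edge)

  P <- vector("list", E)
  for (e in seq_len(E)) {
    mu <- .rfMeanRate(type, pi, kappa, omPo[e])
    P[[e]] <- .rfPmat(type, pi, kappa, omPo[e], st$blen[e] / mu)
  }

  tipPartial <- function(i) {
    m <- matrix(0, 61, S)
    stt <- dat$patterns[i, ] + 1L
    miss <- stt == 0L
    m[cbind(stt[!miss], which(!miss))] <- 1
    m[, miss] <- 1
    m
  }
  up <- vector("list", nnode)
  upMsg <- vector("list", E)  # message through edge e toward the root
  for (e in seq_len(E)) {
    par <- st$edge[e, 1]; ch <- st$edge[e, 2]
    chUp <- if (ch <= ntip) tipPartial(ch) else up[[ch]]
    msg <- P[[e]] %*% chUp
    msg <- sweep(msg, 2, pmax(apply(msg, 2, max), 1e-300), "/")
    upMsg[[e]] <- msg
    up[[par]] <- if (is.null(up[[par]])) msg else up[[par]] * msg
  }
  root <- st$edge[E, 1]

  # outside pass: out[v] = likelihood flow from the rest of the tree
  out <- vector("list", nnode)
  out[[root]] <- matrix(pi, 61, S)
  for (e in rev(seq_len(E))) {
    par <- st$edge[e, 1]; ch <- st$edge[e, 2]
    if (ch <= ntip) next
    above <- out[[par]] * up[[par]] / pmax(upMsg[[e]], 1e-300)
    m <- t(P[[e]]) %*% above
    m <- sweep(m, 2, pmax(apply(m, 2, max), 1e-300), "/")
    out[[ch]] <- m
  }

  codons <- .codons()
  internal <- (ntip + 1L):nnode
  labs <- if (!is.null(tree$node.label) &&
              all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", internal)
  post <- list()
  seqs <- character(length(internal))
  for (k in seq_along(internal)) {
    v <- internal[k]
    m <- up[[v]] * out[[v]]
    m <- sweep(m, 2, colSums(m), "/")
    mFull <- m[, dat$patternOf, drop = FALSE]
    post[[k]] <- mFull
    seqs[k] <- paste(codons[apply(mFull, 2, which.max)], collapse = "")
  }
  names(post) <- names(seqs) <- labs
  list(sequences = seqs, posteriors = post)
}
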