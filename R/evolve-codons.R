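# Codon alignment simulator: GY94-type continuous-time substitution process
# over the 61 sense codons, with per-branch/per-site-class dN/dS and an
# optional positively selected foreground class. Because the state space
# excludes stop codons, simulated alignments never contain stops or gaps.

#' Specification of a codon evolution scenario
#'
#' @param tree a [LabeledTree-class] (foreground edges carry `foregroundOmega`
#'   for the positively selected class) or a plain `phylo` object.
#' @param kappa transition/transversion rate ratio.
#' @param siteClasses data.frame with columns `proportion` and `omega`
#'   describing the background site classes; proportions must sum to 1.
#' @param foregroundOmega dN/dS on foreground edges for the last site class
#'   (`NA` disables the branch-site structure: all classes behave the same on
#'   every edge).
#' @param codonFreqs equilibrium codon frequencies (61, summing to 1);
#'   default uniform.
#' @param nCodons alignment length in codons.
#' @param seed integer seed.
#' @return a list of class `EvolutionSpec`.
#' @export
evolutionSpec <- function(tree, kappa = 2,
                          siteClasses = data.frame(proportion = 1, omega = 1),
                          foregroundOmega = NA, codonFreqs = NULL,
                          nCodons = 300, seed = 1) {
  if (is(tree, "LabeledTree")) ltree <- tree
  else ltree <- labeledTree(tree)
  if (abs(sum(siteClasses$proportion) - 1) > 1e-8)
    stop("site-class proportions must sum to 1")
  if (any(siteClasses$omega < 0)) stop("omega must be >= 0")
  .codonTables()
  if (is.null(codonFreqs)) codonFreqs <- rep(1 / 61, 61)
  if (length(codonFreqs) != 61 || abs(sum(codonFreqs) - 1) > 1e-6)
    stop("codonFreqs must be a 61-vector summing to 1")
  structure(list(tree = ltree, kappa = kappa, siteClasses = siteClasses,
                 foregroundOmega = foregroundOmega, codonFreqs = codonFreqs,
                 nCodons = nCodons, seed = seed), class = "EvolutionSpec")
}

#' Simulate a codon alignment under a GY94 process
#'
#' Sites are assigned to classes by the spec proportions; each branch/class
#' transition matrix is the exact matrix exponential of the (scaled) GY94
#' generator, so sampling child codons from it is exact CTMC endpoint
#' sampling. Branch lengths are interpreted as expected substitutions per
#' codon under the class mixture.
#'
#' @param spec an [evolutionSpec()].
#' @return list with `alignment` (a [CodonAlignment-class]), `classLabels`
#'   (integer per site, the true class) and `spec`.
#' @export
evolveCodons <- function(spec) {
  stopifnot(inherits(spec, "EvolutionSpec"))
  set.seed(spec$seed)
  .codonTables()
  idx <- ape::reorder.phylo(treePhylo(spec$tree), "postorder",
                            index.only = TRUE)
  tr <- ape::reorder.phylo(treePhylo(spec$tree), "postorder")
  fg <- foregroundEdges(spec$tree)[idx]
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  nnode <- max(edge)
  pi <- spec$codonFreqs / sum(spec$codonFreqs)
  type <- .codonType()
  nC <- nrow(spec$siteClasses)
  S <- spec$nCodons

  # per-site class labels
  cls <- sample.int(nC, S, replace = TRUE, prob = spec$siteClasses$proportion)

  omegaFor <- function(class, isFg) {
    om <- spec$siteClasses$omega[class]
    if (isFg && !is.na(spec$foregroundOmega) && class == nC)
      om <- spec$foregroundOmega
    om
  }
  # scale so one unit of branch length = 1 expected substitution per codon
  # under the class mixture of that edge
  mu <- function(om) .rfMeanRate(type, pi, spec$kappa, om)
  scaleFor <- function(isFg) {
    oms <- vapply(seq_len(nC), function(c) omegaFor(c, isFg), numeric(1))
    sum(spec$siteClasses$proportion * vapply(oms, mu, numeric(1)))
  }
  scales <- c(`FALSE` = scaleFor(FALSE), `TRUE` = scaleFor(TRUE))

  states <- matrix(NA_integer_, nnode, S)
  root <- edge[nrow(edge), 1]
  states[root, ] <- sample.int(61, S, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    t <- tr$edge.length[e]
    sc <- scales[[as.character(fg[e])]]
    for (c in seq_len(nC)) {
      idx <- which(cls == c)
      if (!length(idx)) next
      om <- omegaFor(c, fg[e])
      if (t <= 0) { states[ch, idx] <- states[par, idx]; next }
      P <- .rfPmat(type, pi, spec$kappa, om, t / sc)
      parent <- states[par, idx]
      child <- integer(length(idx))
      for (p in unique(parent)) {
        sel <- parent == p
        child[sel] <- sample.int(61, sum(sel), replace = TRUE, prob = P[p, ])
      }
      states[ch, idx] <- child
    }
  }
  codons <- .codons()
  seqs <- vapply(seq_len(ntip), function(i)
    paste(codons[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  list(alignment = codonAlignment(seqs, clean = FALSE), classLabels = cls,
       spec = spec)
}
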