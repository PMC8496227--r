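# GY94 likelihood plumbing: F61 frequency estimation, site-pattern
# compression, and the R-side wrapper around the C++ pruning kernel.

#' F61 codon frequencies from an alignment
#'
#' Observed sense-codon frequencies across the whole alignment, floored at a
#' small value and renormalized so the reversible generator stays well
#' conditioned.
#'
#' @param aln a [CodonAlignment-class].
#' @param floor minimum frequency assigned to unobserved codons.
#' @return named numeric 61-vector summing to 1.
#' @export
codonFrequencies <- function(aln, floor = 1e-6) {
  .codonTables()
  m <- codonMatrix(aln)
  tab <- table(factor(m[m %in% .codons()], levels = .codons()))
  f <- as.numeric(tab) / sum(tab)
  f <- pmax(f, floor)
  f <- f / sum(f)
  names(f) <- .codons()
  f
}

# internal: compress an alignment into site patterns against a tree's tips
.codonData <- function(aln, tree) {
  .codonTables()
  m <- codonMatrix(aln)
  tips <- tree$tip.label
  if (!all(tips %in% rownames(m)))
    stop("alignment is missing taxa: ",
         paste(setdiff(tips, rownames(m)), collapse = ", "))
  m <- m[tips, , drop = FALSE]
  idx <- matrix(.rf$codonIndex[m], nrow = nrow(m))
  idx[is.na(idx)] <- 0L  # ambiguous/stop -> missing
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  patterns <- idx[, u, drop = FALSE] - 1L  # 0-based, -1 = missing
  weights <- as.numeric(table(key)[key[u]])
  list(patterns = patterns, weights = weights, nSites = ncol(idx),
       patternOf = match(key, key[u]))
}

# internal: postorder edge structure for the pruning kernel
.treeStructure <- function(tree, foreground = NULL) {
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  po <- ape::reorder.phylo(tree, "postorder")
  fg <- if (is.null(foreground)) rep(FALSE, nrow(po$edge)) else foreground[idx]
  list(edge = po$edge, ntip = length(po$tip.label),
       blen = po$edge.length, fg = fg)
}

#' GY94 log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense codons with per-branch (and
#' optionally per-site-class) dN/dS. Branch lengths are expected
#' substitutions per codon; each class generator is scaled by the
#' proportion-weighted mean rate so a shared branch length applies to all
#' classes.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree a `phylo` object with branch lengths (or a
#'   [LabeledTree-class]).
#' @param kappa transition/transversion ratio.
#' @param omega either a single value, a vector with one dN/dS per edge of
#'   `tree$edge`, or a list of site classes, each
#'   `list(proportion =, omega =)` where `omega` is scalar or per-edge.
#' @param codonFreqs 61-vector; default [codonFrequencies()] of `aln`.
#' @return the total log-likelihood, with attributes `siteLogLik` (per-site
#'   log-likelihoods, mixed over classes) and `classSiteLogLik`.
#' @export
gy94Loglik <- function(aln, tree, kappa, omega, codonFreqs = NULL) {
  if (is(tree, "LabeledTree")) tree <- treePhylo(tree)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(codonFreqs)) codonFreqs <- codonFrequencies(aln)
  st <- .treeStructure(tree)
  dat <- .codonData(aln, tree)
  E <- nrow(st$edge)
  if (!is.list(omega)) {
    omega <- if (length(omega) == 1L) rep(omega, E) else omega[
      ape::reorder.phylo(tree, "postorder", index.only = TRUE)]
    classes <- list(list(proportion = 1, omega = omega))
  } else {
    classes <- lapply(omega, function(cl) {
      om <- cl$omega
      om <- if (length(om) == 1L) rep(om, E) else om[
        ape::reorder.phylo(tree, "postorder", index.only = TRUE)]
      list(proportion = cl$proportion, omega = om)
    })
  }
  props <- vapply(classes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-8) stop("class proportions must sum to 1")
  omegaMat <- do.call(rbind, lapply(classes, `[[`, "omega"))
  .gy94Core(st, dat, kappa, omegaMat, props, codonFreqs)
}

# eigendecomposition cache: one environment per fit, keyed by (kappa, omega)
.eigenCache <- function() new.env(parent = emptyenv())

.getEigens <- function(cache, type, pi, kappa, omegas) {
  lapply(omegas, function(om) {
    key <- sprintf("%.17g|%.17g", kappa, om)
    e <- cache[[key]]
    if (is.null(e)) {
      if (length(ls(cache)) > 4000L) rm(list = ls(cache), envir = cache)
      e <- .rfCodonEigen(type, pi, kappa, om)
      cache[[key]] <- e
    }
    e
  })
}

# core evaluation shared by gy94Loglik and the fitters; omegaMat is C x E in
# postorder edge order, props the class proportions. scaling = "mixture"
# interprets branch lengths as expected substitutions per codon under the
# class mixture (the public convention); "neutral" divides all classes by
# the omega = 1 mean rate instead - the likelihood optimum is identical
# because branch lengths absorb the shared factor, but the scale no longer
# depends on the mixture weights, which the fitters exploit.
.gy94Core <- function(st, dat, kappa, omegaMat, props, pi, cache = NULL,
                      scaling = c("mixture", "neutral"), classOnly = FALSE) {
  scaling <- match.arg(scaling)
  type <- .codonType()
  E <- ncol(omegaMat)
  C <- nrow(omegaMat)
  if (is.null(cache)) cache <- .eigenCache()
  uom <- unique(as.numeric(omegaMat))
  if (scaling == "neutral" && !1 %in% uom) uom <- c(uom, 1)
  eig <- .getEigens(cache, type, pi, kappa, uom)
  idx <- matrix(match(as.numeric(omegaMat), uom), C, E)
  mus <- vapply(eig, `[[`, numeric(1), "mu")
  if (scaling == "mixture") {
    mu <- matrix(mus[idx], C, E)
    scale <- colSums(mu * props)
  } else {
    scale <- rep(mus[match(1, uom)], E)
  }
  teff <- matrix(rep(st$blen / scale, each = C), C, E)
  cs <- .rfClassSiteLoglikPre(st$edge, st$ntip, dat$patterns, teff, idx,
                              eig, pi)
  if (classOnly) return(cs)
  # mix classes in log space
  mx <- apply(cs, 2, max)
  siteLog <- mx + log(colSums(exp(sweep(cs, 2, mx)) * props))
  ll <- sum(siteLog * dat$weights)
  attr(ll, "siteLogLik") <- siteLog
  attr(ll, "classSiteLogLik") <- cs
  attr(ll, "weights") <- dat$weights
  ll
}
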