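# Maximum-likelihood codon-model fits: the free-ratio branch model (one
# dN/dS per branch) and branch-site Model A with its omega2 = 1 null, both
# optimized by bounded quasi-Newton with seeded multi-starts, plus the
# likelihood ratio test. Internals: eigendecompositions are cached across
# objective evaluations, generators are scaled by the neutral mean rate
# (branch lengths absorb the shared factor and are converted back to the
# mixture scale for reporting), and the Model A mixture weights are profiled
# out of the quasi-Newton search by an inner EM.

.LOGL_TOL <- 1e-8

.optimize <- function(par, fn, lower, upper, nStarts, seed, control) {
  set.seed(seed)
  starts <- list(par)
  if (nStarts > 1L) for (k in seq_len(nStarts - 1L))
    starts[[k + 1L]] <- pmin(pmax(par + rnorm(length(par), 0, 0.7), lower),
                             upper)
  best <- NULL
  msgs <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, fn, lower = lower, upper = upper,
             control = modifyList(list(rel.tol = .LOGL_TOL, iter.max = 500,
                                       eval.max = 2000), control)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    msgs <- c(msgs, fit$message)
    if (is.null(best) || fit$objective < best$objective - 1e-10) best <- fit
  }
  if (is.null(best)) stop("optimizer failed from every start")
  best$allMessages <- msgs
  best
}

#' Fit the free-ratio branch model
#'
#' Jointly optimizes kappa, all branch lengths and one dN/dS per branch
#' (bounded to `[1e-4, 99]`) under the GY94 model with F61 frequencies.
#' Branches estimated at (numerically) zero length carry no substitutions,
#' so their dN/dS is flagged unidentifiable.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree `phylo` or [LabeledTree-class]; topology is fixed, input
#'   branch lengths seed the optimizer.
#' @param codonFreqs 61-vector, default F61 from the alignment.
#' @param nStarts number of seeded multi-starts.
#' @param seed integer seed for the extra starts.
#' @param control extra `nlminb` control entries.
#' @return list of class `FreeRatioFit`: `omega` (per edge of `tree$edge`,
#'   NA where unidentifiable), `omegaFlag`, `branchLengths` (expected
#'   substitutions per codon), `kappa`, `logL`, `tree`, `convergence`.
#' @export
fitFreeRatio <- function(aln, tree, codonFreqs = NULL, nStarts = 5,
                         seed = 1, control = list()) {
  if (is(tree, "LabeledTree")) tree <- treePhylo(tree)
  if (length(tree$tip.label) < 2L) stop("need at least 2 taxa")
  if (is.null(codonFreqs)) codonFreqs <- codonFrequencies(aln)
  st <- .treeStructure(tree)
  dat <- .codonData(aln, tree)
  E <- nrow(st$edge)
  cache <- .eigenCache()
  b0 <- pmax(st$blen, 0.02)
  if (is.null(tree$edge.length) || all(st$blen == 0)) b0 <- rep(0.1, E)
  par <- c(log(2), log(b0), rep(log(0.5), E))
  lower <- c(log(0.1), rep(log(1e-6), E), rep(log(1e-4), E))
  upper <- c(log(99), rep(log(10), E), rep(log(99), E))
  negll <- function(p) {
    kappa <- exp(p[1])
    blen <- exp(p[2:(E + 1)])
    om <- exp(p[(E + 2):(2 * E + 1)])
    s <- st; s$blen <- blen
    -as.numeric(.gy94Core(s, dat, kappa, matrix(om, 1), 1, codonFreqs,
                          cache = cache, scaling = "neutral"))
  }
  best <- .optimize(par, negll, lower, upper, nStarts, seed, control)
  p <- best$par
  kappa <- exp(p[1])
  blenPo <- exp(p[2:(E + 1)])
  omPo <- exp(p[(E + 2):(2 * E + 1)])
  # internal branch lengths are on the neutral scale; convert to expected
  # substitutions per codon under each branch's own dN/dS
  type <- .codonType()
  muN <- .rfMeanRate(type, codonFreqs, kappa, 1)
  muB <- vapply(omPo, function(om) .rfMeanRate(type, codonFreqs, kappa, om),
                numeric(1))
  blenPo <- blenPo * muB / muN
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  blen <- omega <- numeric(E)
  blen[idx] <- blenPo
  omega[idx] <- omPo
  flag <- ifelse(blen < 1e-5, "unidentifiable", "ok")
  omega[flag != "ok"] <- NA_real_
  fitted <- tree
  fitted$edge.length <- blen
  structure(list(omega = omega, omegaFlag = flag, branchLengths = blen,
                 kappa = kappa, logL = -best$objective, tree = fitted,
                 codonFreqs = codonFreqs,
                 convergence = list(code = best$convergence,
                                    message = best$message,
                                    iterations = best$iterations,
                                    starts = length(best$allMessages))),
            class = "FreeRatioFit")
}

#' @export
print.FreeRatioFit <- function(x, ...) {
  cat(sprintf("FreeRatioFit: logL = %.2f, kappa = %.2f\n", x$logL, x$kappa))
  om <- ifelse(is.na(x$omega), "--", sprintf("%.3f", x$omega))
  cat("  per-branch omega:", paste(om, collapse = " "), "\n")
  invisible(x)
}

# Model A class structure: classes (0, 1, 2a, 2b); on background branches
# 2a/2b evolve under omega0/1, on foreground branches both under omega2.
.modelAOmegaMat <- function(w0, w2, fg) {
  rbind(rep(w0, length(fg)), rep(1, length(fg)),
        ifelse(fg, w2, w0), ifelse(fg, w2, 1))
}

.modelAProps <- function(q, r) c(q * r, q * (1 - r), (1 - q) * r,
                                 (1 - q) * (1 - r))

# Profile maximization of the Model A mixture weights (q = p0 + p1,
# r = p0/(p0 + p1)) given the 4 x patterns class site log-likelihood matrix.
# Exact profiling is possible because the class likelihoods do not depend on
# the weights under neutral scaling. The 2-d problem is solved by bounded
# quasi-Newton from several fixed starts; the surface has a known ridge at
# q -> 1 (no positively selected sites) that a single start can get lost on.
.mixProfile <- function(cs, w, starts = rbind(c(0.85, 0.5), c(0.6, 0.5),
                                              c(0.97, 0.5))) {
  .rfMixProfile(cs, w, starts)
}

#' Fit branch-site Model A (or its null)
#'
#' Standard branch-site Model A: four site classes (0, 1, 2a, 2b) with
#' 0 <= omega0 <= 1, omega1 = 1 and, on the labeled foreground branches, a
#' positively selected ratio omega2 >= 1 shared by classes 2a/2b. The null
#' model fixes omega2 = 1. Kappa, branch lengths and the class mixture are
#' re-optimized for each model. The reported `p2plus3` is the combined
#' proportion of classes 2a and 2b.
#'
#' @param aln a [CodonAlignment-class].
#' @param ltree a [LabeledTree-class] with at least one foreground edge.
#' @param null fit the omega2 = 1 null instead of the alternative.
#' @param codonFreqs 61-vector, default F61 from the alignment.
#' @param nStarts seeded multi-starts.
#' @param seed integer seed.
#' @param init optional `BranchSiteFit` used to warm-start the optimizer
#'   (typically the null fit when fitting the alternative).
#' @param control extra `nlminb` control entries.
#' @return a [BranchSiteFit-class].
#' @export
fitBranchSite <- function(aln, ltree, null = FALSE, codonFreqs = NULL,
                          nStarts = 3, seed = 1, init = NULL,
                          control = list()) {
  stopifnot(is(ltree, "LabeledTree"))
  tree <- treePhylo(ltree)
  if (!any(foregroundEdges(ltree))) stop("no foreground branch labeled")
  if (is.null(codonFreqs)) codonFreqs <- codonFrequencies(aln)
  st <- .treeStructure(tree, foregroundEdges(ltree))
  dat <- .codonData(aln, tree)
  E <- nrow(st$edge)
  cache <- .eigenCache()
  b0 <- pmax(st$blen, 0.02)
  if (is.null(tree$edge.length) || all(st$blen == 0)) b0 <- rep(0.1, E)

  # outer parameters: log kappa, log blens, qlogis(w0), and for the
  # alternative log(w2 - 1); the mixture (q, r) is profiled out by EM
  par <- c(log(2), log(b0), qlogis(0.3))
  if (!null) par <- c(par, log(1.5))
  if (!is.null(init)) {
    par[1] <- log(min(max(init@kappa, 0.11), 98))
    par[2:(E + 1)] <- log(pmin(pmax(init@details$blenNeutral, 1e-6), 10))
    par[E + 2] <- qlogis(min(max(init@omega0, 1e-4), 1 - 1e-4))
    # never start the alternative on the omega2 = 1 ridge
    if (!null) par[E + 3] <- log(max(init@omega2 - 1, 1.5))
  }
  lower <- c(log(0.1), rep(log(1e-6), E), qlogis(1e-4))
  upper <- c(log(99), rep(log(10), E), qlogis(1 - 1e-4))
  if (!null) { lower <- c(lower, log(1e-4)); upper <- c(upper, log(98)) }


  evalModel <- function(p) {
    kappa <- exp(p[1])
    blen <- exp(p[2:(E + 1)])
    w0 <- plogis(p[E + 2])
    w2 <- if (null) 1 else 1 + exp(p[E + 3])
    s <- st; s$blen <- blen
    cs <- .gy94Core(s, dat, kappa, .modelAOmegaMat(w0, w2, st$fg),
                    rep(0.25, 4), codonFreqs, cache = cache,
                    scaling = "neutral", classOnly = TRUE)
    em <- .mixProfile(cs, dat$weights)
    list(logL = em$logL, q = em$q, r = em$r, cs = cs,
         kappa = kappa, blen = blen, w0 = w0, w2 = w2)
  }
  negll <- function(p) -evalModel(p)$logL
  starts <- list(par)
  if (!null && nStarts >= 2) {
    # a deterministic high-omega2 start guards against the w2 = 1 ridge
    p2 <- par; p2[E + 3] <- log(7)
    starts <- c(starts, list(p2))
  }
  best <- NULL
  for (sp in starts) {
    fit <- .optimize(sp, negll, lower, upper,
                     max(1L, nStarts - length(starts) + 1L), seed, control)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!null && !is.null(init)) {
    # the nested floor: the alternative can never fall below the null's own
    # optimum, which it contains in the omega2 -> 1 limit
    par0 <- c(log(min(max(init@kappa, 0.11), 98)),
              log(pmin(pmax(init@details$blenNeutral, 1e-6), 10)),
              qlogis(min(max(init@omega0, 1e-4), 1 - 1e-4)), log(1e-8))
    v0 <- negll(par0)
    if (v0 < best$objective) {
      best$par <- par0
      best$objective <- v0
      best$message <- paste(best$message, "(null-limit candidate used)")
    }
  }
  fin <- evalModel(best$par)
  props <- .modelAProps(fin$q, fin$r)
  # convert neutral-scale branch lengths to the mixture scale for reporting
  type <- .codonType()
  muN <- .rfMeanRate(type, codonFreqs, fin$kappa, 1)
  muOf <- function(om) .rfMeanRate(type, codonFreqs, fin$kappa, om)
  omegaMat <- .modelAOmegaMat(fin$w0, fin$w2, st$fg)
  mus <- matrix(vapply(as.numeric(omegaMat), muOf, numeric(1)), 4, E)
  blenMix <- fin$blen * colSums(mus * props) / muN
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  blen <- numeric(E); blen[idx] <- blenMix
  fitted <- tree; fitted$edge.length <- blen
  new("BranchSiteFit",
      model = if (null) "ModelA_null" else "ModelA",
      p0 = props[1], p1 = props[2], p2plus3 = props[3] + props[4],
      omega0 = fin$w0, omega1 = 1, omega2 = fin$w2, kappa = fin$kappa,
      logL = fin$logL, tree = fitted,
      convergence = list(code = best$convergence, message = best$message,
                         iterations = best$iterations,
                         starts = length(best$allMessages)),
      details = list(classSiteLogLik = fin$cs, patternOf = dat$patternOf,
                     props = props, blenNeutral = fin$blen, ltree = ltree,
                     codonFreqs = codonFreqs))
}

#' Fit the branch-site test (Model A vs its null) end to end
#'
#' Fits the null, warm-starts the alternative from it, then refits the null
#' warm-started from the alternative and keeps the better null optimum.
#' The final polish matters for the test's calibration: without it the
#' alternative can look better than the null merely because it continued
#' optimizing the shared parameters (branch lengths, kappa) from the
#' null's stopping point.
#'
#' @param aln a [CodonAlignment-class].
#' @param ltree a [LabeledTree-class] with foreground edges.
#' @param codonFreqs 61-vector, default F61 from the alignment.
#' @param nStarts multi-starts for the alternative fit.
#' @param seed integer seed.
#' @param control extra `nlminb` control entries.
#' @return list with `null`, `alt` (both [BranchSiteFit-class]) and `lrt`
#'   (an [LRTResult-class]).
#' @export
branchSiteTest <- function(aln, ltree, codonFreqs = NULL, nStarts = 2,
                           seed = 1, control = list()) {
  null <- fitBranchSite(aln, ltree, null = TRUE, codonFreqs = codonFreqs,
                        nStarts = 1, seed = seed, control = control)
  alt <- fitBranchSite(aln, ltree, null = FALSE, codonFreqs = codonFreqs,
                       nStarts = nStarts, seed = seed, init = null,
                       control = control)
  null2 <- fitBranchSite(aln, ltree, null = TRUE, codonFreqs = codonFreqs,
                         nStarts = 1, seed = seed, init = alt,
                         control = control)
  if (fitLogL(null2) > fitLogL(null)) null <- null2
  if (fitLogL(alt) < fitLogL(null)) {
    # the polished null overtook the alternative; refit the alternative
    # from it (the alternative contains the null at omega2 = 1)
    alt2 <- fitBranchSite(aln, ltree, null = FALSE,
                          codonFreqs = codonFreqs, nStarts = 1,
                          seed = seed, init = null, control = control)
    if (fitLogL(alt2) > fitLogL(alt)) alt <- alt2
  }
  list(null = null, alt = alt,
       lrt = suppressWarnings(lrt(null, alt)))
}

#' Likelihood ratio test of nested codon models
#'
#' `2 * (logL_alt - logL_null)` against the upper tail of the chi-square
#' distribution. Small negative statistics (optimizer noise, within `1e-4`)
#' are clamped to zero with a warning; larger ones are an error.
#'
#' @param logLNull,logLAlt log-likelihoods of the nested fits (numbers or
#'   fit objects with a `logL`).
#' @param df degrees of freedom (>= 1).
#' @return an [LRTResult-class].
#' @export
lrt <- function(logLNull, logLAlt, df = 1) {
  getLL <- function(x) {
    if (is(x, "BranchSiteFit")) return(x@logL)
    if (is.list(x) && !is.null(x$logL)) return(x$logL)
    as.numeric(x)
  }
  ln <- getLL(logLNull); la <- getLL(logLAlt)
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (la - ln)
  if (stat < -1e-4)
    stop("alternative log-likelihood below null beyond tolerance ",
         "(optimizer failure): 2dl = ", signif(stat, 4))
  if (stat < 0) {
    warning("negative 2*deltaL within tolerance clamped to 0")
    stat <- 0
  }
  new("LRTResult", twoDeltaL = stat, df = df,
      pValue = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Empirical-Bayes site posteriors for the positively selected class
#'
#' Naive empirical Bayes: the fitted parameters are plugged in and the
#' posterior probability that each site belongs to the foreground positively
#' selected classes (2a + 2b) is computed from the class site likelihoods.
#'
#' @param fit a [BranchSiteFit-class] for Model A (not the null).
#' @param threshold sites with posterior above this are flagged.
#' @return data.frame with `site`, `posterior`, `flagged`.
#' @export
sitePosteriors <- function(fit, threshold = 0.5) {
  stopifnot(is(fit, "BranchSiteFit"))
  if (fit@model != "ModelA")
    stop("site posteriors are defined for the Model A fit, not the null")
  cs <- fit@details$classSiteLogLik
  props <- fit@details$props
  mx <- apply(cs, 2, max)
  lik <- exp(sweep(cs, 2, mx)) * props
  post <- colSums(lik[3:4, , drop = FALSE]) / colSums(lik)
  post <- post[fit@details$patternOf]
  data.frame(site = seq_along(post), posterior = post,
             flagged = post > threshold)
}
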