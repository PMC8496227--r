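# Monte-Carlo neutral null for pairwise dN/dS: place a fixed number of
# substitutions on a template coding sequence uniformly at random (with
# transition/transversion weighting, ignoring synonymous/nonsynonymous
# status), recompute NG86 dN/dS against the template, and derive an
# upper-tail p-value for an observed pair.

#' Configuration for the neutral null
#'
#' @param templateSeq in-frame codon template (character, no stops).
#' @param K total substitutions to place per replicate (`K = 0` is allowed
#'   as a degenerate testing mode and yields an undefined omega).
#' @param tsTv transition/transversion ratio used to weight substitutions.
#' @param nReps number of null replicates (>= 100).
#' @param seed integer seed.
#' @return list of class `NeutralNullConfig`.
#' @export
neutralNullConfig <- function(templateSeq, K, tsTv = 2, nReps = 10000,
                              seed = 1) {
  if (K < 0) stop("K must be >= 0")
  if (nReps < 100) stop("nReps must be >= 100")
  if (tsTv <= 0) stop("tsTv must be > 0")
  if (nchar(templateSeq) %% 3L != 0L) stop("template must be in frame")
  structure(list(templateSeq = toupper(templateSeq), K = as.integer(K),
                 tsTv = tsTv, nReps = as.integer(nReps),
                 seed = as.integer(seed)), class = "NeutralNullConfig")
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# place K neutral substitutions on the template; substitutions that create a
# stop codon are resampled so K is exact; returns the mutated characters and
# the (1-based) indices of the codons touched
.neutralMutate <- function(chars, K, tsTv) {
  n <- length(chars)
  placed <- 0L
  changed <- integer(0)
  pTs <- tsTv / (tsTv + 2)  # two transversions share the rest
  gc <- Biostrings::GENETIC_CODE
  while (placed < K) {
    pos <- sample.int(n, 1)
    old <- chars[pos]
    new <- if (runif(1) < pTs) .TRANSITION[[old]] else
      sample(setdiff(c("A", "C", "G", "T"), c(old, .TRANSITION[[old]])), 1)
    cod <- (pos - 1L) %/% 3L
    codon <- chars[(cod * 3L + 1L):(cod * 3L + 3L)]
    codon[(pos - 1L) %% 3L + 1L] <- new
    if (gc[[paste(codon, collapse = "")]] == "*") next
    chars[pos] <- new
    changed <- c(changed, cod + 1L)
    placed <- placed + 1L
  }
  list(chars = chars, changed = unique(changed))
}

# fast NG86 omega of a mutated copy against a precomputed template: only the
# touched codons are revisited
.templateInfo <- function(templateSeq) {
  .codonTables()
  cods <- .splitCodons(templateSeq)
  s <- .rf$sSites[cods]
  list(codons = cods, sPerCodon = s, Stot = sum(s), n = length(cods))
}

.fastOmega <- function(info, chars, changed) {
  if (length(changed) == 0L)
    return(list(omega = NA_real_, defined = FALSE, Nd = 0, Sd = 0))
  mutCods <- vapply(changed, function(cd)
    paste(chars[(cd * 3L - 2L):(cd * 3L)], collapse = ""), character(1))
  Smut <- info$Stot - sum(info$sPerCodon[changed]) + sum(.rf$sSites[mutCods])
  S <- (info$Stot + Smut) / 2
  N <- 3 * info$n - S
  d <- vapply(seq_along(changed), function(i)
    .pairDiffs(info$codons[changed[i]], mutCods[i]), numeric(2))
  Nd <- sum(d["nd", ]); Sd <- sum(d["sd", ])
  pN <- Nd / N; pS <- Sd / S
  if (pS >= 0.75 || pN >= 0.75 || Sd == 0)
    return(list(omega = NA_real_, defined = FALSE, Nd = Nd, Sd = Sd))
  dN <- -0.75 * log(1 - 4 * pN / 3)
  dS <- -0.75 * log(1 - 4 * pS / 3)
  list(omega = dN / dS, defined = TRUE, Nd = Nd, Sd = Sd)
}

#' One neutral null draw of pairwise dN/dS
#'
#' @param config a [neutralNullConfig()]; its seed is used as-is, so call
#'   sites wanting independent draws should vary it.
#' @return the `Ng86Result` of the mutated copy against the template.
#' @export
simulateNeutralPair <- function(config) {
  stopifnot(inherits(config, "NeutralNullConfig"))
  set.seed(config$seed)
  chars <- strsplit(config$templateSeq, "")[[1]]
  mut <- .neutralMutate(chars, config$K, config$tsTv)
  ng86(config$templateSeq, paste(mut$chars, collapse = ""))
}

#' Monte-Carlo p-value against the neutral null
#'
#' Draws `nReps` neutral replicates (K substitutions each), computes NG86
#' dN/dS for each against the template, and reports the continuity-corrected
#' upper-tail p-value `(1 + #(null >= observed)) / (nReps + 1)`. Null draws
#' with undefined dN/dS (no synonymous changes) are counted as >= observed,
#' keeping the p-value conservative.
#'
#' @param observed either an `Ng86Result` for the observed pair or a
#'   length-2 character vector of sequences.
#' @param config a [neutralNullConfig()]; defaults for `K` and `tsTv` are
#'   taken from the observed pair when constructed by the caller.
#' @return a [NeutralNullResult-class].
#' @export
mcPvalue <- function(observed, config) {
  if (is.character(observed)) observed <- ng86(observed[1], observed[2])
  if (!observed$omegaDefined)
    stop("observed omega undefined (dS = 0); nothing to test")
  stopifnot(inherits(config, "NeutralNullConfig"))
  set.seed(config$seed)
  chars <- strsplit(config$templateSeq, "")[[1]]
  info <- .templateInfo(config$templateSeq)
  draws <- numeric(config$nReps)
  for (i in seq_len(config$nReps)) {
    mut <- .neutralMutate(chars, config$K, config$tsTv)
    r <- .fastOmega(info, mut$chars, mut$changed)
    draws[i] <- if (r$defined) r$omega else Inf
  }
  r <- sum(draws >= observed$omega)
  p <- (1 + r) / (config$nReps + 1)
  new("NeutralNullResult", observedOmega = observed$omega,
      nullSamples = draws, pValue = p,
      quantiles = quantile(draws[is.finite(draws)],
                           c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
}
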