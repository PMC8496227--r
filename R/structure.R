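# Interface partition and free-energy classification of substitutions:
# minimum atom-atom distance to the partner chain, the strict-cutoff
# classifier (far / fold-perturbed / binding-disruptive / functional), and
# per-group summaries.

#' Minimum distance from a residue to a partner chain
#'
#' Minimum Euclidean distance over all atom pairs between residue `site` of
#' chain A and every atom of chain B, using all atoms present in the
#' coordinate file.
#'
#' @param site residue number on chain A.
#' @param chainA,chainB coordinate data.frames from [readCoords()].
#' @return distance in Angstrom, or `NA` with attribute
#'   `reason = "missing"` when the residue is unresolved in the structure.
#' @export
minDistanceToChain <- function(site, chainA, chainB) {
  a <- chainA[chainA$resno == site, c("x", "y", "z"), drop = FALSE]
  if (nrow(a) == 0L) {
    warning("residue ", site, " absent from chain A (unresolved); ",
            "excluded from the interface partition")
    return(structure(NA_real_, reason = "missing"))
  }
  b <- as.matrix(chainB[, c("x", "y", "z")])
  a <- as.matrix(a)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Classify a substitution by distance and free-energy change
#'
#' The classifier is total: residues more than `distCutoff` from the partner
#' chain are `far_from_interface`; interface residues with a folding
#' free-energy change outside the open band are `fold_perturbed`; those with
#' a binding free-energy change above `bindCutoff` are
#' `binding_disruptive`; everything else is `functional`. All cutoffs are
#' strict inequalities, so boundary values fall in the permissive class.
#'
#' @param ddgBind binding free-energy change, kcal/mol.
#' @param ddgFold folding free-energy change, kcal/mol.
#' @param minDist distance to the partner chain, Angstrom (`NA` = missing
#'   residue, classified `NA`).
#' @param distCutoff interface distance cutoff (Angstrom).
#' @param bindCutoff binding disruption cutoff (kcal/mol).
#' @param foldBand open interval of tolerated folding changes (kcal/mol).
#' @return factor with levels `functional`, `binding_disruptive`,
#'   `fold_perturbed`, `far_from_interface`.
#' @export
classifyMutation <- function(ddgBind, ddgFold, minDist, distCutoff = 5,
                             bindCutoff = 2, foldBand = c(-3, 3)) {
  lev <- c("functional", "binding_disruptive", "fold_perturbed",
           "far_from_interface")
  n <- max(length(ddgBind), length(ddgFold), length(minDist))
  ddgBind <- rep_len(ddgBind, n)
  ddgFold <- rep_len(ddgFold, n)
  minDist <- rep_len(minDist, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is.na(minDist[i])) NA_character_
    else if (minDist[i] > distCutoff) "far_from_interface"
    else if (ddgFold[i] <= foldBand[1] || ddgFold[i] >= foldBand[2])
      "fold_perturbed"
    else if (ddgBind[i] > bindCutoff) "binding_disruptive"
    else "functional"
  }
  factor(out, levels = lev)
}

#' Classify a table of substitutions against a structure
#'
#' Computes the minimum distance to the partner chain for every row of a
#' free-energy table and applies [classifyMutation()].
#'
#' @param ddg data.frame from [readDdgTable()].
#' @param chainA,chainB coordinate data.frames from [readCoords()].
#' @param ... cutoffs passed to [classifyMutation()].
#' @return the input with `min_dist` and `class` columns appended; rows for
#'   unresolved residues carry `NA` in both.
#' @export
classifyDdgTable <- function(ddg, chainA, chainB, ...) {
  ddg$min_dist <- vapply(ddg$site, function(s)
    suppressWarnings(as.numeric(minDistanceToChain(s, chainA, chainB))),
    numeric(1))
  ddg$class <- classifyMutation(ddg$ddg_bind, ddg$ddg_fold, ddg$min_dist, ...)
  ddg
}

#' Per-group mean and standard deviation of free-energy changes
#'
#' @param ddg a classified table ([classifyDdgTable()] output, or any
#'   data.frame with `ddg_bind`, `ddg_fold` and a grouping column).
#' @param by name of the grouping column.
#' @param out optional TSV path.
#' @return data.frame with group, `n`, means and sample SDs (n-1
#'   denominator; singleton groups report SD 0 with `singleton = TRUE`).
#' @export
summarizeDdg <- function(ddg, by = "class", out = NULL) {
  grp <- ddg[[by]]
  keep <- !is.na(grp)
  ddg <- ddg[keep, , drop = FALSE]
  grp <- droplevels(factor(grp[keep]))
  rows <- lapply(levels(grp), function(g) {
    d <- ddg[grp == g, , drop = FALSE]
    singleton <- nrow(d) == 1L
    data.frame(group = g, n = nrow(d),
               mean_ddg_bind = mean(d$ddg_bind),
               sd_ddg_bind = if (singleton) 0 else sd(d$ddg_bind),
               mean_ddg_fold = mean(d$ddg_fold),
               sd_ddg_fold = if (singleton) 0 else sd(d$ddg_fold),
               singleton = singleton, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out))
    write.table(res, out, sep = "\t", row.names = FALSE, quote = FALSE)
  res
}
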