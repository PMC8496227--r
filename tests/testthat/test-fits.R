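# Model fitting: free-ratio parameter recovery, the branch-site nested
# likelihood invariant, LRT arithmetic, and empirical-Bayes site posteriors.

test_that("free-ratio recovers a shared omega and branch lengths", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.3,C:0.25);")
  ev <- evolveCodons(evolutionSpec(
    tr, kappa = 2.5, siteClasses = data.frame(proportion = 1, omega = 0.5),
    nCodons = 1500, seed = 13))
  fit <- fitFreeRatio(ev$alignment, tr, nStarts = 1,
                      control = list(rel.tol = 1e-7))
  expect_true(all(abs(fit$omega - 0.5) < 0.2))
  expect_true(all(abs(fit$branchLengths - tr$edge.length) < 0.08))
  expect_gt(fit$kappa, 1.8)
  expect_lt(fit$kappa, 3.3)
})

test_that("identical sequences collapse branch lengths and flag omega", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  aln <- codonAlignment(c(A = strrep("ATGAAACCG", 20),
                          B = strrep("ATGAAACCG", 20),
                          C = strrep("ATGAAACCG", 20)), clean = FALSE)
  fit <- fitFreeRatio(aln, tr, nStarts = 1)
  expect_true(all(fit$branchLengths < 1e-4))
  expect_true(all(fit$omegaFlag == "unidentifiable"))
  expect_true(all(is.na(fit$omega)))
})

test_that("Model A always dominates its null (nested likelihoods)", {
  tr <- ape::read.tree(text = "((fg1:0.25,fg2:0.25):0.25,bg1:0.35,bg2:0.35);")
  fgTips <- which(tr$tip.label %in% c("fg1", "fg2"))
  lt <- labeledTree(tr, tr$edge[, 2] %in%
                      c(fgTips, ape::getMRCA(tr, fgTips)))
  for (s in c(3, 11)) {
    ev <- evolveCodons(evolutionSpec(
      lt, kappa = 2,
      siteClasses = data.frame(proportion = c(0.45, 0.45, 0.1),
                               omega = c(0.1, 1, 1)),
      foregroundOmega = if (s == 3) 5 else 1, nCodons = 200, seed = s))
    null <- fitBranchSite(ev$alignment, lt, null = TRUE, nStarts = 1,
                          seed = 1, control = list(rel.tol = 1e-6))
    alt <- fitBranchSite(ev$alignment, lt, null = FALSE, nStarts = 2,
                         seed = 1, init = null,
                         control = list(rel.tol = 1e-6))
    expect_gte(fitLogL(alt), fitLogL(null) - 1e-4)
    expect_identical(alt@omega1, 1)
    expect_identical(null@omega2, 1)
    p <- fitParams(alt)
    expect_equal(unname(p["p0"] + p["p1"] + p["p2plus3"]), 1,
                 tolerance = 1e-6)
  }
})

test_that("branch-site recovers strong foreground selection", {
  tr <- ape::read.tree(text = "((fg1:0.25,fg2:0.25):0.25,bg1:0.35,bg2:0.35);")
  fgTips <- which(tr$tip.label %in% c("fg1", "fg2"))
  lt <- labeledTree(tr, tr$edge[, 2] %in%
                      c(fgTips, ape::getMRCA(tr, fgTips)))
  ev <- evolveCodons(evolutionSpec(
    lt, kappa = 2,
    siteClasses = data.frame(proportion = c(0.45, 0.45, 0.1),
                             omega = c(0.1, 1, 1)),
    foregroundOmega = 8, nCodons = 400, seed = 21))
  null <- fitBranchSite(ev$alignment, lt, null = TRUE, nStarts = 1,
                        seed = 1, control = list(rel.tol = 1e-6))
  alt <- fitBranchSite(ev$alignment, lt, null = FALSE, nStarts = 2,
                       seed = 1, init = null,
                       control = list(rel.tol = 1e-6))
  expect_gt(alt@omega2, 2)
  expect_lt(suppressWarnings(lrt(null, alt)@pValue), 0.05)
})

test_that("the LRT reproduces chi-square arithmetic and guards nesting", {
  expect_equal(round(lrt(0, 4.75 / 2)@pValue, 3), 0.029)
  expect_equal(round(lrt(0, 2.29 / 2)@pValue, 3), 0.130)
  expect_identical(lrt(-100, -100)@pValue, 1)
  expect_error(lrt(-99, -100), "optimizer failure")
  expect_warning(lrt(-100, -100 - 1e-5), "clamped")
  expect_error(lrt(0, 1, df = 0), "df")
})

test_that("site posteriors are probabilities that vanish without signal", {
  tr <- ape::read.tree(text = "((fg1:0.25,fg2:0.25):0.25,bg1:0.35,bg2:0.35);")
  fgTips <- which(tr$tip.label %in% c("fg1", "fg2"))
  lt <- labeledTree(tr, tr$edge[, 2] %in%
                      c(fgTips, ape::getMRCA(tr, fgTips)))
  ev <- evolveCodons(evolutionSpec(
    lt, kappa = 2,
    siteClasses = data.frame(proportion = c(0.45, 0.45, 0.1),
                             omega = c(0.1, 1, 1)),
    foregroundOmega = 8, nCodons = 300, seed = 5))
  null <- fitBranchSite(ev$alignment, lt, null = TRUE, nStarts = 1,
                        seed = 1, control = list(rel.tol = 1e-6))
  alt <- fitBranchSite(ev$alignment, lt, null = FALSE, nStarts = 2,
                       seed = 1, init = null,
                       control = list(rel.tol = 1e-6))
  post <- sitePosteriors(alt)
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
  expect_identical(nrow(post), nCodons(ev$alignment))
  # flagged sites are enriched for the truly selected class
  sel <- ev$classLabels == 3
  expect_gt(mean(post$posterior[sel]), mean(post$posterior[!sel]))
  auc <- mean(outer(post$posterior[sel], post$posterior[!sel], ">") +
                0.5 * outer(post$posterior[sel], post$posterior[!sel], "=="))
  expect_gt(auc, 0.7)
  expect_error(sitePosteriors(null), "null")
})
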