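# GY94 pruning likelihood: closed forms, exhaustive ancestral-state oracles
# on toy trees, reversibility under re-rooting, and input validation.

test_that("zero branch lengths give the closed-form stationary likelihood", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln <- codonAlignment(c(A = "ATGAAA", B = "ATGAAA"), clean = FALSE)
  pi <- rep(1 / 61, 61)
  ll <- gy94Loglik(aln, tr, kappa = 2, omega = 0.5, codonFreqs = pi)
  expect_equal(as.numeric(ll), 2 * log(1 / 61), tolerance = 1e-9)
})

test_that("pruning equals the exhaustive-state oracle on toy trees", {
  pi <- rep(1 / 61, 61)
  cases <- list(
    list(tree = "(A:0.3,B:0.2);", n = 5, omega = 1),
    list(tree = "((A:0.2,B:0.3):0.1,C:0.25);", n = 4, omega = 0.4),
    list(tree = "((A:0.2,B:0.3):0.1,(C:0.25,D:0.15):0.2);", n = 3,
         omega = 2))
  for (cs in cases) {
    tr <- ape::read.tree(text = cs$tree)
    ev <- evolveCodons(evolutionSpec(
      tr, kappa = 2.2, siteClasses = data.frame(proportion = 1,
                                                omega = cs$omega),
      nCodons = cs$n, seed = 7))
    mine <- gy94Loglik(ev$alignment, tr, kappa = 2.2, omega = cs$omega,
                       codonFreqs = pi)
    oracle <- exhaustiveLoglik(ev$alignment, tr, 2.2, cs$omega, pi)
    expect_equal(as.numeric(mine), oracle, tolerance = 1e-8,
                 label = cs$tree)
  }
})

test_that("the likelihood is invariant to re-rooting (reversibility)", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.25,D:0.15):0.2);")
  ev <- evolveCodons(evolutionSpec(tr, kappa = 2, nCodons = 40, seed = 9))
  pi <- rep(1 / 61, 61)
  ll1 <- as.numeric(gy94Loglik(ev$alignment, tr, 2, 0.7, codonFreqs = pi))
  rerooted <- ape::root(tr, outgroup = "C", resolve.root = FALSE)
  ll2 <- as.numeric(gy94Loglik(ev$alignment, rerooted, 2, 0.7,
                               codonFreqs = pi))
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("negative branch lengths are rejected", {
  tr <- ape::read.tree(text = "(A:0.1,B:-0.1);")
  aln <- codonAlignment(c(A = "ATGAAA", B = "ATGAAA"), clean = FALSE)
  expect_error(gy94Loglik(aln, tr, 2, 1), "negative")
})

test_that("F61 frequencies sum to 1 and reflect observed usage", {
  aln <- codonAlignment(c(A = "ATGATGAAA", B = "ATGATGAAA"), clean = FALSE)
  f <- codonFrequencies(aln)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_gt(f[["ATG"]], f[["AAA"]])
  expect_lt(f[["TTT"]], 1e-4)  # unobserved, floored
})

test_that("cleaning removes gap and ambiguity columns with a count", {
  aln <- codonAlignment(c(A = "ATG---AAA", B = "ATGCCGANA"))
  expect_identical(nCodons(aln), 1L)
  expect_identical(aln@removedColumns, 2L)
})

test_that("marginal ancestral reconstruction matches enumeration", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.3,C:0.25);")
  ev <- evolveCodons(evolutionSpec(
    tr, kappa = 2, siteClasses = data.frame(proportion = 1, omega = 0.6),
    nCodons = 4, seed = 9))
  pi <- rep(1 / 61, 61)
  fit <- list(tree = tr, kappa = 2, omega = 0.6, codonFreqs = pi)
  anc <- ancestralReconstruct(ev$alignment, fit)
  # oracle: enumerate the root state directly
  type <- retroforge:::.codonType()
  ci <- retroforge:::.rf$codonIndex
  mu <- retroforge:::.rfMeanRate(type, pi, 2, 0.6)
  P <- lapply(tr$edge.length, function(t)
    retroforge:::.rfPmat(type, pi, 2, 0.6, t / mu))
  m <- codonMatrix(ev$alignment)
  for (s in 1:4) {
    v <- pi * P[[1]][, ci[[m["A", s]]]] * P[[2]][, ci[[m["B", s]]]] *
      P[[3]][, ci[[m["C", s]]]]
    expect_equal(anc$posteriors[[1]][, s], v / sum(v), tolerance = 1e-10)
    expect_equal(sum(anc$posteriors[[1]][, s]), 1, tolerance = 1e-12)
  }
})

test_that("identical leaves reconstruct to the same sequence", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  seqs <- c(A = "ATGCCGAAA", B = "ATGCCGAAA", C = "ATGCCGAAA")
  aln <- codonAlignment(seqs, clean = FALSE)
  fit <- list(tree = tr, kappa = 2, omega = 1,
              codonFreqs = rep(1 / 61, 61))
  anc <- ancestralReconstruct(aln, fit)
  expect_identical(unname(anc$sequences[1]), "ATGCCGAAA")
})
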