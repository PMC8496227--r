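# NG86 counting: frozen single-codon examples, brute-force path-enumeration
# oracles for multi-difference codons, and the site-count invariant.

test_that("frozen examples: identical pair and TTT/TTC", {
  r0 <- ng86("ATGATG", "ATGATG")
  expect_identical(r0$Nd, 0)
  expect_identical(r0$Sd, 0)
  expect_identical(r0$dN, 0)
  expect_identical(r0$dS, 0)

  r <- ng86("TTT", "TTC")
  expect_identical(r$Nd, 0)
  expect_identical(r$Sd, 1)
  # TTT has 1/3 synonymous sites (only the third-position T->C change is
  # synonymous) and 8/3 nonsynonymous
  expect_equal(r$S, 1 / 3, tolerance = 1e-12)
  expect_equal(r$N, 8 / 3, tolerance = 1e-12)
})

test_that("multi-difference codons match the path-enumeration oracle", {
  pairs <- list(c("AAA", "AGG"), c("TTT", "GAT"), c("ATG", "CCG"),
                c("TGG", "AGA"), c("CCC", "GGG"))
  for (p in pairs) {
    mine <- retroforge:::.pairDiffs(p[1], p[2])
    oracle <- pairOracle(p[1], p[2])
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-12,
                 label = paste(p, collapse = "->"))
  }
})

test_that("a 2-codon pair differing at 2 positions averages both orderings", {
  r <- ng86("ATGAAA", "ATGAGG")
  oracle <- pairOracle("AAA", "AGG")
  expect_equal(r$Nd, unname(oracle["nd"]), tolerance = 1e-12)
  expect_equal(r$Sd, unname(oracle["sd"]), tolerance = 1e-12)
})

test_that("site counts conserve N + S = 3 x nCodons on random sequences", {
  set.seed(21)
  codons <- retroforge:::.codons()
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    s1 <- paste(sample(codons, n, replace = TRUE), collapse = "")
    s2 <- paste(sample(codons, n, replace = TRUE), collapse = "")
    r <- ng86(s1, s2)
    expect_equal(r$N + r$S, 3 * n, tolerance = 1e-9)
    expect_lte(r$Nd, r$N)
    expect_lte(r$Sd, r$S)
  }
})

test_that("dS = 0 flags omega as undefined rather than infinite", {
  # single nonsynonymous difference, no synonymous differences
  r <- ng86("ATGAAA", "ATGACA")
  expect_false(r$omegaDefined)
  expect_true(is.na(r$omega))
})

test_that("classifySubstitutions matches the genetic code and path oracle", {
  expect_equal(classifySubstitutions("ATG", "ATG"),
               c(nonsynonymous = 0, synonymous = 0))
  expect_equal(classifySubstitutions("AAA", "AAG"),
               c(nonsynonymous = 0, synonymous = 1))
  oracle <- pairOracle("AAA", "AGG")
  got <- classifySubstitutions("AAA", "AGG")
  expect_equal(unname(got["nonsynonymous"]), round(unname(oracle["nd"]), 2))
  expect_equal(unname(got["synonymous"]), round(unname(oracle["sd"]), 2))
  expect_error(classifySubstitutions("ATGA", "ATG"), "frame|length")
})
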