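# Monte-Carlo neutral null: degenerate inputs, the K = 1 enumeration
# oracle, determinism, monotonicity and the large-K neutral mean.

neutralTemplate <- function(nCodons, seed) {
  set.seed(seed)
  codons <- retroforge:::.codons()
  paste(sample(codons, nCodons, replace = TRUE), collapse = "")
}

test_that("K = 0 is a degenerate draw with undefined omega", {
  cfg <- neutralNullConfig(neutralTemplate(50, 1), K = 0, nReps = 100)
  r <- simulateNeutralPair(cfg)
  expect_false(r$omegaDefined)
  expect_identical(r$Nd + r$Sd, 0)
})

test_that("single-substitution outcomes match the enumeration oracle", {
  tpl <- "TTTGAAACC"
  tsTv <- 2
  # oracle: enumerate all (position, base) outcomes with ts/tv weights,
  # dropping stop-creating changes, and record P(nonsynonymous)
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(tpl, "")[[1]]
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  pTs <- tsTv / (tsTv + 2)
  outcomes <- data.frame(prob = numeric(0), nonsyn = logical(0))
  for (pos in seq_along(chars)) for (b in c("A", "C", "G", "T")) {
    if (b == chars[pos]) next
    w <- if (b == ts[[chars[pos]]]) pTs else (1 - pTs) / 2
    mut <- chars; mut[pos] <- b
    cod <- (pos - 1) %/% 3
    codon <- paste(mut[(cod * 3 + 1):(cod * 3 + 3)], collapse = "")
    if (gc[[codon]] == "*") next
    old <- paste(chars[(cod * 3 + 1):(cod * 3 + 3)], collapse = "")
    outcomes <- rbind(outcomes, data.frame(
      prob = w / 9, nonsyn = gc[[codon]] != gc[[old]]))
  }
  # stop-creating draws are resampled, so renormalize over kept outcomes
  pNonsyn <- sum(outcomes$prob[outcomes$nonsyn]) / sum(outcomes$prob)
  draws <- vapply(1:4000, function(i) {
    set.seed(i)
    mut <- retroforge:::.neutralMutate(chars, 1, tsTv)
    cod <- mut$changed[1]
    codon <- paste(mut$chars[(cod * 3 - 2):(cod * 3)], collapse = "")
    old <- substr(tpl, cod * 3 - 2, cod * 3)
    gc[[codon]] != gc[[old]]
  }, logical(1))
  obs <- mean(draws)
  expect_gt(stats::binom.test(sum(draws), length(draws),
                              pNonsyn)$p.value, 0.01)
  expect_lt(abs(obs - pNonsyn), 0.03)
})

test_that("identical configs give identical p-values (seeded determinism)", {
  tpl <- neutralTemplate(80, 2)
  mut <- decaySequence(tpl, 0.04, seed = 5)$seq
  obs <- ng86(tpl, mut)
  p1 <- nullPValue(mcPvalue(obs, neutralNullConfig(tpl, K = 10,
                                                   nReps = 200, seed = 9)))
  p2 <- nullPValue(mcPvalue(obs, neutralNullConfig(tpl, K = 10,
                                                   nReps = 200, seed = 9)))
  expect_identical(p1, p2)
})

test_that("a larger observed omega never yields a larger p on one null", {
  tpl <- neutralTemplate(100, 3)
  cfg <- neutralNullConfig(tpl, K = 12, nReps = 300, seed = 4)
  mkObs <- function(omega)
    structure(list(omega = omega, omegaDefined = TRUE), class = "Ng86Result")
  ps <- vapply(c(0.5, 1, 2, 4), function(om)
    nullPValue(mcPvalue(mkObs(om), cfg)), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("an observed omega of 0 with synonymous changes gives p near 1", {
  tpl <- neutralTemplate(100, 6)
  obs <- ng86(tpl, decaySequence(tpl, 0.05, seed = 2)$seq)
  obs$omega <- 0
  p <- nullPValue(mcPvalue(obs, neutralNullConfig(tpl, K = 10, nReps = 200,
                                                  seed = 1)))
  expect_gt(p, 0.95)
})

test_that("the null mean omega approaches 1 at large K", {
  # unweighted substitutions: with a transition bias NG86's equal-rate site
  # counting plateaus below 1, which is the estimator's documented property
  tpl <- neutralTemplate(600, 7)
  cfg <- neutralNullConfig(tpl, K = 200, tsTv = 1, nReps = 2000, seed = 3)
  obs <- ng86(tpl, decaySequence(tpl, 0.05, seed = 4)$seq)
  res <- mcPvalue(obs, cfg)
  m <- mean(res@nullSamples[is.finite(res@nullSamples)])
  expect_lt(abs(m - 1), 0.05)
})

test_that("undefined observed omega is an error, not a p-value", {
  tpl <- neutralTemplate(50, 8)
  obs <- ng86(tpl, tpl)
  expect_error(mcPvalue(obs, neutralNullConfig(tpl, K = 5, nReps = 100)),
               "undefined")
})
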