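# Synthetic-data generator: splicing identities, insertion construction,
# mutational decay statistics, and truth-tracked determinism.

test_that("single-exon gene: spliced mRNA equals the genomic CDS substring", {
  g <- makeParentGene(nExons = 1, exonLenRange = c(90, 120), seed = 3)
  ex <- exonRanges(g$annot)
  sub <- substr(as.character(g$genome[[1]]), IRanges::start(ex),
                IRanges::end(ex))
  expect_identical(g$mrna, sub)
  expect_identical(substr(g$mrna, 1, 3), "ATG")
  last <- substr(g$mrna, nchar(g$mrna) - 2, nchar(g$mrna))
  expect_true(last %in% c("TAA", "TAG", "TGA"))
})

test_that("multi-exon plus-strand gene splices exons in order", {
  g <- makeParentGene(nExons = 3, seed = 5)
  genomeSeq <- as.character(g$genome[[1]])
  ex <- exonRanges(g$annot)
  parts <- substring(genomeSeq, IRanges::start(ex), IRanges::end(ex))
  expect_identical(g$mrna, paste(parts, collapse = ""))
})

test_that("minus-strand gene matches a manual construction oracle", {
  g <- makeParentGene(nExons = 2, strand = "-", exonLenRange = c(12, 15),
                      intronLenRange = c(6, 9), flank = 10, seed = 8)
  genomeSeq <- as.character(g$genome[[1]])
  ex <- exonRanges(g$annot)
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  e1 <- substring(genomeSeq, IRanges::start(ex)[1], IRanges::end(ex)[1])
  e2 <- substring(genomeSeq, IRanges::start(ex)[2], IRanges::end(ex)[2])
  expect_identical(g$mrna, paste0(rc(e2), rc(e1)))
})

test_that("infeasible length ranges are rejected", {
  expect_error(makeParentGene(nExons = 2, exonLenRange = c(50, 40)),
               "infeasible")
  expect_error(makeParentGene(nExons = 0), "nExons")
})

test_that("plantRetrocopy builds [TSD][insert][polyA][TSD] at the site", {
  g <- makeParentGene(nExons = 1, seed = 2)
  genome0 <- g$genome
  L0 <- Biostrings::width(genome0)[1]
  pl <- plantRetrocopy(genome0, g$mrna, site = 500, tsdLen = 12,
                       polyALen = 20, strand = "+", seed = 4)
  L1 <- Biostrings::width(pl$genome)[1]
  insLen <- nchar(g$mrna) + 20
  expect_equal(L1, L0 + insLen + 12)
  seq1 <- as.character(pl$genome[[1]])
  tr <- pl$truth
  expect_identical(substr(seq1, tr$insert_start - 12, tr$insert_start - 1),
                   tr$tsd_seq)
  expect_identical(substr(seq1, tr$insert_end + 1, tr$insert_end + 12),
                   tr$tsd_seq)
  body <- substr(seq1, tr$insert_start, tr$insert_end - 20)
  expect_identical(body, g$mrna)
  tail <- substr(seq1, tr$insert_end - 19, tr$insert_end)
  expect_identical(tail, strrep("A", 20))
})

test_that("tsdLen 0 grows the genome by the insert alone", {
  g <- makeParentGene(nExons = 1, seed = 2)
  L0 <- Biostrings::width(g$genome)[1]
  pl <- plantRetrocopy(g$genome, g$mrna, site = 500, tsdLen = 0,
                       polyALen = 10)
  expect_equal(Biostrings::width(pl$genome)[1], L0 + nchar(g$mrna) + 10)
})

test_that("5' truncation leaves the 3' portion of the mRNA", {
  g <- makeParentGene(nExons = 1, seed = 2)
  cut <- floor(0.25 * nchar(g$mrna))
  pl <- plantRetrocopy(g$genome, g$mrna, site = 500, tsdLen = 5,
                       polyALen = 0, truncation = cut)
  tr <- pl$truth
  body <- substr(as.character(pl$genome[[1]]), tr$insert_start, tr$insert_end)
  expect_identical(body, substr(g$mrna, cut + 1, nchar(g$mrna)))
  # the inserted ORF is ~75% the parent length
  expect_equal(nchar(body) / nchar(g$mrna), 0.75, tolerance = 0.01)
})

test_that("planting respects forbidden intervals and bounds", {
  g <- makeParentGene(nExons = 1, seed = 2)
  expect_error(plantRetrocopy(g$genome, g$mrna, site = 10 + 1e9), "outside")
  expect_error(plantRetrocopy(g$genome, g$mrna, site = 2100,
                              forbid = IRanges::IRanges(2000, 2300)),
               "forbidden")
  expect_error(plantRetrocopy(g$genome, g$mrna, site = 500,
                              truncation = nchar(g$mrna)), "truncation")
})

test_that("decay is deterministic given seed with binomial substitutions", {
  seq <- randomDna(10000)
  expect_identical(decaySequence(seq, 0, 0)$seq, seq)
  d1 <- decaySequence(seq, 0.1, seed = 7)
  d2 <- decaySequence(seq, 0.1, seed = 7)
  expect_identical(d1$seq, d2$seq)
  counts <- vapply(1:40, function(s)
    sum(decaySequence(seq, 0.1, seed = s)$events$type == "sub"), numeric(1))
  # Binomial(10000, 0.1): mean 1000, SE of the mean over 40 seeds ~ 4.7
  expect_gt(mean(counts), 1000 - 3 * 30 / sqrt(40) * 4)
  expect_lt(mean(counts), 1000 + 3 * 30 / sqrt(40) * 4)
})

test_that("a cassette insertion is recorded as a single logged event", {
  seq <- randomDna(2000)
  d <- decaySequence(seq, 0, 0, cassettes = 1, cassetteLen = 300, seed = 3)
  expect_identical(nchar(d$seq), 2300L)
  expect_identical(sum(d$events$type == "cassette"), 1L)
  expect_identical(nchar(d$events$to[d$events$type == "cassette"]), 300L)
})

test_that("simulated genomes carry recoverable truth with distinct TSDs", {
  sim <- simulateRetrocopyGenome(nRetro = 3, targetLen = 1e5, seed = 12)
  tr <- sim$truth
  expect_identical(nrow(tr), 3L)
  expect_false(anyDuplicated(tr$tsd_seq) > 0)
  g <- as.character(sim$genome[["chrT"]])
  for (i in seq_len(nrow(tr))) {
    expect_identical(
      substr(g, tr$insert_start[i] - tr$tsd_len[i], tr$insert_start[i] - 1),
      tr$tsd_seq[i])
    expect_identical(
      substr(g, tr$insert_end[i] + 1, tr$insert_end[i] + tr$tsd_len[i]),
      tr$tsd_seq[i])
  }
  sim2 <- simulateRetrocopyGenome(nRetro = 3, targetLen = 1e5, seed = 12)
  expect_identical(as.character(sim2$genome), as.character(sim$genome))
})
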