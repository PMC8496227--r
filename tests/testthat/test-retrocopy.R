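# Retrocopy calling: the two gating criteria, TSD/poly-A evidence, the
# census, and the syntenic empty-site classification, all against planted
# truth.

simFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateRetrocopyGenome(nRetro = 3, targetLen = 2e5,
                                        seed = 77)
    cache
  }
})

test_that("the parent self-hit fails the intronless criterion", {
  sim <- simFixture()
  hits <- seedAndExtend(sim$mrna, sim$genome)
  self <- hits[hits$chrom == "chrP", ]
  expect_gte(nrow(self), 1L)
  expect_false(any(vapply(seq_len(nrow(self)), function(i)
    isTRUE(intronlessTest(self[i, ], sim$annot)), logical(1))))
})

test_that("planted retrocopies pass the intronless criterion", {
  sim <- simFixture()
  hits <- seedAndExtend(sim$mrna, sim$genome)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    h <- hits[hits$chrom == "chrT" & hits$tstart <= tr$insert_end[i] &
                hits$tend >= tr$insert_start[i], ]
    expect_gte(nrow(h), 1L)
    expect_true(isTRUE(intronlessTest(h[1, ], sim$annot)))
  }
})

test_that("single-exon parents make the criterion uninformative", {
  g <- makeParentGene(nExons = 1, seed = 3)
  hit <- data.frame(strand = "+", blocks = I(list(data.frame(
    qstart = 1, qend = 100, tstart = 1, tend = 100, nmatch = 100,
    nmismatch = 0))))
  res <- intronlessTest(hit, g$annot)
  expect_true(is.na(res))
  expect_identical(attr(res, "reason"), "uninformative")
})

test_that("a repeat-masked cassette at the junction is not read as intron", {
  # 2-exon parent; a 300 bp cassette planted exactly at the junction of an
  # otherwise intronless copy mimics an intron
  # exons long enough that bridging the 300 bp cassette gap (cost ~304)
  # still pays for the aligner
  g <- makeParentGene(nExons = 2, exonLenRange = c(450, 520),
                      intronLenRange = c(300, 400), seed = 9)
  exw <- IRanges::width(exonRanges(g$annot))
  j <- exw[1]
  cassette <- randomDna(300)
  copySeq <- paste0(substr(g$mrna, 1, j), cassette,
                    substr(g$mrna, j + 1, nchar(g$mrna)))
  host <- randomDna(30000)
  at <- 12000
  genome <- c(g$genome, Biostrings::DNAStringSet(setNames(
    paste0(substr(host, 1, at - 1), copySeq,
           substr(host, at, nchar(host))), "chrX")))
  hits <- seedAndExtend(g$mrna, genome)
  h <- hits[hits$chrom == "chrX", ][1, ]
  expect_false(isTRUE(intronlessTest(h, g$annot)))
  mask <- IRanges::IRanges(at + j, at + j + 299)
  expect_true(isTRUE(intronlessTest(h, g$annot, repeatMask = mask)))
})

test_that("reciprocal best hit separates parent copies from paralog decoys", {
  g <- makeParentGene(nExons = 1, exonLenRange = c(600, 700), seed = 41)
  paralog <- decaySequence(g$mrna, 0.30, seed = 1)$seq  # ~70% identical
  tdb <- Biostrings::DNAStringSet(c(parent = g$mrna, paralog = paralog))
  expect_true(reciprocalBestHit(g$mrna, tdb, "parent")$rbh)
  copy <- decaySequence(g$mrna, 0.08, seed = 2)$seq  # 92% identity copy
  expect_true(reciprocalBestHit(copy, tdb, "parent")$rbh)
  decoy <- decaySequence(paralog, 0.05, seed = 3)$seq
  r <- reciprocalBestHit(decoy, tdb, "parent")
  expect_false(r$rbh)
  expect_identical(r$bestId, "paralog")
  expect_error(reciprocalBestHit(copy, Biostrings::DNAStringSet(), "p"),
               "empty")
})

test_that("findTsd recovers exact and mismatched planted repeats", {
  set.seed(51)
  # junction bases are fixed so the planted repeat cannot be extended by a
  # chance match across the insertion boundaries (in which case "the" TSD
  # would genuinely be longer than planted)
  mkFlank <- function(n, lastChar)
    paste0(randomDna(n - 1), lastChar)
  for (rep in 1:10) {
    flank <- mkFlank(200, "C")
    tsd <- paste0("G", randomDna(10), "G")
    insert <- paste0("T", randomDna(498), "T")
    right <- paste0("A", randomDna(199))
    genome <- Biostrings::DNAStringSet(setNames(
      paste0(flank, tsd, insert, tsd, right), "c"))
    s <- 200 + 12 + 1
    found <- findTsd(genome, "c", c(s, s + 499))
    expect_false(is.null(found))
    expect_identical(found$seq, tsd)
    expect_identical(found$mismatches, 0L)
  }
  # one substitution in the right copy is tolerated and counted
  flank <- mkFlank(200, "C"); right <- paste0("A", randomDna(199))
  tsd <- "GCATGCTAGCTGACG"  # 15-mer without self-similar runs
  tsdMut <- paste0(substr(tsd, 1, 7), "C", substr(tsd, 9, 15))
  insert <- paste0("T", randomDna(398), "T")
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(flank, tsd, insert, tsdMut, right), "c"))
  found <- findTsd(genome, "c", c(216, 615))
  expect_identical(found$len, 15L)
  expect_identical(found$mismatches, 1L)
  # no repeat planted: nothing qualifying
  genome0 <- Biostrings::DNAStringSet(setNames(randomDna(1200), "c"))
  found0 <- findTsd(genome0, "c", c(400, 800), maxMismatchFrac = 0)
  if (!is.null(found0)) expect_lt(found0$len, 8L)
})

test_that("findPolyA detects planted tails and honours purity", {
  flank <- randomDna(300)
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(flank, strrep("A", 30), strrep("G", 100)), "c"))
  pa <- findPolyA(genome, "c", 300, "+", window = 40)
  expect_equal(pa$length, 30)
  expect_equal(pa$purity, 1)
  # 2 substitutions in 20 nt: detected with purity 0.9
  tail20 <- paste0(strrep("A", 9), "G", strrep("A", 7), "C", "AA")
  genome2 <- Biostrings::DNAStringSet(setNames(
    paste0(flank, tail20, strrep("G", 50)), "c"))
  pa2 <- findPolyA(genome2, "c", 300, "+")
  expect_equal(pa2$length, 20)
  expect_equal(pa2$purity, 0.9)
  # false-positive rate on random flanks
  set.seed(52)
  fp <- sum(vapply(1:200, function(i) {
    g <- Biostrings::DNAStringSet(setNames(randomDna(400), "c"))
    !is.null(findPolyA(g, "c", 200, "+"))
  }, logical(1)))
  expect_lt(fp / 200, 0.05)
})

test_that("verdicts follow the two criteria and evidence is attached", {
  sim <- simFixture()
  tdb <- Biostrings::DNAStringSet(setNames(sim$mrna, "parent"))
  calls <- callRetrocopies(sim$annot, sim$mrna, sim$genome, tdb)
  expect_true(all(calls$verdict %in%
                    c("retrocopy", "rejected_intron", "rejected_rbh")))
  expect_identical(calls$verdict == "retrocopy",
                   calls$intronless & calls$rbh)
  rc <- calls[calls$verdict == "retrocopy", ]
  expect_identical(nrow(rc), nrow(sim$truth))
  expect_identical(sort(rc$tsd_seq), sort(sim$truth$tsd_seq))
  expect_true(all(rc$percent_identity == round(rc$percent_identity, 1)))
  # decoy fragments are rejected as intron-containing
  expect_gte(sum(calls$verdict == "rejected_intron"), 1L)
})

test_that("an insert-free genome yields no retrocopy verdicts", {
  g <- makeParentGene(seed = 15)
  tdb <- Biostrings::DNAStringSet(setNames(g$mrna, "parent"))
  calls <- callRetrocopies(g$annot, g$mrna, g$genome, tdb)
  expect_identical(sum(calls$verdict == "retrocopy"), 0L)
})

test_that("the census histogram matches planted counts and is deterministic", {
  sim <- simFixture()
  tdb <- Biostrings::DNAStringSet(setNames(sim$mrna, "parent"))
  genes <- list(list(annot = sim$annot, mrna = sim$mrna))
  out <- tempfile(fileext = ".tsv")
  c1 <- retrocopyCensus(genes, sim$genome, tdb, out = out)
  expect_identical(unname(c1$perGene["parent"]), 3)
  expect_identical(c1$histogram$genes[c1$histogram$copies == 3], 1L)
  expect_true(file.exists(out))
  c2 <- retrocopyCensus(genes, sim$genome, tdb)
  expect_identical(c1$perGene, c2$perGene)
  expect_identical(retrocopyCensus(list(), sim$genome, tdb)$perGene,
                   setNames(numeric(0), character(0)))
})

test_that("empty-site classification separates empty, filled and deleted", {
  sim <- simFixture()
  tdb <- Biostrings::DNAStringSet(setNames(sim$mrna, "parent"))
  calls <- callRetrocopies(sim$annot, sim$mrna, sim$genome, tdb)
  rc <- calls[calls$verdict == "retrocopy", ][1, ]
  empty <- emptySiteCheck(sim$genome, sim$preInsertionGenome, rc)
  expect_identical(empty$status, "empty")
  expect_true(grepl(empty$preInsertionSeq,
                    as.character(sim$preInsertionGenome[["chrT"]]),
                    fixed = TRUE))
  filled <- emptySiteCheck(sim$genome, sim$genome, rc)
  expect_identical(filled$status, "filled")
  g <- as.character(sim$genome[["chrT"]])
  deleted <- paste0(substr(g, 1, rc$insert_start - 700),
                    substr(g, rc$insert_end + 700, nchar(g)))
  res <- emptySiteCheck(sim$genome,
                        Biostrings::DNAStringSet(c(chrT = deleted)), rc)
  expect_identical(res$status, "deleted/ambiguous")
})
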