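test_that("mutation indicators mark differing unambiguous sites", {
  x <- PcpSet("AAAA", "AATA")
  expect_identical(mutationIndicators(x)[[1]], c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(sum(lossMasks(x)[[1]]), 4L)

  x2 <- PcpSet("AAAA", "ANAA")
  expect_false(lossMasks(x2)[[1]][2]) # N site is non-informative
  expect_identical(mutationIndicators(x2)[[1]], rep(FALSE, 4))

  x3 <- PcpSet("ACGT", "ACGT")
  expect_identical(mutationIndicators(x3)[[1]], rep(FALSE, 4))
  expect_error(PcpSet("AAAA", "AAA"), "lengths differ")
})

test_that("normalized mutation count divides by informative sites only", {
  x <- uniformPair(100, 2)
  expect_equal(normalizedMutationCount(x), 0.02)

  # 3 substitutions, 300 sites with 60 masked: t = 3/240
  parent <- strrep("A", 300)
  child <- paste0(strrep("C", 3), strrep("A", 297))
  mask <- list(c(rep(TRUE, 240), rep(FALSE, 60)))
  x2 <- PcpSet(parent, child, lossMask = mask)
  expect_equal(normalizedMutationCount(x2), 3 / 240)

  # zero substitutions: t = 0 and pair flagged
  x3 <- PcpSet("ACGT", "ACGT")
  expect_equal(branchLengths(x3), 0)
  expect_true(zeroSubstitutionPairs(x3))

  x4 <- PcpSet("NNNN", "NNNN", branchLength = 0)
  expect_error(normalizedMutationCount(x4), "zero informative")
})

test_that("masked substitutions do not count toward the mutation filter", {
  parent <- strrep("A", 50)
  child <- paste0(strrep("G", 12), strrep("A", 38))
  mask <- list(c(rep(FALSE, 4), rep(TRUE, 46))) # hide 4 of the 12 substitutions
  x <- PcpSet(parent, child, lossMask = mask)
  expect_identical(mutationCounts(x), 8L)
})

test_that("the mutation-count filter keeps strictly-below-threshold pairs", {
  mk <- function(m) {
    paste0(strrep("C", m), strrep("A", 50 - m))
  }
  x <- PcpSet(rep(strrep("A", 50), 3), c(mk(9), mk(10), mk(2)),
              familyId = c("f9", "f10", "f2"))
  kept <- filterByMutationCount(x, 10)
  expect_identical(familyIds(kept), c("f9", "f2")) # order preserved
  # idempotence
  expect_identical(familyIds(filterByMutationCount(kept, 10)), c("f9", "f2"))
  # empty in, empty out
  e <- x[integer(0)]
  expect_length(filterByMutationCount(e, 10), 0L)
})

test_that("gapped sequences are rejected at load time", {
  expect_error(PcpSet("AC-T", "ACGT"), "gap")
  expect_error(PcpSet("ACGT", "AC-T"), "gap")
})

test_that("fourfold mask retains exactly fourfold third positions (all 64 codons)", {
  for (codon in thriftySHM:::.allKmers(3)) {
    parent <- paste0("ATG", codon) # leading Met codon is never fourfold
    x <- fourfoldDegenerateMask(PcpSet(parent, parent, branchLength = 0))
    expected <- rep(FALSE, 6)
    expected[6] <- substr(codon, 1, 2) %in% FOURFOLD_PREFIXES
    expect_identical(lossMasks(x)[[1]], expected, label = codon)
  }
})

test_that("fourfold mask handles worked examples, partial codons and N codons", {
  x <- fourfoldDegenerateMask(PcpSet("GGAGGA", "GGTGGC"))
  expect_identical(which(lossMasks(x)[[1]]) - 1L, c(2L, 5L)) # 0-based sites 2,5
  m <- mutationIndicators(x)[[1]] & lossMasks(x)[[1]]
  expect_identical(which(m) - 1L, c(2L, 5L)) # retained A->T and A->C

  x2 <- fourfoldDegenerateMask(PcpSet("ATGAAA", "ATGAAA", branchLength = 0))
  expect_false(any(lossMasks(x2)[[1]])) # Met, Lys: nothing fourfold

  x3 <- fourfoldDegenerateMask(PcpSet("GGAGGAG", "GGAGGAG", branchLength = 0))
  expect_false(lossMasks(x3)[[1]][7]) # trailing partial codon masked

  x4 <- fourfoldDegenerateMask(PcpSet("GNAGGA", "GNAGGA", branchLength = 0))
  expect_identical(which(lossMasks(x4)[[1]]), 6L) # N codon wholly masked

  expect_error(fourfoldDegenerateMask(PcpSet("GGAGGA", "GGAGGA", branchLength = 0),
                                      frameOffset = -1), "nonnegative")
})

test_that("fourfold mask is idempotent and never unmasks ambiguity-masked sites", {
  set.seed(11)
  tm <- randomTrueModel(3, seed = 3)
  sim <- simulateDataset(simConfig(4, 60, 0.1, inFrame = TRUE, seed = 9), tm)
  once <- fourfoldDegenerateMask(sim)
  twice <- fourfoldDegenerateMask(once)
  expect_identical(lossMasks(once), lossMasks(twice))
  # inject Ns and confirm those sites stay masked
  p <- parentSeqs(sim)[1]
  substr(p, 6, 6) <- "N"
  x <- fourfoldDegenerateMask(PcpSet(p, childSeqs(sim)[1]))
  expect_false(lossMasks(x)[[1]][6])
})

test_that("PCP tables round-trip sequences, masks and t bit-exactly", {
  tm <- randomTrueModel(3, seed = 4)
  sim <- simulateDataset(simConfig(5, 40, "loguniform", seed = 6), tm)
  sim <- fourfoldDegenerateMask(sim) # non-trivial masks
  path <- withr::local_tempfile(fileext = ".tsv")
  writePcpTable(sim, path)
  back <- readPcpTable(path)
  expect_identical(parentSeqs(back), parentSeqs(sim))
  expect_identical(childSeqs(back), childSeqs(sim))
  expect_identical(branchLengths(back), branchLengths(sim))
  expect_identical(lossMasks(back), lossMasks(sim))
  expect_identical(sampleIds(back), sampleIds(sim))
  expect_identical(familyIds(back), familyIds(sim))
})

test_that("PcpSet subsetting and accessors preserve order", {
  x <- PcpSet(c("AAAA", "CCCC", "GGGG"), c("AATA", "CCCC", "GGTG"),
              familyId = c("a", "b", "c"))
  s <- x[c(3, 1)]
  expect_identical(familyIds(s), c("c", "a"))
  expect_identical(parentSeqs(s), c("GGGG", "AAAA"))
})
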