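test_that("reading a FASTA plus population map validates the pairing", {
  f <- writeFixture(
    c(a = "ACGTT", b = "ACGAT"),
    c(a = "North", b = "South")
  )
  aln <- readAlignment(f$fasta, f$popmap)
  expect_s4_class(aln, "PopAlignment")
  expect_equal(nSequences(aln), 2L)
  expect_equal(alignmentWidth(aln), 5L)
  expect_equal(levels(populations(aln)), c("North", "South"))

  # unaligned input names the offending sequence
  bad <- writeFixture(c(a = "ACGTT", b = "ACGA"), c(a = "N", b = "S"))
  expect_error(readAlignment(bad$fasta, bad$popmap), "b")

  # popmap id missing from the FASTA and vice versa
  f2 <- writeFixture(c(a = "ACGTT", b = "ACGAT"), c(a = "N", b = "S", z = "S"))
  expect_error(readAlignment(f2$fasta, f2$popmap), "z")
  f3 <- writeFixture(c(a = "ACGTT", b = "ACGAT"), c(a = "N"))
  expect_error(readAlignment(f3$fasta, f3$popmap), "b")

  # empty FASTA
  fa <- tempfile()
  writeLines(character(0), fa)
  expect_error(readAlignment(fa, f$popmap), "no sequences|empty")

  # U mapped to T, case folded
  aln2 <- PopAlignment(c(x = "acgu"), c(x = "P"))
  expect_equal(as.character(alignmentSeqs(aln2)), c(x = "ACGT"))
})

test_that("complete-deletion filtering removes exactly the gapped columns", {
  aln <- makeAln(c(a = "ACGTACGTAC", b = "ACG-ACGTAC", c = "ACGTACGTNC"))
  flt <- filterSites(aln)
  expect_equal(alignmentWidth(flt), 8L)
  expect_equal(attr(flt, "siteMap"), c(1:3, 5:8, 10))

  # gapless alignment passes through unchanged
  clean <- randomAln(6, 40, seed = 3)
  expect_equal(
    as.character(alignmentSeqs(filterSites(clean))),
    as.character(alignmentSeqs(clean))
  )

  # randomly gapped fixture agrees with a per-column brute-force scan
  set.seed(11)
  chars <- matrix(sample(c("A", "C", "G", "T"), 8 * 200, replace = TRUE), 8, 200)
  gapCols <- sample(200, 10)
  for (g in gapCols) chars[sample(8, 1), g] <- "-"
  aln3 <- makeAln(apply(chars, 1, paste0, collapse = ""))
  keepOracle <- vapply(
    seq_len(200),
    function(j) !any(chars[, j] %in% c("-", "N")), TRUE
  )
  expect_equal(alignmentWidth(filterSites(aln3)), sum(keepOracle))
  expect_equal(attr(filterSites(aln3), "siteMap"), which(keepOracle))

  # all columns gapped is a degenerate alignment
  expect_error(filterSites(makeAln(c(a = "A-", b = "-A"))), "no columns")
})

test_that("haplotype collapsing merges identical sequences with counts", {
  # 22 sequences, exactly two identical -> 21 haplotypes
  set.seed(5)
  base <- replicate(21, paste0(sample(c("A", "C", "G", "T"), 30, TRUE),
    collapse = ""
  ))
  seqs <- c(base, base[1])
  names(seqs) <- paste0("s", 1:22)
  haps <- collapseHaplotypes(makeAln(seqs))
  expect_equal(nrow(haplotypeCounts(haps)), 21L)

  # all identical -> 1
  one <- collapseHaplotypes(makeAln(setNames(rep("ACGT", 10), paste0("i", 1:10))))
  expect_equal(nrow(haplotypeCounts(one)), 1L)

  # hand enumeration: 6 sequences, 3 distinct, counts (3, 2, 1)
  aln <- makeAln(c(
    a = "AAAA", b = "AAAA", c = "AAAA",
    d = "AAAT", e = "AAAT", f = "ATTT"
  ))
  haps2 <- collapseHaplotypes(aln)
  expect_equal(unname(rowSums(haplotypeCounts(haps2))), c(3, 2, 1))
})

test_that("collapsing is order-invariant and round-trips through FASTA", {
  aln <- randomAln(12, 25, seed = 9)
  # force duplicates
  s <- as.character(alignmentSeqs(aln))
  s[4] <- s[1]
  s[9] <- s[2]
  aln <- makeAln(setNames(s, names(s)))
  haps <- collapseHaplotypes(aln)

  perm <- sample(seq_along(s))
  alnP <- makeAln(s[perm])
  hapsP <- collapseHaplotypes(alnP)
  expect_equal(
    sort(unname(as.character(haplotypes(haps)))),
    sort(unname(as.character(haplotypes(hapsP))))
  )
  expect_equal(
    sort(unname(rowSums(haplotypeCounts(haps)))),
    sort(unname(rowSums(haplotypeCounts(hapsP))))
  )

  fa <- tempfile(fileext = ".fasta")
  writeHaplotypeFasta(haps, fa)
  rereadSeqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(rereadSeqs), as.character(haplotypes(haps)))
  # re-collapsing the expanded alignment reproduces the table exactly
  haps2 <- collapseHaplotypes(aln)
  expect_identical(haplotypeCounts(haps), haplotypeCounts(haps2))
})

test_that("site classification separates singleton and informative sites", {
  # toy from the definitions: cols (A,A,G,G), (C,T,T,T), (A,A,A,A)
  aln <- makeAln(c(a = "ACA", b = "ATA", c = "GTA", d = "GTA"))
  cls <- classifySites(aln)
  expect_equal(cls$polymorphicSites, 2L)
  expect_equal(cls$informativeSites, 1L)
  expect_equal(cls$singletonSites, 1L)
  expect_equal(cls$transitions, 2L) # A/G and C/T pairs
  expect_equal(cls$transversions, 0L)
  expect_true(is.na(cls$tvTsRatio) || cls$tvTsRatio == 0)

  # a column with bases A x12, G x1 is a singleton site with one ts pair
  aln2 <- makeAln(setNames(
    c(rep("AA", 12), "GA"),
    paste0("i", 1:13)
  ))
  cls2 <- classifySites(aln2)
  expect_equal(cls2$singletonSites, 1L)
  expect_equal(cls2$transitions, 1L)

  # A x5 / G x5 is informative
  aln3 <- makeAln(setNames(c(rep("A", 5), rep("G", 5)), paste0("i", 1:10)))
  expect_equal(classifySites(aln3)$informativeSites, 1L)

  # base frequencies pool all cells and sum to one
  expect_equal(sum(cls$baseFreqs), 1, tolerance = 1e-12)
  expect_error(classifySites(makeAln(c(a = "ACGT"))), "two sequences")
})

test_that("singletons plus informative sites equal the polymorphic count", {
  for (seed in 1:5) {
    aln <- randomAln(7, 60, seed = seed)
    cls <- classifySites(aln)
    expect_equal(
      cls$singletonSites + cls$informativeSites,
      cls$polymorphicSites
    )
  }
})
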