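test_that("AMOVA variance components follow the sums-of-squares algebra", {
  # two pairs of identical haplotypes, one difference between the pairs
  aln <- makeAln(
    c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AAAT"),
    c(a = "X", b = "X", c = "Y", d = "Y")
  )
  am <- amova(aln, permutations = 0)
  expect_equal(am@va, 0.5, tolerance = 1e-12)
  expect_equal(am@vb, 0, tolerance = 1e-12)
  expect_equal(am@phiST, 1, tolerance = 1e-12)
  expect_equal(am@pctAmong + am@pctWithin, 100, tolerance = 1e-9)
  expect_equal(unname(am@df), c(1, 2))

  # self-consistency: components recomputed from the printed SS agree
  aln2 <- divergedAln(12, 50,
    subs = 5, seed = 8,
    pops = rep(c("P1", "P2", "P3"), each = 4)
  )
  am2 <- amova(aln2, permutations = 0)
  re <- amovaComponents(am2@ss[1], am2@ss[2], c(4, 4, 4))
  expect_equal(re@va, am2@va, tolerance = 1e-12)
  expect_equal(re@phiST, am2@phiST, tolerance = 1e-12)

  expect_error(amova(makeAln(c(a = "AA", b = "AT"))), "two populations")
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  aln <- divergedAln(10, 60,
    subs = 4, seed = 3,
    pops = rep(c("A", "B"), each = 5)
  )
  a1 <- amova(aln, permutations = 99, seed = 42)
  a2 <- amova(aln, permutations = 99, seed = 42)
  expect_identical(a1@p, a2@p)
  # reordering individuals leaves the statistic and p unchanged
  seqs <- as.character(alignmentSeqs(aln))
  pops <- as.character(populations(aln))
  names(pops) <- names(seqs)
  ord <- rev(seq_along(seqs))
  alnR <- PopAlignment(seqs[ord], pops[ord])
  a3 <- amova(alnR, permutations = 99, seed = 42)
  expect_equal(a3@phiST, a1@phiST, tolerance = 1e-12)
  expect_equal(a3@p, a1@p)
})

test_that("pairwise FST covers both estimator families", {
  # identical haplotype frequencies in both populations: no positive
  # differentiation (the unbiased Weir-Cockerham estimate is <= 0 because
  # the between-population mean square cannot fall below sampling noise)
  aln0 <- makeAln(
    c(a = "AAAA", b = "AATT", c = "AAAA", d = "AATT"),
    c(a = "X", b = "X", c = "Y", d = "Y")
  )
  f0 <- pairwiseFst(aln0, mode = "frequency", permutations = 0)
  expect_lte(f0@stat["X", "Y"], 0)

  # two populations fixed for different haplotypes: Weir-Cockerham theta = 1
  aln1 <- makeAln(
    c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"),
    c(a = "X", b = "X", c = "Y", d = "Y")
  )
  f1 <- pairwiseFst(aln1, mode = "frequency", permutations = 0)
  expect_equal(f1@stat["X", "Y"], 1, tolerance = 1e-12)

  # distance mode equals the two-population AMOVA PhiST
  aln2 <- divergedAln(12, 80,
    subs = 6, seed = 17,
    pops = rep(c("A", "B"), each = 6)
  )
  f2 <- pairwiseFst(aln2, mode = "distance", permutations = 0)
  am <- amova(aln2, permutations = 0)
  expect_equal(f2@stat["A", "B"], am@phiST, tolerance = 1e-12)
  expect_equal(f2@stat, t(f2@stat))
})

test_that("corrected Da equals its defining decomposition", {
  # X and Y hold the same sequences: the defining decomposition gives
  # Da = PiXY - PiX = pi(1 - 1/n) - pi = -pi/n (zero only as n grows);
  # here pi = 2, n = 2, so Da = -1, reported as computed
  alnSame <- makeAln(
    c(a = "AAAT", b = "ATTT", c = "AAAT", d = "ATTT"),
    c(a = "X", b = "X", c = "Y", d = "Y")
  )
  expect_equal(correctedDa(alnSame)@stat["X", "Y"], -1, tolerance = 1e-12)

  # X = {AAAA, AAAT}, Y = {TTTT, TTTA}: PiX = PiY = 1, PiXY = 3.5
  aln <- makeAln(
    c(a = "AAAA", b = "AAAT", c = "TTTT", d = "TTTA"),
    c(a = "X", b = "X", c = "Y", d = "Y")
  )
  da <- correctedDa(aln)
  expect_equal(da@stat["X", "Y"], 3.5 - 1, tolerance = 1e-12)

  # direct substitution: PiXY = 10, PiX = 4, PiY = 6 -> Da = 5
  expect_equal(10 - (4 + 6) / 2, 5)

  # brute-force oracle on random fixtures; symmetry
  for (seed in 1:4) {
    aln <- divergedAln(11, 40,
      subs = 5, seed = seed + 50,
      pops = c(rep("P", 5), rep("Q", 6))
    )
    da <- correctedDa(aln)@stat
    seqs <- as.character(alignmentSeqs(aln))
    px <- bruteMeanPairwise(seqs[1:5])
    py <- bruteMeanPairwise(seqs[6:11])
    cross <- mean(outer(1:5, 6:11, Vectorize(function(i, j) {
      sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
    })))
    expect_equal(da["P", "Q"], cross - (px + py) / 2, tolerance = 1e-12)
    expect_equal(da, t(da))
  }
  expect_error(
    correctedDa(makeAln(c(a = "AA", b = "AA"), c(a = "X", b = "Y"))),
    "n >= 2"
  )
})

test_that("Bonferroni flags respect the comparison count", {
  expect_true(bonferroniAdjust(0.004, alpha = 0.05, m = 10)$significant)
  expect_false(bonferroniAdjust(0.006, alpha = 0.05, m = 10)$significant)
  expect_true(bonferroniAdjust(0.04, alpha = 0.05, m = 1)$significant)
  p <- matrix(c(NA, 0.002, 0.002, NA), 2)
  adj <- bonferroniAdjust(p, alpha = 0.05)
  expect_equal(adj$m, 1L)
  expect_equal(adj$tiers[1, 2], "**")
})

test_that("the Mantel test matches exhaustive enumeration and vegan", {
  gen <- matrix(0, 4, 4)
  gen[lower.tri(gen)] <- c(1, 2.2, 3.1, 4.4, 5.3, 6.9)
  gen <- gen + t(gen)
  dimnames(gen) <- list(letters[1:4], letters[1:4])
  # affine image: r = 1, identity is the unique optimum -> exact p = 1/24
  geo <- 2 * gen
  mt <- mantelTest(gen, geo, exact = TRUE)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$r2, 1, tolerance = 1e-12)
  expect_equal(mt$p, 1 / 24)
  expect_equal(mt$permutations, 24)

  # sampled p is seed-stable and r agrees with vegan's implementation
  skip_if_not_installed("vegan")
  set.seed(77)
  g2 <- as.matrix(dist(matrix(rnorm(12), 6)))
  g3 <- as.matrix(dist(matrix(rnorm(12), 6)))
  mine <- mantelTest(g2, g3, permutations = 199, seed = 5, exact = FALSE)
  ref <- vegan::mantel(g2, g3, permutations = 199)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
  again <- mantelTest(g2, g3, permutations = 199, seed = 5, exact = FALSE)
  expect_identical(mine$p, again$p)

  flat <- matrix(1, 4, 4) - diag(4)
  expect_true(is.na(mantelTest(flat, geo)$r))
  expect_error(mantelTest(gen[1:2, 1:2], geo[1:2, 1:2]), "at least 3")
})

test_that("great-circle helper returns kilometre-scale symmetric matrices", {
  coords <- data.frame(lon = c(-35.5, -39.0, -81.2), lat = c(-9.4, -14.8, 25.4))
  rownames(coords) <- c("ALA", "BAH", "FLO")
  m <- greatCircleDistances(coords)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(ALA = 0, BAH = 0, FLO = 0))
  expect_gt(m["ALA", "FLO"], m["ALA", "BAH"])
})
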