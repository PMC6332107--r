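test_that("K2P distances follow the two-parameter formula", {
  # identical pair
  expect_equal(
    k2pMatrix(makeAln(c(a = "ACGT", b = "ACGT")))["a", "b"], 0
  )
  # L = 4, one transition: P = 0.25, Q = 0 -> -0.5 ln 0.5
  d <- k2pMatrix(makeAln(c(a = "ACGT", b = "GCGT")))
  expect_equal(d["a", "b"], -0.5 * log(0.5), tolerance = 1e-12)
  # P = 0.1, Q = 0.1 over L = 10 (one ts A>G, one tv A>C)
  d2 <- k2pMatrix(makeAln(c(a = "AAAAAAAAAA", b = "GCAAAAAAAA")))
  expect_equal(d2["a", "b"],
    -0.5 * log(1 - 0.2 - 0.1) - 0.25 * log(1 - 0.2),
    tolerance = 1e-12
  )
  expect_equal(round(d2["a", "b"], 4), 0.2341)
  # saturation boundary errors and names the pair
  expect_error(
    k2pMatrix(makeAln(c(x = "AAAA", y = "GGGG"))),
    "saturation.*x / y"
  )
})

test_that("K2P agrees with an independent implementation", {
  skip_if_not_installed("ape")
  aln <- divergedAln(8, 300, subs = 20, seed = 42)
  mine <- k2pMatrix(aln)
  bin <- ape::as.DNAbin(strsplit(as.character(alignmentSeqs(aln)), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
})

test_that("NJ recovers additive trees exactly", {
  # four-point example: ((A:1,B:2):1,(C:3,D:4))
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- neighborJoining(dm)
  # the split {A,B} | {C,D} is recovered with internal branch length 1
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(dm), colnames(dm)],
    dm,
    tolerance = 1e-9
  )
  internal <- tr$edge[, 1] > ape::Ntip(tr) & tr$edge[, 2] > ape::Ntip(tr)
  expect_equal(sum(internal), 1L)
  expect_equal(tr$edge.length[internal], 1, tolerance = 1e-9)

  # random additive trees (n <= 10): path lengths reproduce the input
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:10, 1)
    truth <- ape::rtree(n, rooted = FALSE)
    truth$edge.length <- truth$edge.length + 0.1 # keep branches positive
    dmat <- as.matrix(stats::cophenetic(truth))
    est <- neighborJoining(dmat)
    expect_equal(as.matrix(stats::cophenetic(est))[rownames(dmat), colnames(dmat)],
      dmat,
      tolerance = 1e-9
    )
    expect_equal(ape::dist.topo(ape::unroot(truth), est), 0,
      ignore_attr = TRUE
    )
  }
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr <- neighborJoining(dm)
  # x_a = (d_ab + d_ac - d_bc)/2 etc.
  lens <- setNames(
    tr$edge.length[match(1:3, tr$edge[, 2])],
    tr$tip.label
  )
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 1, 3), tolerance = 1e-12)
})

test_that("bootstrap support is seed-reproducible and saturates at 100", {
  # every variable column supports the same bipartition
  blk <- function(core) paste0(core, strrep("C", 31))
  aln <- makeAln(c(
    a = blk("AAAAAAAAC"), b = blk("AAAAAAAAT"),
    c = blk("GGGGGGGGC"), d = paste0("GGGGGGGGCT", strrep("C", 30))
  ))
  haps <- collapseHaplotypes(aln)
  tr <- bootstrapSupport(haps, reps = 50, seed = 7)
  expect_true(max(tr$node.label, na.rm = TRUE) == 100)
  tr2 <- bootstrapSupport(haps, reps = 50, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)

  # zero variation warns and reports no support
  flat <- makeAln(setNames(rep("ACGT", 5), paste0("i", 1:5)))
  expect_warning(tr3 <- bootstrapSupport(flat, reps = 10, seed = 1), "no variation")
  expect_true(all(is.na(tr3$node.label)))
})

test_that("newick serialization round-trips topology, lengths, supports", {
  aln <- divergedAln(6, 120, subs = 8, seed = 13)
  tr <- bootstrapSupport(collapseHaplotypes(aln), reps = 20, seed = 3)
  txt <- writeNewick(tr)
  back <- readNewick(text = txt)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  ord <- match(back$tip.label, tr$tip.label)
  coTr <- as.matrix(stats::cophenetic(tr))
  coBack <- as.matrix(stats::cophenetic(back))
  expect_equal(coBack[rownames(coTr), colnames(coTr)], coTr, tolerance = 1e-10)
  expect_equal(
    sort(as.numeric(back$node.label)),
    sort(tr$node.label[!is.na(tr$node.label)])
  )
})
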