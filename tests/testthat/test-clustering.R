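test_that("the partition score follows the Dirichlet-multinomial closed form", {
  # single cluster of identical sequences: every site observes one allele,
  # so the marginal reduces to the closed-form single-category value, 0
  same <- makeAln(setNames(rep("ACGT", 6), paste0("i", 1:6)))
  alpha <- 0.25
  closedForm <- sum(vapply(1:4, function(s) {
    lgamma(alpha + 6) - lgamma(alpha) + lgamma(alpha) - lgamma(alpha + 6)
  }, 0))
  expect_equal(dirichletMultinomialScore(rep(1L, 6), same), closedForm)

  # splitting identical sequences never increases the score
  expect_lte(
    dirichletMultinomialScore(c(1L, 1L, 1L, 2L, 2L, 2L), same),
    dirichletMultinomialScore(rep(1L, 6), same)
  )

  # two internally-identical, mutually-different groups: the true split
  # scores strictly higher, and matches a direct evaluation
  aln <- makeAln(setNames(
    c(rep("AAAA", 3), rep("TTTT", 3)), paste0("i", 1:6)
  ))
  split <- c(1L, 1L, 1L, 2L, 2L, 2L)
  merged <- rep(1L, 6)
  direct <- function(countsA, countsT, n) {
    # one site, two observed alleles, alpha = 0.25 each
    sum(lgamma(alpha + c(countsA, countsT))) - 2 * lgamma(alpha) +
      lgamma(2 * alpha) - lgamma(2 * alpha + n)
  }
  expect_equal(
    dirichletMultinomialScore(split, aln),
    4 * (direct(3, 0, 3) + direct(0, 3, 3))
  )
  expect_equal(dirichletMultinomialScore(merged, aln), 4 * direct(3, 3, 6))
  expect_gt(
    dirichletMultinomialScore(split, aln),
    dirichletMultinomialScore(merged, aln)
  )
})

test_that("the score is invariant to relabeling and individual order", {
  aln <- divergedAln(9, 30, subs = 3, seed = 44)
  labels <- c(1L, 2L, 1L, 3L, 2L, 1L, 3L, 2L, 1L)
  s1 <- dirichletMultinomialScore(labels, aln)
  relabeled <- c(3L, 1L, 3L, 2L, 1L, 3L, 2L, 1L, 3L)
  expect_equal(dirichletMultinomialScore(relabeled, aln), s1)
  ord <- sample(9)
  seqs <- as.character(alignmentSeqs(aln))[ord]
  alnP <- makeAln(seqs)
  expect_equal(dirichletMultinomialScore(labels[ord], alnP), s1)
})

test_that("well-separated groups are recovered with confident assignment", {
  grpA <- setNames(rep("AAAAAAAAAACCCC", 4), paste0("a", 1:4))
  grpB <- setNames(rep("TTTTTTTTTTCCCC", 4), paste0("b", 1:4))
  aln <- makeAln(c(grpA, grpB))
  fit <- fitClusters(aln, kMax = 4, replicates = 3, seed = 1)
  expect_equal(fit@k, 2L)
  truth <- rep(1:2, each = 4)
  expect_equal(adjustedRand(fit@labels, truth), 1)
  expect_true(all(apply(fit@membership, 1, max) > 0.99))
  expect_equal(unname(rowSums(fit@membership)), rep(1, 8), tolerance = 1e-9)

  # determinism under the same seed
  fit2 <- fitClusters(aln, kMax = 4, replicates = 3, seed = 1)
  expect_identical(fit@labels, fit2@labels)
  expect_identical(fit@logMarginal, fit2@logMarginal)
})

test_that("mixture data reaches high adjusted Rand index against truth", {
  # two diverged clusters with within-group variation
  set.seed(61)
  mk <- function(core, n, tag) {
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(core, "")[[1]]
      at <- sample(length(s), 2)
      s[at] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      paste0(s, collapse = "")
    }, "")
    setNames(seqs, paste0(tag, seq_len(n)))
  }
  coreA <- paste0(rep("A", 30), collapse = "")
  coreB <- paste0(c(rep("T", 20), rep("A", 10)), collapse = "")
  aln <- makeAln(c(mk(coreA, 8, "a"), mk(coreB, 8, "b")))
  fit <- fitClusters(aln, kMax = 5, replicates = 3, seed = 7)
  truth <- rep(1:2, each = 8)
  expect_gte(adjustedRand(fit@labels, truth), 0.9)
})

test_that("the assignment table is long-format and complete", {
  grp <- makeAln(
    setNames(c(rep("AAAA", 3), rep("TTTT", 3)), paste0("i", 1:6)),
    setNames(rep(c("N", "S"), 3), paste0("i", 1:6))
  )
  fit <- fitClusters(grp, kMax = 3, replicates = 2, seed = 2)
  tab <- assignmentTable(fit, grp)
  expect_equal(nrow(tab), 6 * fit@k)
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
  expect_equal(sum(tab$assigned), 6L)
})
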