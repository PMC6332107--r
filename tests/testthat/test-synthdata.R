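test_that("pair coalescence times average one coalescent unit", {
  set.seed(8)
  sims <- HaploPop:::.coalStats(2, theta = 2, reps = 3000)
  # E[M] = theta * E[T2] = theta
  expect_equal(mean(vapply(sims, `[[`, 0, "M")) / 2, 1, tolerance = 0.05)
})

test_that("total tree length matches the harmonic-sum expectation", {
  lens <- vapply(1:400, function(s) {
    tr <- simulateGenealogy(simulationConfig(demeSizes = 10L, theta = 1),
      seed = s
    )
    sum(tr$edge.length)
  }, 0)
  expect_equal(mean(lens), 2 * sum(1 / (1:9)), tolerance = 0.05)
})

test_that("without migration or a split the demes never find an ancestor", {
  cfg <- simulationConfig(demeSizes = c(3L, 3L), theta = 1)
  expect_error(simulateGenealogy(cfg, seed = 1), "unreachable")
})

test_that("cross-deme coalescences are older than the split time", {
  cfg <- simulationConfig(
    demeSizes = c(4L, 4L), theta = 1,
    splitTime = 1.5, regions = c(1L, 2L)
  )
  for (s in 1:10) {
    tr <- simulateGenealogy(cfg, seed = s)
    co <- as.matrix(stats::cophenetic(tr)) / 2 # tip-to-MRCA depths
    deme <- attr(tr, "deme")[rownames(co)]
    cross <- co[deme == 1, deme == 2]
    expect_true(all(cross >= 1.5 - 1e-9))
  }
})

test_that("mutation dropping respects its limits", {
  cfg <- simulationConfig(demeSizes = 8L, theta = 1e-6, L = 100L)
  ds <- simulateDataset(cfg, seed = 3)
  expect_equal(nrow(haplotypeCounts(collapseHaplotypes(ds@alignment))), 1L)

  # realized transversion/transition ratio decreases with kappa
  ratioAt <- function(kappa) {
    vals <- vapply(1:3, function(s) {
      cfg <- simulationConfig(
        demeSizes = 30L, theta = 12, L = 600L,
        kappa = kappa
      )
      classifySites(simulateDataset(cfg, seed = s)@alignment)$tvTsRatio
    }, 0)
    mean(vals)
  }
  expect_gt(ratioAt(2), ratioAt(30))
  expect_lt(ratioAt(30), 1)
})

test_that("datasets regenerate bit-identically from their seed", {
  cfg <- twoRegionPreset()
  d1 <- simulateDataset(cfg, seed = 5)
  d2 <- simulateDataset(cfg, seed = 5)
  expect_identical(
    as.character(alignmentSeqs(d1)),
    as.character(alignmentSeqs(d2))
  )
  expect_identical(populations(d1), populations(d2))
  dir <- tempfile()
  d3 <- simulateDataset(cfg, seed = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "simulated.fasta")))
  expect_true(file.exists(file.path(dir, "simulated.popmap.tsv")))
  manifest <- jsonlite::read_json(file.path(dir, "simulated.manifest.json"))
  expect_equal(manifest$seed, 5L)
  expect_equal(manifest$L, 710L)
})

test_that("the two-region preset shapes match the survey design", {
  cfg <- twoRegionPreset()
  expect_equal(cfg@demeSizes, c(15L, 15L, 22L, 21L, 24L))
  expect_equal(cfg@L, 710L)
  ds <- simulateDataset(cfg, seed = 2)
  expect_equal(unname(populationSizes(ds@alignment)), c(15L, 15L, 22L, 21L, 24L))
  # nearly all haplotypes unique, the control-region signature
  nh <- nrow(haplotypeCounts(collapseHaplotypes(filterSites(ds@alignment))))
  expect_gte(nh / 97, 0.9)
})

test_that("panmictic settings erase the regional structure", {
  cfg <- twoRegionPreset()
  mig <- matrix(500, 5, 5)
  diag(mig) <- 0
  pan <- simulationConfig(
    demeSizes = cfg@demeSizes, theta = cfg@theta, migration = mig,
    splitTime = NA_real_, regions = cfg@regions, kappa = cfg@kappa,
    baseFreqs = cfg@baseFreqs, L = cfg@L, expansion = cfg@expansion
  )
  phis <- vapply(1:3, function(s) {
    ds <- simulateDataset(pan, seed = s)
    amova(filterSites(ds@alignment), permutations = 0)@phiST
  }, 0)
  expect_lt(median(abs(phis)), 0.05)
})

test_that("island-model differentiation declines with migration", {
  islands <- function(mig) {
    m <- matrix(mig, 3, 3)
    diag(m) <- 0
    simulationConfig(
      demeSizes = c(8L, 8L, 8L), theta = 5, migration = m,
      L = 500L, infiniteSites = TRUE
    )
  }
  phiAt <- function(mig, seeds = 1:12) {
    median(vapply(seeds, function(s) {
      ds <- simulateDataset(islands(mig), seed = s)
      amova(ds@alignment, permutations = 0)@phiST
    }, 0))
  }
  # island-model expectation: E[T within] = d, E[T between] = d + (d-1)/(2m)
  # with m the total emigration rate, so PhiST ~ 1 - w/b; a single
  # non-recombining locus is noisy, hence the wide simulation band
  lo <- phiAt(0.5) # m_tot = 1: expectation ~ 0.25
  hi <- phiAt(10) # m_tot = 20: expectation ~ 0.016
  expect_gt(lo, hi)
  expect_gt(lo, 0.08)
  expect_lt(hi, 0.12)
})

test_that("expansion histories yield unimodal mismatch spectra", {
  set.seed(4)
  sims <- HaploPop:::.coalStats(40, theta = NA, reps = 25,
    expansion = c(10, 0.5, 100), spectrum = TRUE
  )
  localMaxima <- function(x) {
    # count strict interior peaks of the smoothed spectrum
    sm <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    sm <- sm[!is.na(sm)]
    sum(diff(sign(diff(sm))) < -1e-12)
  }
  uni <- vapply(sims, function(s) localMaxima(s$spectrum) <= 1, TRUE)
  expect_gte(mean(uni), 0.8)
})
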