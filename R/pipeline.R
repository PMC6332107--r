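#' Run configuration for the full analysis pipeline
#'
#' Defaults follow the usual practice for control-region surveys: 10,000
#' permutations for fixation-index tests, 1000 tree bootstrap replicates,
#' 10,000 coalescent replicates for neutrality p-values, model-based
#' clustering tried up to k = 10 with five restarts per k, and network
#' epsilon 0.
#'
#' @param permutations AMOVA / pairwise / Mantel permutations.
#' @param bootstrapReps NJ bootstrap replicates.
#' @param neutralityReps coalescent replicates for Tajima/Fu p-values.
#' @param gofReps mismatch goodness-of-fit bootstrap replicates.
#' @param kMax,clusterReplicates clustering search settings.
#' @param epsilon median-joining relaxation parameter.
#' @param filterPolicy `"complete"` or `"none"` site filtering.
#' @param seed master seed; stage seeds are derived from it.
#' @return a named list.
#' @export
runConfig <- function(permutations = 10000, bootstrapReps = 1000,
                      neutralityReps = 10000, gofReps = 1000, kMax = 10,
                      clusterReplicates = 5, epsilon = 0,
                      filterPolicy = "complete", seed = 1L) {
  cfg <- list(
    permutations = .checkCount(permutations, "permutations"),
    bootstrapReps = .checkCount(bootstrapReps, "bootstrapReps"),
    neutralityReps = .checkCount(neutralityReps, "neutralityReps"),
    gofReps = .checkCount(gofReps, "gofReps", min = 0L), # 0 skips the bootstrap
    kMax = .checkCount(kMax, "kMax"),
    clusterReplicates = .checkCount(clusterReplicates, "clusterReplicates"),
    epsilon = .checkCount(epsilon, "epsilon", min = 0L),
    filterPolicy = match.arg(filterPolicy, c("complete", "none")),
    seed = as.integer(seed)
  )
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: site filtering and haplotype collapsing, diversity
#' indices, K2P/NJ tree with bootstrap, median-joining network, AMOVA and
#' pairwise differentiation, model-based clustering, neutrality tests and
#' mismatch-expansion fits, and the saturation assessment. All outputs are
#' written under `outDir`; failures of individual downstream stages are
#' recorded in the log without aborting the remainder. Reruns with the same
#' inputs and config are byte-identical.
#'
#' @param fastaPath,popmapPath input files (see [readAlignment()]), or pass
#'   `aln` directly.
#' @param outDir output directory (created).
#' @param config a list from [runConfig()].
#' @param aln optionally a ready [PopAlignment] instead of file paths.
#' @param geographic optional population distance matrix for the Mantel
#'   isolation-by-distance test.
#' @return invisibly, a list with every stage's results plus `log` and
#'   `errors`.
#' @export
runPipeline <- function(fastaPath = NULL, popmapPath = NULL, outDir,
                        config = runConfig(), aln = NULL,
                        geographic = NULL) {
  t0 <- Sys.time()
  log <- character()
  errors <- list()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      note("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  # fail fast on inputs: an invalid alignment/popmap aborts the run
  if (is.null(aln)) aln <- readAlignment(fastaPath, popmapPath)
  note(
    "input: %d sequences x %d sites, %d populations",
    nSequences(aln), alignmentWidth(aln), nlevels(aln@population)
  )
  flt <- filterSites(aln, config$filterPolicy)
  note("filtered alignment: %d sites retained", alignmentWidth(flt))
  haps <- collapseHaplotypes(flt)
  writeHaplotypeFasta(haps, file.path(outDir, "haplotypes.fasta"))
  sites <- classifySites(flt)
  writeSiteClasses(sites, file.path(outDir, "sites.tsv"))

  results <- list(alignment = flt, haplotypes = haps, sites = sites)

  results$diversity <- stage("diversity", {
    tab <- diversityTable(flt)
    .writeTsv(tab, file.path(outDir, "table1_diversity.tsv"))
    note("diversity: pooled Hd=%.3f", tab$Hd[nrow(tab)])
    tab
  })

  results$tree <- stage("phylo", {
    tr <- bootstrapSupport(haps,
      reps = config$bootstrapReps,
      seed = .subSeed(config$seed, 2L)
    )
    writeNewick(tr, file.path(outDir, "nj_haplotypes.nwk"))
    note("NJ tree with %d bootstrap replicates", config$bootstrapReps)
    tr
  })

  results$network <- stage("network", {
    net <- buildMjNetwork(haps, epsilon = config$epsilon)
    exportNetwork(net,
      gmlPath = file.path(outDir, "network.gml"),
      edgesPath = file.path(outDir, "network_edges.tsv"),
      nodesPath = file.path(outDir, "network_nodes.tsv")
    )
    note("MJ network: total length %d", networkLength(net))
    net
  })

  results$amova <- stage("amova", {
    am <- amova(flt,
      permutations = config$permutations,
      seed = .subSeed(config$seed, 3L)
    )
    .writeTsv(amovaTable(am), file.path(outDir, "table2_amova.tsv"))
    note("AMOVA PhiST=%.3f (p=%.4g)", am@phiST, am@p)
    am
  })

  results$pairwise <- stage("pairwise", {
    fst <- pairwiseFst(flt,
      mode = "frequency",
      permutations = config$permutations, seed = .subSeed(config$seed, 4L)
    )
    phist <- pairwiseFst(flt,
      mode = "distance",
      permutations = config$permutations, seed = .subSeed(config$seed, 5L)
    )
    da <- correctedDa(flt,
      permutations = config$permutations,
      seed = .subSeed(config$seed, 6L)
    )
    .writeTsv(
      pairwiseTable(da, fst),
      file.path(outDir, "table3_da_fst.tsv")
    )
    .writeTsv(
      as.data.frame(fst@p),
      file.path(outDir, "table3_fst_pvalues.tsv")
    )
    list(fst = fst, phist = phist, da = da)
  })

  results$mantel <- if (!is.null(geographic)) {
    stage("mantel", {
      gen <- results$pairwise$fst@stat
      mt <- mantelTest(gen, geographic,
        permutations = config$permutations,
        seed = .subSeed(config$seed, 7L)
      )
      note("Mantel r=%.3f (p=%.4g)", mt$r, mt$p)
      mt
    })
  } else {
    NULL
  }

  results$clusters <- stage("clustering", {
    cl <- fitClusters(flt,
      kMax = config$kMax,
      replicates = config$clusterReplicates,
      seed = .subSeed(config$seed, 8L)
    )
    .writeTsv(assignmentTable(cl, flt), file.path(outDir, "assignments.tsv"))
    note("clustering: k=%d", cl@k)
    cl
  })

  results$neutrality <- stage("neutrality", {
    tab <- neutralityTable(flt,
      reps = config$neutralityReps,
      seed = .subSeed(config$seed, 9L)
    )
    tab
  })

  results$mismatch <- stage("mismatch", {
    mm <- mismatchTable(flt,
      bootstrapReps = config$gofReps,
      seed = .subSeed(config$seed, 10L)
    )
    for (nm in names(mm$spectra)) {
      .writeTsv(
        data.frame(
          differences = seq_along(mm$spectra[[nm]]) - 1L,
          frequency = mm$spectra[[nm]]
        ),
        file.path(outDir, sprintf("mismatch_%s.tsv", nm))
      )
    }
    mm
  })

  if (!is.null(results$neutrality) && !is.null(results$mismatch)) {
    .writeTsv(
      merge(results$neutrality, results$mismatch$table, by = "population", sort = FALSE),
      file.path(outDir, "table4_demography.tsv")
    )
  }

  results$saturation <- stage("saturation", {
    sat <- issTest(flt, seed = .subSeed(config$seed, 11L))
    siteEntropyTable(sat, file.path(outDir, "site_entropy.tsv"))
    note("ISS=%.4f ISS.c=%.4f", sat@iss, sat@issC)
    sat
  })

  writeReport(results, outDir)
  note("pipeline finished in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  results$log <- log
  results$errors <- errors
  writeLines(log, file.path(outDir, "pipeline.log"))
  invisible(results)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = ""
  )
  invisible(path)
}

#' AMOVA result as a report table
#'
#' @param am an [AmovaResult].
#' @return data.frame shaped like a standard AMOVA table (sums of squares,
#'   variance components, percentages, PhiST with its permutation p).
#' @export
amovaTable <- function(am) {
  data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(am@df, sum(am@df)),
    sumOfSquares = round(c(am@ss, sum(am@ss)), 3),
    varianceComponent = round(c(am@va, am@vb, am@va + am@vb), 3),
    percentage = round(c(am@pctAmong, am@pctWithin, 100), 2),
    phiST = c(round(am@phiST, 3), NA, NA),
    p = c(am@p, NA, NA)
  )
}

#' Combined Da / FST matrix table
#'
#' Da above the diagonal, FST below, the conventional compact layout for
#' pairwise differentiation reports.
#'
#' @param da,fst [PairwiseStats] objects with method `"da"` and `"fst"`.
#' @param digits rounding for display.
#' @return data.frame.
#' @export
pairwiseTable <- function(da, fst, digits = 4) {
  m <- fst@stat
  m[upper.tri(m)] <- da@stat[upper.tri(da@stat)]
  m <- round(m, digits)
  out <- data.frame(population = rownames(m), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m))
}

#' Write a human-readable markdown summary of a pipeline run
#'
#' @param results the list produced by [runPipeline()].
#' @param outDir directory for `summary.md`.
#' @return the path, invisibly.
#' @export
writeReport <- function(results, outDir) {
  lines <- c("# Haplotype population analysis summary", "")
  if (!is.null(results$alignment)) {
    lines <- c(lines, sprintf(
      "- %d sequences, %d filtered sites, %d populations, %d haplotypes",
      nSequences(results$alignment), alignmentWidth(results$alignment),
      nlevels(results$alignment@population),
      nrow(results$haplotypes@counts)
    ))
  }
  if (!is.null(results$sites)) {
    s <- results$sites
    lines <- c(lines, sprintf(
      "- %d polymorphic sites (%d informative, %d singleton); Tv/Ts = %.4f",
      s$polymorphicSites, s$informativeSites, s$singletonSites, s$tvTsRatio
    ))
  }
  if (!is.null(results$amova)) {
    am <- results$amova
    lines <- c(lines, sprintf(
      "- AMOVA: PhiST = %.3f (%.2f%% among populations), p = %.4g",
      am@phiST, am@pctAmong, am@p
    ))
  }
  if (!is.null(results$clusters)) {
    lines <- c(lines, sprintf(
      "- Model-based clustering: k = %d groups", results$clusters@k
    ))
  }
  if (!is.null(results$saturation)) {
    sat <- results$saturation
    lines <- c(lines, sprintf(
      "- Substitution saturation: ISS = %.4f vs ISS.c = %.4f (%s)",
      sat@iss, sat@issC,
      if (sat@saturated) "saturation suspected" else "not saturated"
    ))
  }
  if (length(results$errors)) {
    lines <- c(lines, "", "## Stage errors", "")
    lines <- c(lines, sprintf(
      "- %s: %s", names(results$errors),
      unlist(results$errors)
    ))
  }
  path <- file.path(outDir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}
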