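#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Aligned sequences with a population assignment
#'
#' The central container consumed by every analysis stage: an aligned set of
#' equal-length nucleotide sequences (one per sampled individual) together
#' with the locality each individual was collected from.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width, uniquely named
#'   sequences over the alphabet A, C, G, T, N, `-`.
#' @slot population a named factor assigning every sequence id to a
#'   population label; levels give the population ordering used in reports.
#'
#' @exportClass PopAlignment
setClass("PopAlignment",
  slots = c(seqs = "DNAStringSet", population = "factor")
)

setValidity("PopAlignment", function(object) {
  s <- object@seqs
  msg <- character()
  if (length(s) == 0L) msg <- c(msg, "alignment contains no sequences")
  if (length(s) > 0L) {
    w <- Biostrings::width(s)
    if (length(unique(w)) > 1L) {
      bad <- names(s)[w != w[1L]][1L]
      msg <- c(msg, sprintf(
        "sequences are not aligned: '%s' has length %d, expected %d",
        bad, w[w != w[1L]][1L], w[1L]
      ))
    }
    if (w[1L] == 0L) msg <- c(msg, "alignment has zero columns")
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == "")) {
      msg <- c(msg, "sequence ids must be unique and non-empty")
    }
    letters <- Biostrings::uniqueLetters(s)
    bad <- setdiff(letters, c("A", "C", "G", "T", "N", "-"))
    if (length(bad)) {
      msg <- c(msg, sprintf(
        "unsupported characters in alignment: %s (only A,C,G,T,N,- allowed)",
        paste(bad, collapse = ",")
      ))
    }
  }
  if (length(object@population) != length(s)) {
    msg <- c(msg, "population assignment length differs from sequence count")
  } else if (!identical(names(object@population), names(s))) {
    msg <- c(msg, "population assignment names must match sequence ids")
  }
  if (length(msg)) msg else TRUE
})

#' Collapsed haplotype table
#'
#' Distinct sequences (after site filtering) with per-population carrier
#' counts. Haplotypes are ordered by first occurrence in the source
#' alignment and named H1, H2, ...
#'
#' @slot haplotypes a [Biostrings::DNAStringSet] of the distinct sequences.
#' @slot counts integer matrix, haplotypes x populations; column sums equal
#'   the population sample sizes.
#' @slot membership integer vector mapping each source individual to the row
#'   of its haplotype.
#'
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  slots = c(
    haplotypes = "DNAStringSet", counts = "matrix",
    membership = "integer"
  )
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  cts <- object@counts
  if (nrow(cts) != length(object@haplotypes)) {
    msg <- c(msg, "count matrix rows must match number of haplotypes")
  }
  if (any(cts < 0) || any(cts != round(cts))) {
    msg <- c(msg, "counts must be nonnegative integers")
  }
  if (sum(cts) != length(object@membership)) {
    msg <- c(msg, "counts must sum to the number of individuals")
  }
  if (length(msg)) msg else TRUE
})

#' One-level analysis of molecular variance result
#'
#' @slot df numeric(2): among- and within-population degrees of freedom.
#' @slot ss numeric(2): among- and within-population sums of squares.
#' @slot va,vb among- and within-population variance components.
#' @slot phiST fixation index Va/(Va+Vb).
#' @slot pctAmong,pctWithin percentage of total variance.
#' @slot p permutation p-value (NA when permutations were not run).
#' @slot permutations number of permutations used.
#'
#' @exportClass AmovaResult
setClass("AmovaResult",
  slots = c(
    df = "numeric", ss = "numeric", va = "numeric", vb = "numeric",
    phiST = "numeric", pctAmong = "numeric", pctWithin = "numeric",
    p = "numeric", permutations = "numeric"
  )
)

#' Pairwise population differentiation matrices
#'
#' @slot stat matrix of the statistic (FST, PhiST or Da) with populations on
#'   rows and columns; zero diagonal.
#' @slot p matrix of permutation p-values (NA diagonal / when not run).
#' @slot method character label ("fst", "phist" or "da").
#'
#' @exportClass PairwiseStats
setClass("PairwiseStats",
  slots = c(stat = "matrix", p = "matrix", method = "character")
)

#' Mismatch-distribution fit under the sudden-expansion model
#'
#' @slot observed observed relative frequencies of pairwise difference
#'   counts, classes 0..d.
#' @slot expected fitted model spectrum over the same classes (tail mass
#'   aggregated into the last class).
#' @slot tau expansion time in mutational units (2ut).
#' @slot theta0,theta1 pre- and post-expansion scaled population sizes.
#' @slot ssd sum of squared deviations between observed and expected.
#' @slot raggedness Harpending's raggedness index of the observed spectrum.
#' @slot pSSD,pRaggedness parametric-bootstrap p-values (NA when not run).
#' @slot converged FALSE when the optimiser stopped at the coarse grid.
#'
#' @exportClass MismatchFit
setClass("MismatchFit",
  slots = c(
    observed = "numeric", expected = "numeric", tau = "numeric",
    theta0 = "numeric", theta1 = "numeric", ssd = "numeric",
    raggedness = "numeric", pSSD = "numeric", pRaggedness = "numeric",
    converged = "logical"
  )
)

#' Model-based cluster assignment of individuals
#'
#' @slot k number of clusters in the best-scoring partition.
#' @slot labels integer cluster label per individual (named by id).
#' @slot logMarginal Dirichlet-multinomial log marginal likelihood of the
#'   returned partition.
#' @slot membership individuals x clusters matrix of assignment
#'   probabilities; rows sum to 1.
#' @slot replicateScores data.frame of (k, replicate, score) for every
#'   search restart.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
  slots = c(
    k = "integer", labels = "integer", logMarginal = "numeric",
    membership = "matrix", replicateScores = "data.frame"
  )
)

#' Median-joining haplotype network
#'
#' @slot graph an [igraph::igraph] object; vertices are observed haplotypes
#'   plus inferred median vectors, edge attribute `weight` is the number of
#'   substitutions.
#' @slot nodes data.frame with one row per vertex: id, type
#'   ("observed"/"median"), total frequency, and per-population frequencies.
#' @slot sequences character vector of the segregating-site state strings
#'   backing each vertex.
#'
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  slots = c(graph = "ANY", nodes = "data.frame", sequences = "character")
)

#' Substitution-saturation assessment
#'
#' @slot hObs mean observed per-site entropy (bits).
#' @slot hFss Monte-Carlo mean per-site entropy under full saturation.
#' @slot iss observed saturation index hObs/hFss.
#' @slot issC simulation-derived critical value.
#' @slot p one-sided Monte-Carlo p-value for iss >= full-saturation values.
#' @slot siteEntropies per-site entropy vector (bits).
#' @slot saturated logical flag.
#'
#' @exportClass SaturationResult
setClass("SaturationResult",
  slots = c(
    hObs = "numeric", hFss = "numeric", iss = "numeric", issC = "numeric",
    p = "numeric", siteEntropies = "numeric", saturated = "logical"
  )
)

#' Simulated dataset with known truth
#'
#' @slot alignment a [PopAlignment] produced by the coalescent simulator.
#' @slot genealogy the generating genealogy as an [ape::phylo] tree with
#'   branch lengths in coalescent units.
#' @slot config the [SimulationConfig] used.
#' @slot seed integer seed the dataset regenerates from bit-identically.
#'
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  slots = c(
    alignment = "PopAlignment", genealogy = "ANY", config = "ANY",
    seed = "integer"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "PopAlignment", function(object) {
  cat(sprintf(
    "PopAlignment: %d sequences x %d sites, %d populations\n",
    length(object@seqs), Biostrings::width(object@seqs)[1L],
    nlevels(object@population)
  ))
  tab <- table(object@population)
  cat(paste(sprintf("  %s: n=%d", names(tab), as.integer(tab)),
    collapse = "\n"
  ), "\n")
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: %d haplotypes from %d individuals, %d populations\n",
    nrow(object@counts), sum(object@counts), ncol(object@counts)
  ))
  singletons <- sum(rowSums(object@counts) == 1L)
  cat(sprintf("  singleton haplotypes: %d\n", singletons))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (one level)\n")
  cat(sprintf(
    "  Among populations : df=%d  SS=%.3f  Va=%.3f  (%.2f%%)\n",
    object@df[1L], object@ss[1L], object@va, object@pctAmong
  ))
  cat(sprintf(
    "  Within populations: df=%d  SS=%.3f  Vb=%.3f  (%.2f%%)\n",
    object@df[2L], object@ss[2L], object@vb, object@pctWithin
  ))
  cat(sprintf("  PhiST = %.3f", object@phiST))
  if (!is.na(object@p)) {
    cat(sprintf("  (p = %.4g, %d permutations)", object@p,
      as.integer(object@permutations)))
  }
  cat("\n")
})

setMethod("show", "MismatchFit", function(object) {
  cat("Sudden-expansion mismatch fit\n")
  cat(sprintf(
    "  tau=%.4f  theta0=%.4f  theta1=%.4f  SSD=%.5f  raggedness=%.5f\n",
    object@tau, object@theta0, object@theta1, object@ssd, object@raggedness
  ))
  if (!is.na(object@pSSD)) {
    cat(sprintf(
      "  p(SSD)=%.4f  p(raggedness)=%.4f\n", object@pSSD, object@pRaggedness
    ))
  }
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: k=%d clusters, log marginal likelihood %.3f\n",
    object@k, object@logMarginal
  ))
  print(table(cluster = object@labels))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  nobs <- sum(object@nodes$type == "observed")
  nmed <- sum(object@nodes$type == "median")
  cat(sprintf(
    "HaplotypeNetwork: %d observed haplotypes, %d median vectors, %d edges (total length %d)\n",
    nobs, nmed, igraph::ecount(object@graph),
    sum(igraph::E(object@graph)$weight)
  ))
})

setMethod("show", "SaturationResult", function(object) {
  cat(sprintf(
    "Saturation: ISS=%.4f  ISS.c=%.4f  -> %s (p=%.4g)\n",
    object@iss, object@issC,
    if (object@saturated) "saturation suspected" else "not saturated",
    object@p
  ))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (seed %d)\n", object@seed))
  show(object@alignment)
})

## ---- accessors ----------------------------------------------------------

#' Accessors for HaploPop containers
#'
#' `alignmentSeqs()` returns the `DNAStringSet`; `populations()` the named
#' population factor; `populationSizes()` the per-population sample sizes;
#' `haplotypes()` the distinct sequences of a [HaplotypeTable];
#' `haplotypeCounts()` the haplotype x population count matrix.
#'
#' @param x a [PopAlignment] or [HaplotypeTable].
#' @return see the individual descriptions.
#' @name accessors
#' @aliases alignmentSeqs populations populationSizes haplotypes
#'   haplotypeCounts
NULL

#' @rdname accessors
#' @export
setGeneric("alignmentSeqs", function(x) standardGeneric("alignmentSeqs"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("populationSizes", function(x) standardGeneric("populationSizes"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

setMethod("alignmentSeqs", "PopAlignment", function(x) x@seqs)
setMethod("populations", "PopAlignment", function(x) x@population)
setMethod("populationSizes", "PopAlignment", function(x) {
  tab <- table(x@population)
  stats::setNames(as.integer(tab), names(tab))
})
setMethod("haplotypes", "HaplotypeTable", function(x) x@haplotypes)
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)
setMethod("alignmentSeqs", "SimulatedDataset", function(x) {
  x@alignment@seqs
})
setMethod("populations", "SimulatedDataset", function(x) {
  x@alignment@population
})

#' Number of sequences and alignment width
#'
#' @param x a [PopAlignment].
#' @return integer scalar.
#' @export
nSequences <- function(x) length(x@seqs)

#' @rdname nSequences
#' @export
alignmentWidth <- function(x) {
  if (length(x@seqs) == 0L) 0L else Biostrings::width(x@seqs)[1L]
}
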