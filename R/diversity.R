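#' Nei's haplotype (gene) diversity with standard deviation
#'
#' Hd = n/(n-1) * (1 - sum p_i^2), the unbiased probability that two
#' sequences drawn without replacement carry different haplotypes, with
#' Nei's (1987) sampling variance of heterozygosity:
#' V = 2/(n(n-1)) * ( 2(n-2) * (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2 ).
#'
#' @param counts vector of haplotype carrier counts (zeros allowed).
#' @param n sample size; defaults to `sum(counts)`.
#' @return named numeric: `Hd`, `sd`.
#' @examples
#' haplotypeDiversity(rep(1, 15)) # all unique: exactly 1
#' haplotypeDiversity(c(2, rep(1, 20))) # 0.996
#' @export
haplotypeDiversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (sum(counts) != n) stop("counts must sum to n", call. = FALSE)
  if (n < 2L) stop("haplotype diversity needs n >= 2", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(Hd = hd, sd = sqrt(max(v, 0)))
}

# Tajima (1989) total variance of the mean pairwise difference estimate,
# b1*M + b2*M^2 (stochastic + sampling components).
.pairwiseDiffVariance <- function(m, n) {
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  b1 * m + b2 * m^2
}

#' Mean pairwise differences, segregating sites and nucleotide diversity
#'
#' M is the average Hamming distance over all n(n-1)/2 sequence pairs; S the
#' number of variable columns; pi = M / L the per-site nucleotide diversity
#' on the filtered length L. Standard deviations use Tajima's (1989) total
#' variance (stochastic plus sampling), so SD is roughly M/2 at the
#' diversity levels typical of control-region data.
#'
#' @param aln a [PopAlignment] after [filterSites()]; n >= 2.
#' @return named numeric: `n`, `S`, `M`, `Msd`, `pi`, `piSd`, `L`.
#' @export
pairwiseDifferenceStats <- function(aln) {
  n <- length(aln@seqs)
  if (n < 2L) stop("pairwise statistics need n >= 2", call. = FALSE)
  im <- .intMatrix(aln@seqs)
  d <- .hammingMatrix(im)
  m <- mean(.condensed(d))
  s <- sum(apply(im, 2L, function(col) length(unique(col)) > 1L))
  L <- ncol(im)
  v <- .pairwiseDiffVariance(m, n)
  c(
    n = n, S = s, M = m, Msd = sqrt(v),
    pi = m / L, piSd = sqrt(v) / L, L = L
  )
}

#' Per-population and pooled diversity report
#'
#' One row per population plus a pooled row, with the columns of a standard
#' summary table: N, Nh, Np, Tv/Ts, M +/- SD, Hd +/- SD, pi +/- SD.
#'
#' @param aln a filtered [PopAlignment].
#' @return a data.frame.
#' @export
diversityTable <- function(aln) {
  pops <- levels(aln@population)
  rows <- lapply(c(pops, "Pooled"), function(p) {
    sub <- if (p == "Pooled") aln else subsetPopulations(aln, p)
    haps <- collapseHaplotypes(sub)
    cls <- classifySites(sub)
    pds <- pairwiseDifferenceStats(sub)
    hd <- haplotypeDiversity(rowSums(haps@counts))
    data.frame(
      population = p, N = unname(pds["n"]), Nh = nrow(haps@counts),
      Np = cls$polymorphicSites, TvTs = cls$tvTsRatio,
      M = unname(pds["M"]), Msd = unname(pds["Msd"]),
      Hd = unname(hd["Hd"]), HdSd = unname(hd["sd"]),
      pi = unname(pds["pi"]), piSd = unname(pds["piSd"]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Restrict an alignment to a subset of populations
#'
#' @param aln a [PopAlignment].
#' @param pops character vector of population labels to keep.
#' @return a [PopAlignment] on those individuals (population levels reduced).
#' @export
subsetPopulations <- function(aln, pops) {
  keep <- aln@population %in% pops
  if (!any(keep)) stop("no individuals in the requested populations", call. = FALSE)
  pop <- factor(aln@population[keep], levels = pops)
  names(pop) <- names(aln@population)[keep]
  out <- methods::new("PopAlignment", seqs = aln@seqs[keep], population = pop)
  attr(out, "siteMap") <- attr(aln, "siteMap")
  out
}
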