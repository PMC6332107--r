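#' AMOVA variance components from sums of squares
#'
#' One-level analysis of molecular variance on squared inter-individual
#' distances. Given among- and within-population sums of squares and the
#' population sample sizes, the variance components are
#' Vb = SS_within/(N-k) and Va = (SS_among/(k-1) - Vb)/n' with
#' n' = (N - sum(n_i^2)/N)/(k-1), and PhiST = Va/(Va+Vb).
#'
#' @param ssAmong,ssWithin sums of squares among and within populations.
#' @param sizes integer vector of population sample sizes.
#' @return an [AmovaResult] (without a permutation p-value).
#' @examples
#' # variance components from a published AMOVA table's sums of squares
#' amovaComponents(1097.095, 1309.117, c(15, 15, 22, 21, 24))
#' @export
amovaComponents <- function(ssAmong, ssWithin, sizes) {
  ssAmong <- unname(ssAmong)
  ssWithin <- unname(ssWithin)
  k <- length(sizes)
  n <- sum(sizes)
  if (k < 2L) stop("AMOVA needs at least two populations", call. = FALSE)
  dfAmong <- k - 1
  dfWithin <- n - k
  vb <- ssWithin / dfWithin
  nPrime <- (n - sum(sizes^2) / n) / (k - 1)
  va <- (ssAmong / dfAmong - vb) / nPrime
  tot <- va + vb
  phi <- if (tot > 0) va / tot else NA_real_
  methods::new("AmovaResult",
    df = c(dfAmong, dfWithin), ss = c(ssAmong, ssWithin),
    va = va, vb = vb, phiST = phi,
    pctAmong = 100 * va / tot, pctWithin = 100 * vb / tot,
    p = NA_real_, permutations = 0
  )
}

# Squared-distance sums of squares for a grouping; dsq is the full matrix of
# squared inter-individual distances (pairwise difference counts by default).
.amovaSS <- function(dsq, groups) {
  n <- nrow(dsq)
  ssTotal <- sum(dsq[lower.tri(dsq)]) / n
  ssWithin <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- dsq[idx, idx]
      ssWithin <- ssWithin + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  c(among = ssTotal - ssWithin, within = ssWithin)
}

#' One-level AMOVA with permutation test
#'
#' Squared inter-individual distances are the raw pairwise nucleotide
#' difference counts (the haplotypic convention) unless `dsq` supplies
#' another matrix (e.g. squared Kimura distances). Significance is assessed
#' by permuting individuals among populations and recomputing PhiST.
#'
#' @param aln a filtered [PopAlignment] with at least two populations.
#' @param permutations number of label permutations (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @param dsq optional user squared-distance matrix (individuals x
#'   individuals, same order as the alignment).
#' @return an [AmovaResult]. Negative variance components are reported as
#'   computed.
#' @export
amova <- function(aln, permutations = 10000, seed = 1L, dsq = NULL) {
  groups <- aln@population
  k <- nlevels(groups)
  if (k < 2L) stop("AMOVA needs at least two populations", call. = FALSE)
  if (is.null(dsq)) dsq <- .hammingMatrix(.intMatrix(aln@seqs))
  # canonical individual order (by id) so permutation p-values do not
  # depend on the input row order
  ord <- order(names(groups))
  groups <- groups[ord]
  dsq <- dsq[ord, ord]
  sizes <- as.integer(table(groups))
  ss <- .amovaSS(dsq, groups)
  res <- amovaComponents(ss["among"], ss["within"], sizes)
  if (all(dsq == 0)) {
    res@p <- NA_real_
    return(res)
  }
  if (permutations > 0) {
    set.seed(seed)
    obs <- res@phiST
    phiPerm <- replicate(permutations, {
      g <- factor(sample(as.integer(groups)), levels = seq_len(k))
      ssp <- .amovaSS(dsq, g)
      r <- amovaComponents(ssp["among"], ssp["within"], sizes)
      r@phiST
    })
    res@p <- mean(phiPerm >= obs, na.rm = TRUE)
    res@permutations <- permutations
  }
  res
}

# Weir & Cockerham theta for haploid data at a single multi-allelic locus
# (haplotypes as alleles). countsByPop: alleles x populations count matrix.
.weirCockerhamTheta <- function(countsByPop) {
  sizes <- colSums(countsByPop)
  r <- ncol(countsByPop)
  n <- sum(sizes)
  nc <- (n - sum(sizes^2) / n) / (r - 1)
  p <- sweep(countsByPop, 2L, sizes, "/")
  pbar <- as.numeric(countsByPop %*% rep(1, r)) / n
  msaNum <- 0
  denom <- 0
  for (a in seq_len(nrow(countsByPop))) {
    msa <- sum(sizes * (p[a, ] - pbar[a])^2) / (r - 1)
    msw <- sum(sizes * p[a, ] * (1 - p[a, ])) / sum(sizes - 1)
    msaNum <- msaNum + (msa - msw)
    denom <- denom + msa + (nc - 1) * msw
  }
  if (denom == 0) {
    return(0)
  }
  msaNum / denom
}

# Two-population distance-based PhiST (AMOVA restricted to the pair).
.pairPhiST <- function(dsq, groups) {
  sizes <- as.integer(table(groups))
  ss <- .amovaSS(dsq, groups)
  amovaComponents(ss["among"], ss["within"], sizes)@phiST
}

#' Pairwise population differentiation (FST / PhiST)
#'
#' `mode = "frequency"` computes the Weir-Cockerham theta treating each
#' haplotype as an allele at one haploid locus; `mode = "distance"` computes
#' the two-population AMOVA PhiST on pairwise difference counts. P-values
#' come from reshuffling individuals between the two populations.
#'
#' @param aln a filtered [PopAlignment].
#' @param mode `"frequency"` or `"distance"`.
#' @param permutations permutations per pair (0 skips p-values).
#' @param seed RNG seed.
#' @return a [PairwiseStats] with the statistic matrix and p-value matrix.
#' @export
pairwiseFst <- function(aln, mode = c("frequency", "distance"),
                        permutations = 10000, seed = 1L) {
  mode <- match.arg(mode)
  pops <- levels(aln@population)
  k <- length(pops)
  haps <- collapseHaplotypes(aln)
  dsqFull <- if (mode == "distance") .hammingMatrix(.intMatrix(aln@seqs)) else NULL
  stat <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- which(aln@population %in% pops[c(i, j)])
      idx <- idx[order(names(aln@population)[idx])] # canonical order
      groups <- droplevels(aln@population[idx])
      if (any(table(groups) < 2L)) {
        warning(sprintf(
          "population pair %s/%s has a sample of size < 2", pops[i], pops[j]
        ), call. = FALSE)
      }
      if (mode == "frequency") {
        cts <- haps@counts[, c(i, j), drop = FALSE]
        cts <- cts[rowSums(cts) > 0L, , drop = FALSE]
        obs <- .weirCockerhamTheta(cts)
        statFun <- function(g) {
          tab <- table(
            factor(haps@membership[idx], levels = seq_len(nrow(haps@counts))),
            g
          )
          .weirCockerhamTheta(matrix(as.numeric(tab), nrow = nrow(tab)))
        }
      } else {
        dsq <- dsqFull[idx, idx]
        obs <- .pairPhiST(dsq, groups)
        statFun <- function(g) .pairPhiST(dsq, g)
      }
      stat[i, j] <- stat[j, i] <- obs
      if (permutations > 0 && is.finite(obs)) {
        perm <- replicate(permutations, {
          g <- factor(sample(as.integer(groups)), levels = 1:2)
          statFun(g)
        })
        p <- mean(perm >= obs, na.rm = TRUE)
        pmat[i, j] <- pmat[j, i] <- p
      }
    }
  }
  methods::new("PairwiseStats",
    stat = stat, p = pmat,
    method = if (mode == "frequency") "fst" else "phist"
  )
}

#' Corrected average pairwise difference between populations
#'
#' Da = PiXY - (PiX + PiY)/2, where PiXY is the mean number of pairwise
#' differences between sequences of populations X and Y and PiX, PiY the
#' within-population means. Negative values are reported as computed.
#'
#' @param aln a filtered [PopAlignment]; every population needs n >= 2.
#' @param permutations permutations per pair for a one-sided p-value
#'   (0 skips).
#' @param seed RNG seed.
#' @return a [PairwiseStats] with method `"da"`.
#' @export
correctedDa <- function(aln, permutations = 0, seed = 1L) {
  pops <- levels(aln@population)
  k <- length(pops)
  sizes <- table(aln@population)
  if (any(sizes < 2L)) {
    stop("corrected Da needs n >= 2 in every population", call. = FALSE)
  }
  d <- .hammingMatrix(.intMatrix(aln@seqs))
  daOf <- function(groups) {
    within <- vapply(levels(groups), function(g) {
      idx <- which(groups == g)
      sub <- d[idx, idx]
      mean(sub[lower.tri(sub)])
    }, 0)
    m <- matrix(0, nlevels(groups), nlevels(groups))
    for (a in seq_len(nlevels(groups) - 1L)) {
      for (b in (a + 1L):nlevels(groups)) {
        cross <- mean(d[groups == levels(groups)[a], groups == levels(groups)[b]])
        m[a, b] <- m[b, a] <- cross - (within[a] + within[b]) / 2
      }
    }
    m
  }
  da <- daOf(aln@population)
  dimnames(da) <- list(pops, pops)
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  if (permutations > 0) {
    set.seed(seed)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        idx <- which(aln@population %in% pops[c(i, j)])
        idx <- idx[order(names(aln@population)[idx])] # canonical order
        groups <- droplevels(aln@population[idx])
        dsub <- d[idx, idx]
        obs <- da[i, j]
        perm <- replicate(permutations, {
          g <- factor(sample(as.integer(groups)), levels = 1:2)
          dp <- dsub
          w <- vapply(1:2, function(a) {
            ii <- which(as.integer(g) == a)
            s <- dp[ii, ii]
            mean(s[lower.tri(s)])
          }, 0)
          mean(dp[as.integer(g) == 1L, as.integer(g) == 2L]) - mean(w)
        })
        pmat[i, j] <- pmat[j, i] <- mean(perm >= obs)
      }
    }
  }
  methods::new("PairwiseStats", stat = da, p = pmat, method = "da")
}

#' Bonferroni correction flags for a p-value matrix
#'
#' Flags entry (i, j) significant when p <= alpha/m with m the number of
#' distinct comparisons; also annotates the conventional reporting tiers
#' (`"**"` for alpha 0.01, `"*"` for alpha 0.10 after correction).
#'
#' @param p a symmetric p-value matrix (or vector).
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons; default: number of non-NA off-diagonal
#'   pairs (or vector entries).
#' @return a list with `significant` (logical like `p`), `tiers` (character
#'   like `p`, `""`/`"*"`/`"**"`), and `m`.
#' @export
bonferroniAdjust <- function(p, alpha = 0.05, m = NULL) {
  if (is.matrix(p)) {
    vals <- p[upper.tri(p)]
    if (is.null(m)) m <- sum(!is.na(vals))
  } else if (is.null(m)) {
    m <- sum(!is.na(p))
  }
  m <- max(m, 1L)
  sig <- !is.na(p) & p <= alpha / m
  tiers <- ifelse(!is.na(p) & p <= 0.01 / m, "**",
    ifelse(!is.na(p) & p <= 0.10 / m, "*", "")
  )
  if (is.matrix(p)) {
    diag(sig) <- NA
    diag(tiers) <- ""
  }
  list(significant = sig, tiers = tiers, m = m)
}

#' Mantel test of matrix correlation (isolation by distance)
#'
#' Pearson correlation between the off-diagonal entries of two symmetric
#' distance matrices, with significance from random (or, when `exact`,
#' exhaustive) permutations of the rows and columns of the second matrix.
#' The one-sided p-value counts permutations with r >= observed; for random
#' permutations the observed configuration is included in both numerator
#' and denominator.
#'
#' @param genetic,geographic symmetric matrices with matching dimnames
#'   (k >= 3).
#' @param permutations number of random permutations.
#' @param seed RNG seed.
#' @param exact enumerate all k! permutations (exact p); default when
#'   k! <= `permutations`.
#' @return list with `r`, `r2`, `p`, `permutations`, `exact`.
#' @export
mantelTest <- function(genetic, geographic, permutations = 10000, seed = 1L,
                       exact = NULL) {
  genetic <- as.matrix(genetic)
  geographic <- as.matrix(geographic)
  k <- nrow(genetic)
  if (k < 3L) stop("Mantel test needs at least 3 items", call. = FALSE)
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic))) {
    if (!identical(rownames(genetic), rownames(geographic))) {
      geographic <- geographic[rownames(genetic), rownames(genetic)]
    }
  }
  x <- genetic[lower.tri(genetic)]
  if (stats::sd(x) == 0 || stats::sd(geographic[lower.tri(geographic)]) == 0) {
    return(list(
      r = NA_real_, r2 = NA_real_, p = NA_real_,
      permutations = 0L, exact = FALSE, flag = "zero-variance matrix"
    ))
  }
  rOf <- function(gg) stats::cor(x, gg[lower.tri(gg)])
  obs <- rOf(geographic)
  if (is.null(exact)) exact <- factorial(k) <= permutations
  if (exact) {
    perms <- .allPermutations(k)
    rs <- vapply(perms, function(pm) rOf(geographic[pm, pm]), 0)
    p <- mean(rs >= obs - 1e-12)
    nperm <- length(perms)
  } else {
    set.seed(seed)
    rs <- replicate(permutations, {
      pm <- sample.int(k)
      rOf(geographic[pm, pm])
    })
    p <- (1 + sum(rs >= obs - 1e-12)) / (1 + permutations)
    nperm <- permutations
  }
  list(r = obs, r2 = obs^2, p = p, permutations = nperm, exact = exact)
}

.allPermutations <- function(k) {
  if (k == 1L) {
    return(list(1L))
  }
  sub <- .allPermutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (s in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(s, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Great-circle distance matrix from coordinates
#'
#' Convenience helper for building a geographic matrix from sampling-site
#' coordinates. Note that for coastal species the biologically relevant
#' distance is usually the along-coast path, which must be supplied by the
#' user; great-circle values are a lower bound.
#'
#' @param coords data.frame with columns `lon` and `lat` (decimal degrees)
#'   and row names giving population labels.
#' @return symmetric matrix of distances in kilometres.
#' @export
greatCircleDistances <- function(coords) {
  k <- nrow(coords)
  m <- matrix(0, k, k, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- geosphere::distGeo(
        c(coords$lon[i], coords$lat[i]),
        c(coords$lon[j], coords$lat[j])
      ) / 1000
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}
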