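# Tajima's (1989) coefficients a1..e2 for sample size n.
.tajimaCoefficients <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(
    a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
    e1 = c1 / a1, e2 = c2 / (a1^2 + a2)
  )
}

.tajimaDStat <- function(S, M, n) {
  if (S == 0L) {
    return(NA_real_)
  }
  co <- .tajimaCoefficients(n)
  (M - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
}

#' Tajima's D with a coalescent simulation p-value
#'
#' D contrasts the mean pairwise difference M with the scaled number of
#' segregating sites S/a1; D = (M - S/a1)/sqrt(e1 S + e2 S(S-1)) with
#' Tajima's (1989) coefficients. The p-value is the two-tailed fraction of
#' neutral constant-size coalescent replicates, conditioned on n and
#' theta-hat = M, whose |D| is at least the observed |D|.
#'
#' @param aln a filtered [PopAlignment] (n >= 4 recommended).
#' @param reps neutral coalescent replicates for the p-value (0 skips it).
#' @param seed RNG seed.
#' @return list with `D`, `p`, `S`, `M`, `n`; `D` is NA (flagged) when
#'   S = 0.
#' @export
tajimasD <- function(aln, reps = 10000, seed = 1L) {
  pds <- pairwiseDifferenceStats(aln)
  n <- as.integer(pds["n"])
  S <- as.integer(pds["S"])
  M <- unname(pds["M"])
  D <- .tajimaDStat(S, M, n)
  p <- NA_real_
  if (!is.na(D) && reps > 0) {
    set.seed(seed)
    sims <- .coalStats(n, theta = M, reps = reps)
    Dsim <- vapply(sims, function(s) .tajimaDStat(s$S, s$M, n), 0)
    p <- mean(abs(Dsim) >= abs(D), na.rm = TRUE)
  }
  list(D = D, p = p, S = S, M = M, n = n)
}

# Unsigned Stirling numbers of the first kind, log scale, rows 1..n.
# logS[[m]][k] = log |s(m, k)|; built by the standard recurrence in
# log-safe arithmetic so n up to a few hundred is exact to double precision.
.logStirlingFirst <- function(n) {
  rows <- vector("list", n)
  rows[[1L]] <- 0 # |s(1,1)| = 1
  if (n == 1L) {
    return(rows)
  }
  for (m in 2L:n) {
    prev <- rows[[m - 1L]]
    cur <- numeric(m)
    cur[1L] <- log(m - 1) + prev[1L]
    cur[m] <- 0
    if (m > 2L) {
      for (k in 2L:(m - 1L)) {
        cur[k] <- .logSumExp(c(prev[k - 1L], log(m - 1) + prev[k]))
      }
    }
    rows[[m]] <- cur
  }
  rows
}

#' Ewens sampling-formula distribution of the number of haplotypes
#'
#' P(K = k | theta, n) = |s(n, k)| theta^k / theta^(n) with unsigned
#' Stirling numbers of the first kind and the rising factorial
#' theta^(n) = theta (theta+1) ... (theta+n-1).
#'
#' @param theta scaled mutation rate.
#' @param n sample size.
#' @return numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewensK <- function(theta, n) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  ls <- .logStirlingFirst(n)[[n]]
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(logp)
}

#' Fu's Fs with a coalescent simulation p-value
#'
#' S' = P(K >= k_obs | theta = M, n) under the Ewens sampling formula and
#' Fs = ln(S'/(1-S')). Strongly negative values indicate an excess of rare
#' haplotypes relative to the pairwise diversity, as expected after a
#' population expansion. The p-value is the fraction of neutral coalescent
#' replicates with Fs at most the observed value.
#'
#' @param aln a filtered [PopAlignment], n >= 2 with M > 0.
#' @param reps neutral replicates for the p-value (0 skips it).
#' @param seed RNG seed.
#' @return list with `Fs`, `p`, `Sprime`, `k`, `M`, `n`; `Fs` is NA
#'   (flagged) when M = 0.
#' @export
fusFs <- function(aln, reps = 10000, seed = 1L) {
  pds <- pairwiseDifferenceStats(aln)
  n <- as.integer(pds["n"])
  M <- unname(pds["M"])
  k <- nrow(collapseHaplotypes(aln)@counts)
  if (M <= 0) {
    return(list(Fs = NA_real_, p = NA_real_, Sprime = NA_real_, k = k, M = M, n = n))
  }
  fs <- .fsStat(k, M, n)
  p <- NA_real_
  if (reps > 0) {
    set.seed(seed)
    sims <- .coalStats(n, theta = M, reps = reps)
    fsSim <- vapply(sims, function(s) {
      if (s$M <= 0) {
        return(NA_real_)
      }
      .fsStat(s$K, s$M, n, warn = FALSE)
    }, 0)
    p <- mean(fsSim <= fs, na.rm = TRUE)
  }
  list(Fs = fs, p = p, Sprime = .fsSprime(k, M, n), k = k, M = M, n = n)
}

.fsSprime <- function(k, theta, n) {
  probs <- ewensK(theta, n)
  sum(probs[k:n])
}

.fsStat <- function(k, theta, n, warn = TRUE) {
  sp <- .fsSprime(k, theta, n)
  eps <- 1e-15
  if (sp <= eps || sp >= 1 - eps) {
    if (warn) {
      warning("Ewens tail probability numerically at 0 or 1; Fs clamped",
        call. = FALSE
      )
    }
    sp <- min(max(sp, eps), 1 - eps)
  }
  log(sp / (1 - sp))
}

#' Neutrality-test report for every population and pooled
#'
#' @param aln a filtered [PopAlignment].
#' @param reps coalescent replicates per test.
#' @param seed RNG seed.
#' @return data.frame with one row per population plus `Pooled`: D, pD, Fs,
#'   pFs.
#' @export
neutralityTable <- function(aln, reps = 10000, seed = 1L) {
  groups <- c(as.list(levels(aln@population)), list(NULL))
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    sub <- if (is.null(g)) aln else subsetPopulations(aln, g)
    td <- tajimasD(sub, reps = reps, seed = .subSeed(seed, gi))
    ff <- fusFs(sub, reps = reps, seed = .subSeed(seed, gi + 1000L))
    data.frame(
      population = if (is.null(g)) "Pooled" else g,
      D = td$D, pD = td$p, Fs = ff$Fs, pFs = ff$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
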