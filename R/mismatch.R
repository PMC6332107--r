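#' Observed mismatch distribution
#'
#' Relative frequency of each pairwise difference count over all
#' n(n-1)/2 sequence pairs, classes 0..max.
#'
#' @param aln a filtered [PopAlignment] with n >= 2.
#' @return numeric vector of proportions named "0", "1", ...
#' @export
mismatchObserved <- function(aln) {
  if (length(aln@seqs) < 2L) stop("mismatch spectrum needs n >= 2", call. = FALSE)
  d <- .condensed(.hammingMatrix(.intMatrix(aln@seqs)))
  spec <- tabulate(d + 1L, nbins = max(d) + 1L) / length(d)
  names(spec) <- as.character(seq_along(spec) - 1L)
  spec
}

#' Expected mismatch distribution under sudden expansion
#'
#' Probability of observing i pairwise differences for a population whose
#' scaled size jumped from theta0 to theta1 at tau mutational units (2ut)
#' before the present. With F_eq(i, theta) = theta^i/(1+theta)^(i+1) the
#' equilibrium geometric spectrum and a = (1+theta1)/theta1:
#'
#'   F(i) = F_eq(i, theta1) (1 - P(Pois(a tau) <= i))
#'        + exp(-tau/theta1) sum_j dpois(j, tau) F_eq(i-j, theta0)
#'
#' obtained by integrating the pairwise coalescence density through the
#' size change. Mass beyond `dMax` is aggregated into the last class so the
#' returned spectrum always sums to one.
#'
#' @param tau expansion time in mutational units (>= 0).
#' @param theta0,theta1 pre-/post-expansion scaled sizes (>= 0).
#' @param dMax largest difference class reported.
#' @param aggregateTail add the remaining tail mass to class `dMax`.
#' @return numeric vector over classes 0..dMax.
#' @export
expectedSuddenExpansion <- function(tau, theta0, theta1, dMax,
                                    aggregateTail = TRUE) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0, dMax >= 0)
  i <- 0:dMax
  feq <- function(i, th) {
    if (th == 0) as.numeric(i == 0L) else th^i / (1 + th)^(i + 1)
  }
  f1 <- feq(i, theta1)
  f0 <- feq(i, theta0)
  if (tau == 0) {
    # expansion happening now: the whole history is at theta0
    spec <- f0
  } else if (theta1 == 0) {
    # zero current size: pairs coalesce immediately, no differences
    spec <- as.numeric(i == 0L)
  } else {
    a <- (1 + theta1) / theta1
    term1 <- f1 * stats::ppois(i, a * tau, lower.tail = FALSE)
    dp <- stats::dpois(i, tau)
    conv <- stats::convolve(dp, rev(f0), type = "open")[seq_len(dMax + 1L)]
    term2 <- exp(-tau / theta1) * pmax(conv, 0)
    spec <- term1 + term2
  }
  if (aggregateTail) {
    spec[dMax + 1L] <- spec[dMax + 1L] + max(1 - sum(spec), 0)
  }
  names(spec) <- as.character(i)
  spec
}

#' Harpending's raggedness index
#'
#' r = sum over classes of the squared difference between successive
#' spectrum frequencies, with the convention that the class after the last
#' observed one has frequency zero (classes start at 0).
#'
#' @param spectrum numeric spectrum over classes 0..d.
#' @return the raggedness index.
#' @export
raggedness <- function(spectrum) {
  sum(diff(c(unname(spectrum), 0))^2)
}

#' Fit the sudden-expansion model to an observed mismatch spectrum
#'
#' Minimises the sum of squared deviations between the observed spectrum
#' and [expectedSuddenExpansion()] over (tau, theta0, theta1), by a coarse
#' deterministic grid followed by Nelder-Mead refinement on log-transformed
#' parameters. Plain (unweighted) least squares is used.
#'
#' @param observed observed spectrum (proportions over classes 0..d), e.g.
#'   from [mismatchObserved()].
#' @param tauMax upper bound of the tau search grid (default 2d).
#' @param thetaMax upper bound for theta1 (default 5 times the observed
#'   mean).
#' @return a [MismatchFit] (without bootstrap p-values).
#' @export
fitSuddenExpansion <- function(observed, tauMax = NULL, thetaMax = NULL) {
  d <- length(observed) - 1L
  if (d < 1L) stop("observed spectrum needs at least two classes", call. = FALSE)
  meanD <- sum((0:d) * observed)
  if (is.null(tauMax)) tauMax <- max(2 * d, 4)
  if (is.null(thetaMax)) thetaMax <- max(100, 10 * d)
  ssdOf <- function(tau, th0, th1) {
    e <- expectedSuddenExpansion(tau, th0, th1, d)
    sum((observed - e)^2)
  }
  grid <- expand.grid(
    tau = seq(0, tauMax, length.out = 17L),
    th0 = c(0, 0.1, 0.5, 1, 2, 5, max(meanD, 1)),
    th1 = c(0.5, 1, 2, 5, 10, 25, thetaMax)
  )
  gssd <- mapply(ssdOf, grid$tau, grid$th0, grid$th1)
  best <- which.min(gssd)
  eps <- 1e-6
  upper <- c(tauMax, thetaMax, thetaMax)
  start <- log(c(grid$tau[best], grid$th0[best], grid$th1[best]) + eps)
  obj <- function(p) {
    v <- exp(p) - eps
    v[v < 0] <- 0
    if (any(v > upper)) {
      return(1e6 + sum(pmax(v - upper, 0))) # keep the search in bounds
    }
    ssdOf(v[1L], v[2L], v[3L])
  }
  opt <- stats::optim(start, obj,
    method = "Nelder-Mead",
    control = list(maxit = 2000L, reltol = 1e-12)
  )
  converged <- opt$convergence == 0L && opt$value <= gssd[best] + 1e-15
  if (opt$value <= gssd[best]) {
    pars <- pmax(exp(opt$par) - eps, 0)
    ssd <- opt$value
  } else {
    pars <- c(grid$tau[best], grid$th0[best], grid$th1[best])
    ssd <- gssd[best]
    converged <- FALSE
  }
  methods::new("MismatchFit",
    observed = as.numeric(observed),
    expected = as.numeric(expectedSuddenExpansion(pars[1L], pars[2L], pars[3L], d)),
    tau = pars[1L], theta0 = pars[2L], theta1 = pars[3L], ssd = ssd,
    raggedness = raggedness(as.numeric(observed)),
    pSSD = NA_real_, pRaggedness = NA_real_, converged = converged
  )
}

#' Parametric-bootstrap goodness of fit for a mismatch fit
#'
#' Simulates coalescent samples of size n under the fitted sudden-expansion
#' parameters (infinite-sites mutations at rate theta1/2, size change at
#' tau/theta1 coalescent units), refits each replicate spectrum, and
#' reports p(SSD) and p(raggedness) as the fraction of replicates whose
#' statistic is at least the observed one.
#'
#' @param fit a [MismatchFit].
#' @param n sample size behind the observed spectrum.
#' @param reps bootstrap replicates (values below 100 give unstable
#'   p-values and raise a warning).
#' @param seed RNG seed.
#' @return the [MismatchFit] with `pSSD` and `pRaggedness` filled in.
#' @export
goodnessOfFit <- function(fit, n, reps = 1000, seed = 1L) {
  if (reps < 100) {
    warning("fewer than 100 bootstrap replicates: p-values are unstable",
      call. = FALSE
    )
  }
  set.seed(seed)
  expPars <- c(fit@tau, fit@theta0, max(fit@theta1, 1e-6))
  sims <- .coalStats(n,
    theta = NA, reps = reps, expansion = expPars,
    spectrum = TRUE
  )
  ssdRep <- numeric(reps)
  ragRep <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- sims[[r]]$spectrum
    if (length(spec) < 2L) spec <- c(spec, 0)
    f <- fitSuddenExpansion(spec)
    ssdRep[r] <- f@ssd
    ragRep[r] <- raggedness(spec)
  }
  fit@pSSD <- mean(ssdRep >= fit@ssd)
  fit@pRaggedness <- mean(ragRep >= fit@raggedness)
  fit
}

#' Mismatch / demography report per population and pooled
#'
#' @param aln a filtered [PopAlignment].
#' @param bootstrapReps goodness-of-fit bootstrap replicates (0 skips).
#' @param seed RNG seed.
#' @return list with `table` (data.frame: tau, theta0, theta1, SSD, pSSD,
#'   raggedness, pRaggedness per population and pooled) and `spectra`
#'   (named list of observed spectra).
#' @export
mismatchTable <- function(aln, bootstrapReps = 1000, seed = 1L) {
  groups <- c(as.list(levels(aln@population)), list(NULL))
  spectra <- list()
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    nameG <- if (is.null(g)) "Pooled" else g
    sub <- if (is.null(g)) aln else subsetPopulations(aln, g)
    spec <- mismatchObserved(sub)
    spectra[[nameG]] <<- spec
    fit <- fitSuddenExpansion(spec)
    if (bootstrapReps > 0) {
      fit <- goodnessOfFit(fit, length(sub@seqs),
        reps = bootstrapReps,
        seed = .subSeed(seed, gi)
      )
    }
    data.frame(
      population = nameG, tau = fit@tau, theta0 = fit@theta0,
      theta1 = fit@theta1, SSD = fit@ssd, pSSD = fit@pSSD,
      raggedness = fit@raggedness, pRaggedness = fit@pRaggedness,
      stringsAsFactors = FALSE
    )
  })
  list(table = do.call(rbind, rows), spectra = spectra)
}
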