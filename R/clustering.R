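# The clustering model treats each cluster as a panmictic group with its
# own allele frequencies at every site, integrated out under a symmetric
# Dirichlet prior: the marginal likelihood of a cluster is a product over
# sites of Dirichlet-multinomial terms. The Dirichlet support at a site is
# the set of bases actually observed there in the full alignment (the
# usual allele-based treatment); sites observing a single base therefore
# contribute nothing to any partition's score and are skipped.

# Site coding shared by the scoring routines: recode each variable column
# to 1..K (K = number of observed bases) and drop constant columns.
.clusterSiteData <- function(im) {
  keep <- integer(0)
  recoded <- NULL
  Ks <- integer(0)
  for (s in seq_len(ncol(im))) {
    obs <- sort(unique(im[, s]))
    if (length(obs) < 2L) next
    keep <- c(keep, s)
    Ks <- c(Ks, length(obs))
    recoded <- cbind(recoded, match(im[, s], obs))
  }
  if (!length(keep)) {
    recoded <- matrix(integer(0), nrow = nrow(im), ncol = 0L)
  }
  list(recoded = recoded, K = Ks)
}

# Score of one cluster (n rows of `sd$recoded` counted in `counts`, a
# 4 x S matrix over the recoded alleles).
.dmClusterScore <- function(counts, n, sd, alpha) {
  if (!length(sd$K) || n == 0L) {
    return(0)
  }
  total <- 0
  for (s in seq_along(sd$K)) {
    K <- sd$K[s]
    cts <- counts[seq_len(K), s]
    total <- total + sum(lgamma(alpha + cts)) - K * lgamma(alpha) +
      lgamma(K * alpha) - lgamma(K * alpha + n)
  }
  total
}

#' Dirichlet-multinomial log marginal likelihood of a partition
#'
#' Score = sum over clusters and variable sites of the
#' Dirichlet-multinomial marginal log-likelihood of the cluster's per-site
#' allele counts, under a symmetric prior with concentration `alpha` per
#' allele observed at the site (alignment-wide). Empty clusters contribute
#' nothing, and so do constant columns. The score is invariant to cluster
#' relabeling and individual order.
#'
#' @param labels integer cluster label per individual.
#' @param aln a filtered [PopAlignment] (pure A/C/G/T).
#' @param alpha symmetric Dirichlet concentration per allele (default
#'   0.25).
#' @return the log marginal likelihood.
#' @export
dirichletMultinomialScore <- function(labels, aln, alpha = 0.25) {
  im <- .intMatrix(aln@seqs)
  if (anyNA(im)) stop("clustering requires fully resolved sites", call. = FALSE)
  if (length(labels) != nrow(im)) {
    stop("labels must cover every individual", call. = FALSE)
  }
  sd <- .clusterSiteData(im)
  score <- 0
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    counts <- .alleleCounts(sd$recoded[rows, , drop = FALSE])
    score <- score + .dmClusterScore(counts, length(rows), sd, alpha)
  }
  score
}

# 4 x S recoded allele count matrix.
.alleleCounts <- function(recoded) {
  S <- ncol(recoded)
  counts <- matrix(0L, 4L, max(S, 1L))[, seq_len(S), drop = FALSE]
  for (b in 1:4) counts[b, ] <- colSums(recoded == b)
  counts
}

#' Model-based clustering of individuals into panmictic groups
#'
#' For each number of clusters k up to `kMax`, runs `replicates` seeded
#' restarts of a greedy search and returns the best-scoring partition over
#' all k (model selection by maximum marginal likelihood; all restart
#' scores are reported). Each restart starts from a hierarchical-clustering
#' cut of the pairwise-difference matrix — the first unperturbed, later
#' ones with a random quarter of the individuals reassigned — and then
#' repeats the best single-individual reassignment until no move improves
#' the Dirichlet-multinomial marginal likelihood. Assignment probabilities
#' are the leave-one-out predictive probabilities of each individual under
#' each fitted cluster profile, renormalized per individual.
#'
#' @param aln a filtered [PopAlignment] with N >= 2.
#' @param kMax maximum number of clusters tried (default 10).
#' @param replicates restarts per k (default 5).
#' @param seed RNG seed; the whole search is deterministic given it.
#' @param alpha Dirichlet concentration per observed allele.
#' @return a [ClusterResult].
#' @export
fitClusters <- function(aln, kMax = 10L, replicates = 5L, seed = 1L,
                        alpha = 0.25) {
  im <- .intMatrix(aln@seqs)
  if (anyNA(im)) stop("clustering requires fully resolved sites", call. = FALSE)
  N <- nrow(im)
  if (N < 2L) stop("clustering needs at least two individuals", call. = FALSE)
  kMax <- min(.checkCount(kMax, "kMax"), N)
  sd <- .clusterSiteData(im)
  hc <- stats::hclust(stats::as.dist(.hammingMatrix(im)), method = "average")
  best <- NULL
  scores <- list()
  for (k in seq_len(kMax)) {
    baseInit <- as.integer(stats::cutree(hc, k = k))
    for (repi in seq_len(replicates)) {
      set.seed(.subSeed(seed, k * 131L + repi))
      init <- baseInit
      if (repi > 1L) {
        shuffle <- sample.int(N, max(1L, round(0.25 * N)))
        init[shuffle] <- sample.int(k, length(shuffle), replace = TRUE)
      }
      fit <- .greedyDmSearch(sd, k, alpha, init)
      scores[[length(scores) + 1L]] <- data.frame(
        k = k, replicate = repi, score = fit$score
      )
      if (is.null(best) || fit$score > best$score) best <- fit
    }
  }
  labels <- as.integer(factor(best$labels)) # drop empty clusters
  k <- max(labels)
  names(labels) <- rownames(im)
  membership <- .membershipProbs(sd, labels, k, alpha)
  rownames(membership) <- rownames(im)
  methods::new("ClusterResult",
    k = k, labels = labels,
    logMarginal = best$score,
    membership = membership,
    replicateScores = do.call(rbind, scores)
  )
}

# Greedy best-single-move search over partitions with (at most) k groups.
.greedyDmSearch <- function(sd, k, alpha, init, maxPass = 100L) {
  N <- nrow(sd$recoded)
  S <- ncol(sd$recoded)
  labels <- init
  counts <- array(0L, dim = c(4L, max(S, 1L), k))
  sizes <- tabulate(labels, nbins = k)
  idxOf <- lapply(seq_len(N), function(i) cbind(sd$recoded[i, ], seq_len(S)))
  if (S > 0L) {
    for (i in seq_len(N)) {
      counts[cbind(idxOf[[i]], labels[i])] <-
        counts[cbind(idxOf[[i]], labels[i])] + 1L
    }
  }
  # log denominator sums: logDen[n+1] = sum_s log(K_s*alpha + n)
  logDen <- vapply(0:N, function(n) sum(log(sd$K * alpha + n)), 0)
  scoreAll <- function() {
    sum(vapply(which(sizes > 0L), function(cl) {
      .dmClusterScore(
        matrix(counts[, , cl], nrow = 4L)[, seq_len(S), drop = FALSE],
        sizes[cl], sd, alpha
      )
    }, 0))
  }
  if (S == 0L) {
    return(list(labels = labels, score = 0))
  }
  for (pass in seq_len(maxPass)) {
    moved <- FALSE
    for (i in sample.int(N)) {
      cur <- labels[i]
      ix <- idxOf[[i]]
      # gain of deleting i from its cluster
      base <- -(sum(log(alpha + counts[cbind(ix, cur)] - 1L)) -
        logDen[sizes[cur]])
      gains <- vapply(seq_len(k), function(cl) {
        if (cl == cur) {
          return(0)
        }
        add <- sum(log(alpha + counts[cbind(ix, cl)])) -
          logDen[sizes[cl] + 1L]
        base + add
      }, 0)
      bestCl <- which.max(gains)
      if (gains[bestCl] > 1e-9 && bestCl != cur) {
        counts[cbind(ix, cur)] <- counts[cbind(ix, cur)] - 1L
        counts[cbind(ix, bestCl)] <- counts[cbind(ix, bestCl)] + 1L
        sizes[cur] <- sizes[cur] - 1L
        sizes[bestCl] <- sizes[bestCl] + 1L
        labels[i] <- bestCl
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(labels = labels, score = scoreAll())
}

# Leave-one-out predictive assignment probabilities.
.membershipProbs <- function(sd, labels, k, alpha) {
  N <- nrow(sd$recoded)
  S <- ncol(sd$recoded)
  probs <- matrix(1 / k, N, k, dimnames = list(NULL, paste0("C", seq_len(k))))
  if (S == 0L) {
    return(probs)
  }
  counts <- array(0L, dim = c(4L, S, k))
  sizes <- tabulate(labels, nbins = k)
  idxOf <- lapply(seq_len(N), function(i) cbind(sd$recoded[i, ], seq_len(S)))
  for (i in seq_len(N)) {
    counts[cbind(idxOf[[i]], labels[i])] <-
      counts[cbind(idxOf[[i]], labels[i])] + 1L
  }
  for (i in seq_len(N)) {
    ix <- idxOf[[i]]
    lp <- vapply(seq_len(k), function(cl) {
      own <- as.integer(cl == labels[i])
      n <- sizes[cl] - own
      sum(log(alpha + counts[cbind(ix, cl)] - own)) -
        sum(log(sd$K * alpha + n))
    }, 0)
    probs[i, ] <- exp(lp - .logSumExp(lp))
  }
  probs
}

#' Assignment table for reporting
#'
#' Long-format assignment table mirroring the usual stacked-bar plot input:
#' one row per individual and cluster with the membership probability.
#'
#' @param result a [ClusterResult].
#' @param aln the [PopAlignment] it was fitted to.
#' @return data.frame with id, population, cluster, probability, assigned.
#' @export
assignmentTable <- function(result, aln) {
  ids <- names(result@labels)
  out <- do.call(rbind, lapply(seq_len(result@k), function(cl) {
    data.frame(
      id = ids,
      population = as.character(aln@population[ids]),
      cluster = cl,
      probability = result@membership[, cl],
      assigned = result@labels == cl,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
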