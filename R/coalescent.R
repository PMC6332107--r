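#' Configuration for the structured-coalescent sequence simulator
#'
#' @slot demeSizes integer sample sizes per deme.
#' @slot theta scaled mutation rate per locus (2Nu for the reference
#'   population size; mtDNA is one non-recombining locus).
#' @slot migration deme x deme matrix of scaled backward migration rates
#'   (rate per lineage per coalescent time unit); diagonal ignored.
#' @slot splitTime optional divergence time (coalescent units) at which,
#'   looking backward, all demes merge into a single panmictic ancestral
#'   population; `NA` for none.
#' @slot regions integer region id per deme (used only for bookkeeping and
#'   truth labels of two-region presets).
#' @slot kappa transition/transversion rate ratio of the Kimura-type
#'   mutation kernel; the expected transversion/transition count ratio is
#'   2/kappa.
#' @slot baseFreqs root base frequencies (A, C, G, T).
#' @slot L number of sites.
#' @slot expansion numeric c(tau, theta0, theta1) describing an
#'   instantaneous expansion in mutational units, or NA for constant size.
#'   When set, `theta` is ignored and theta1 drives the mutation rate.
#' @slot infiniteSites logical; if TRUE every mutation hits a fresh site
#'   (clean oracle mode), ignoring `L`, `kappa`, `baseFreqs`.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    demeSizes = "integer", theta = "numeric", migration = "matrix",
    splitTime = "numeric", regions = "integer", kappa = "numeric",
    baseFreqs = "numeric", L = "integer", expansion = "numeric",
    infiniteSites = "logical"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@demeSizes < 1L)) msg <- c(msg, "deme sizes must be >= 1")
  if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
  if (object@L < 1L) msg <- c(msg, "L must be > 0")
  if (any(object@migration < 0)) msg <- c(msg, "migration rates must be >= 0")
  if (abs(sum(object@baseFreqs) - 1) > 1e-9) {
    msg <- c(msg, "base frequencies must sum to 1")
  }
  if (!anyNA(object@expansion) && (length(object@expansion) != 3L ||
    any(object@expansion < 0))) {
    msg <- c(msg, "expansion must be c(tau, theta0, theta1), all >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param demeSizes,theta,migration,splitTime,regions,kappa,baseFreqs,L,expansion,infiniteSites
#'   see the slot documentation.
#' @return a validated [SimulationConfig].
#' @export
simulationConfig <- function(demeSizes, theta = 10, migration = NULL,
                             splitTime = NA_real_, regions = NULL,
                             kappa = 12, baseFreqs = rep(0.25, 4), L = 710L,
                             expansion = NA_real_, infiniteSites = FALSE) {
  demeSizes <- as.integer(demeSizes)
  d <- length(demeSizes)
  if (is.null(migration)) migration <- matrix(0, d, d)
  if (is.null(regions)) regions <- rep(1L, d)
  if (!anyNA(expansion)) expansion <- as.numeric(expansion)
  methods::new("SimulationConfig",
    demeSizes = demeSizes, theta = theta, migration = migration,
    splitTime = splitTime, regions = as.integer(regions), kappa = kappa,
    baseFreqs = baseFreqs, L = as.integer(L), expansion = expansion,
    infiniteSites = infiniteSites
  )
}

#' Preset emulating a five-population, two-region mtDNA survey
#'
#' Five demes of sample sizes 15, 15, 22, 21, 24 (N = 97) at 710 sites,
#' grouped into two regions (demes 1-3 vs 4-5) that diverged `splitTime`
#' coalescent units ago, with free migration within regions and none
#' between, and a strong recent expansion within every deme (scaled size
#' theta0 -> theta1 at tau mutational units before present). The expansion
#' makes genealogies star-like, which is what produces the hallmark of
#' control-region surveys: essentially every sequence a unique haplotype
#' at moderate mean pairwise differences. Defaults give within-population
#' mean pairwise differences near 19, a realized transversion/transition
#' ratio near 0.16, >95% unique haplotypes, and a realized AMOVA PhiST
#' whose median across seeds lies between 0.35 and 0.60.
#'
#' Time is expressed in coalescent units of the large post-expansion size,
#' so `splitTime` is numerically small; the between-region sequence
#' divergence it implies is roughly theta * splitTime differences.
#'
#' @param splitTime between-region divergence in coalescent units of the
#'   current (post-expansion) size.
#' @param theta scaled mutation rate per locus (post-expansion theta1).
#' @param tau expansion age in mutational units.
#' @param growth expansion factor theta1/theta0.
#' @param migrationWithin scaled migration rate among demes of a region.
#' @return a [SimulationConfig].
#' @export
twoRegionPreset <- function(splitTime = 0.024, theta = 2000, tau = 14,
                            growth = 1000, migrationWithin = 500) {
  d <- 5L
  regions <- c(1L, 1L, 1L, 2L, 2L)
  mig <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (i != j && regions[i] == regions[j]) mig[i, j] <- migrationWithin
    }
  }
  simulationConfig(
    demeSizes = c(15L, 15L, 22L, 21L, 24L), theta = theta, migration = mig,
    splitTime = splitTime, regions = regions, kappa = 30,
    baseFreqs = c(A = 0.443, C = 0.161, G = 0.083, T = 0.313), L = 710L,
    expansion = c(tau, theta / growth, theta)
  )
}

## ---- genealogy ----------------------------------------------------------

# Structured coalescent with optional instantaneous expansion and a single
# all-deme merge at splitTime. Returns parent pointers, node times and the
# deme of each leaf. Nodes: leaves 1..n, internals n+1..2n-1 in time order.
.coalesce <- function(config) {
  sizes <- config@demeSizes
  n <- sum(sizes)
  d <- length(sizes)
  mig <- config@migration
  diag(mig) <- 0
  splitT <- config@splitTime
  # expansion: rate factor theta1/theta0 applies beyond tExp (backward)
  if (!anyNA(config@expansion)) {
    tau <- config@expansion[1L]
    th0 <- config@expansion[2L]
    th1 <- config@expansion[3L]
    tExp <- tau / th1
    rateOld <- if (th0 > 0) min(th1 / th0, 1e8) else 1e8
  } else {
    tExp <- Inf
    rateOld <- 1
  }
  if (is.na(splitT) && d > 1L) {
    g <- igraph::graph_from_adjacency_matrix(mig > 0, mode = "max")
    if (igraph::components(g)$no > 1L) {
      stop(
        "demes are mutually unreachable: zero migration and no split time",
        call. = FALSE
      )
    }
  }
  deme <- rep(seq_len(d), sizes)
  parent <- integer(2L * n - 1L)
  nodeTime <- numeric(2L * n - 1L)
  active <- seq_len(n)
  lineDeme <- deme
  t <- 0
  nextNode <- n + 1L
  merged <- FALSE
  while (length(active) > 1L) {
    if (!merged && !is.na(splitT) && t >= splitT) {
      lineDeme[] <- 1L
      merged <- TRUE
    }
    rho <- if (t >= tExp) rateOld else 1
    kd <- tabulate(lineDeme[seq_along(active)], nbins = d)
    coalRates <- choose(kd, 2) * rho
    migRates <- if (merged || d == 1L) {
      rep(0, d)
    } else {
      kd * rowSums(mig)
    }
    total <- sum(coalRates) + sum(migRates)
    boundary <- min(
      if (!merged && !is.na(splitT)) splitT else Inf,
      if (t < tExp) tExp else Inf
    )
    if (total <= 0) {
      # isolated lineages can only wait for the next demographic event
      if (!is.finite(boundary)) {
        stop("no feasible coalescent event", call. = FALSE)
      }
      t <- boundary
      next
    }
    wait <- stats::rexp(1L, total)
    if (t + wait > boundary) {
      t <- boundary
      next
    }
    t <- t + wait
    ev <- sample.int(2L * d, 1L, prob = c(coalRates, migRates))
    if (ev <= d) {
      inDeme <- which(lineDeme[seq_along(active)] == ev)
      pick <- sample(inDeme, 2L)
      node <- nextNode
      nextNode <- nextNode + 1L
      parent[active[pick]] <- node
      nodeTime[node] <- t
      keep <- setdiff(seq_along(active), pick)
      active <- c(active[keep], node)
      lineDeme <- c(lineDeme[keep], ev)
    } else {
      from <- ev - d
      inDeme <- which(lineDeme[seq_along(active)] == from)
      mover <- if (length(inDeme) == 1L) inDeme else sample(inDeme, 1L)
      lineDeme[mover] <- sample.int(d, 1L, prob = mig[from, ])
    }
  }
  list(parent = parent, time = nodeTime, n = n, deme = deme)
}

# Convert the internal genealogy to an ape phylo (root renumbered to n+1).
.asPhylo <- function(gen, tipLabels) {
  n <- gen$n
  nInt <- n - 1L
  # internal node n+s (s-th coalescence) -> ape id 2n - s, so root -> n+1
  remap <- function(v) ifelse(v <= n, v, 2L * n - (v - n))
  child <- seq_len(2L * n - 2L)
  edge <- cbind(remap(gen$parent[child]), remap(child))
  len <- gen$time[gen$parent[child]] - gen$time[child]
  tr <- list(
    edge = edge, edge.length = len, tip.label = tipLabels,
    Nnode = nInt
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a genealogy under the structured coalescent
#'
#' Runs the backward-in-time coalescent with migration among demes,
#' optional merge of all demes at `splitTime`, and optional instantaneous
#' expansion, and returns the timed genealogy.
#'
#' @param config a [SimulationConfig].
#' @param seed RNG seed.
#' @return an [ape::phylo] tree with branch lengths in coalescent units;
#'   tip labels `i1..iN` in deme order, with attributes `deme` (deme per
#'   tip) and `times` (internal representation).
#' @export
simulateGenealogy <- function(config, seed = 1L) {
  methods::validObject(config)
  set.seed(seed)
  gen <- .coalesce(config)
  tips <- paste0("i", seq_len(gen$n))
  tr <- .asPhylo(gen, tips)
  attr(tr, "deme") <- stats::setNames(gen$deme, tips)
  tr
}

#' Drop mutations on a genealogy and build the alignment
#'
#' Mutations arrive as a Poisson process with rate theta/2 per lineage per
#' coalescent unit, scattered uniformly over sites. Each mutation applies a
#' Kimura-type kernel: transition with probability kappa/(kappa+2),
#' otherwise one of the two transversions. The root sequence is drawn from
#' `baseFreqs`. In infinite-sites mode every mutation creates a new
#' segregating column instead.
#'
#' @param genealogy a tree from [simulateGenealogy()].
#' @param config the [SimulationConfig] used to generate it.
#' @param seed RNG seed.
#' @return a [PopAlignment]; populations are `P<deme>` labels.
#' @export
mutateSequences <- function(genealogy, config, seed = 1L) {
  set.seed(seed)
  theta <- if (!anyNA(config@expansion)) config@expansion[3L] else config@theta
  tr <- genealogy
  n <- length(tr$tip.label)
  nmut <- stats::rpois(nrow(tr$edge), theta / 2 * pmax(tr$edge.length, 0))
  if (config@infiniteSites) {
    total <- sum(nmut)
    L <- max(total, 1L)
    seqm <- matrix(1L, nrow = n + tr$Nnode, ncol = L)
    nextSite <- 1L
  } else {
    L <- config@L
    seqm <- matrix(0L, nrow = n + tr$Nnode, ncol = L)
    root <- n + 1L
    seqm[root, ] <- sample.int(4L, L, replace = TRUE, prob = config@baseFreqs)
  }
  transPartner <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  pTs <- config@kappa / (config@kappa + 2)
  # cladewise order guarantees parents are filled before children
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chd <- tr$edge[e, 2L]
    s <- seqm[par, ]
    m <- nmut[e]
    if (m > 0L) {
      if (config@infiniteSites) {
        sites <- seq.int(nextSite, length.out = m)
        nextSite <- nextSite + m
        s[sites] <- 2L
      } else {
        sites <- sample.int(L, m, replace = TRUE)
        for (site in sites) {
          b <- s[site]
          s[site] <- if (stats::runif(1L) < pTs) {
            transPartner[b]
          } else {
            # one of the two transversion partners, uniformly
            tvs <- setdiff(1:4, c(b, transPartner[b]))
            tvs[sample.int(2L, 1L)]
          }
        }
      }
      seqm[chd, ] <- s
    } else {
      seqm[chd, ] <- s
    }
  }
  if (config@infiniteSites) seqm <- seqm[, seq_len(max(nextSite - 1L, 1L)), drop = FALSE]
  tipSeqs <- seqm[seq_len(n), , drop = FALSE]
  chars <- matrix(BASES[tipSeqs], nrow = n)
  seqs <- Biostrings::DNAStringSet(apply(chars, 1L, paste0, collapse = ""))
  names(seqs) <- tr$tip.label
  deme <- attr(genealogy, "deme")
  pop <- paste0("P", deme[tr$tip.label])
  PopAlignment(seqs, stats::setNames(pop, tr$tip.label))
}

#' Simulate a complete dataset with known truth
#'
#' Couples [simulateGenealogy()] and [mutateSequences()] under a single
#' seed; optionally writes the FASTA, population map and a JSON manifest
#' (configuration, seed, file checksum) to `dir`.
#'
#' @param config a [SimulationConfig].
#' @param seed master RNG seed; the dataset regenerates bit-identically
#'   from (config, seed).
#' @param dir optional output directory.
#' @param prefix file name prefix when writing.
#' @return a [SimulatedDataset].
#' @export
simulateDataset <- function(config, seed = 1L, dir = NULL, prefix = "simulated") {
  gen <- simulateGenealogy(config, seed = .subSeed(seed, 1L))
  aln <- mutateSequences(gen, config, seed = .subSeed(seed, 2L))
  ds <- methods::new("SimulatedDataset",
    alignment = aln, genealogy = gen,
    config = config, seed = as.integer(seed)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, paste0(prefix, ".fasta"))
    pm <- file.path(dir, paste0(prefix, ".popmap.tsv"))
    Biostrings::writeXStringSet(aln@seqs, fa)
    utils::write.table(
      data.frame(id = names(aln@population), population = aln@population),
      pm,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    manifest <- list(
      seed = as.integer(seed),
      demeSizes = config@demeSizes, theta = config@theta,
      splitTime = config@splitTime, regions = config@regions,
      kappa = config@kappa, baseFreqs = config@baseFreqs, L = config@L,
      expansion = config@expansion, infiniteSites = config@infiniteSites,
      migration = config@migration,
      fastaMd5 = unname(tools::md5sum(fa))
    )
    jsonlite::write_json(manifest, file.path(dir, paste0(prefix, ".manifest.json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  ds
}

## ---- fast neutral/expansion summary simulator ---------------------------

# Single-population coalescent with optional expansion, infinite-sites
# mutations. Returns per-replicate S, M (mean pairwise differences), K
# (haplotype count) and optionally the pairwise-difference spectrum.
# Used for neutrality-test p-values and mismatch parametric bootstraps;
# much faster than the full sequence simulator.
.coalStats <- function(n, theta, reps, expansion = NULL, spectrum = FALSE) {
  if (!is.null(expansion)) {
    tau <- expansion[1L]
    th0 <- expansion[2L]
    th1 <- expansion[3L]
    tExp <- if (th1 > 0) tau / th1 else 0
    rateOld <- if (th0 > 0) min(th1 / th0, 1e8) else 1e8
    mutRate <- th1 / 2
  } else {
    tExp <- Inf
    rateOld <- 1
    mutRate <- theta / 2
  }
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    parent <- integer(2L * n - 1L)
    ntime <- numeric(2L * n - 1L)
    active <- seq_len(n)
    t <- 0
    nxt <- n + 1L
    while (length(active) > 1L) {
      k <- length(active)
      rho <- if (t >= tExp) rateOld else 1
      wait <- stats::rexp(1L, choose(k, 2) * rho)
      if (t < tExp && t + wait > tExp) {
        t <- tExp
        next
      }
      t <- t + wait
      pick <- sample.int(k, 2L)
      parent[active[pick]] <- nxt
      ntime[nxt] <- t
      active <- c(active[-pick], nxt)
      nxt <- nxt + 1L
    }
    # branch mutation counts (root 2n-1 has none)
    nodes <- seq_len(2L * n - 2L)
    blen <- ntime[parent[nodes]] - ntime[nodes]
    m <- stats::rpois(length(nodes), mutRate * blen)
    # leaf sets bottom-up
    leafIdx <- vector("list", 2L * n - 1L)
    for (i in seq_len(n)) leafIdx[[i]] <- i
    ord <- order(ntime[(n + 1L):(2L * n - 1L)]) + n
    kids <- split(nodes, parent[nodes])
    for (v in ord) {
      ch <- kids[[as.character(v)]]
      leafIdx[[v]] <- c(leafIdx[[ch[1L]]], leafIdx[[ch[2L]]])
    }
    S <- sum(m)
    cSize <- lengths(leafIdx)[nodes]
    M <- sum(m * cSize * (n - cSize)) / choose(n, 2)
    # haplotype classes: propagate down; a mutated branch starts a new class
    cls <- integer(2L * n - 1L)
    cls[2L * n - 1L] <- 0L
    nextCls <- 1L
    for (v in rev(c(seq_len(n), ord))) {
      if (v == 2L * n - 1L) next
      if (m[v] > 0L) {
        cls[v] <- nextCls
        nextCls <- nextCls + 1L
      } else {
        cls[v] <- cls[parent[v]]
      }
    }
    K <- length(unique(cls[seq_len(n)]))
    rec <- list(S = S, M = M, K = K)
    if (spectrum) {
      D <- matrix(0L, n, n)
      for (v in nodes) {
        if (m[v] > 0L && cSize[v] < n) {
          a <- leafIdx[[v]]
          D[a, -a] <- D[a, -a] + m[v]
          D[-a, a] <- D[-a, a] + m[v]
        }
      }
      # cap the class range so pathological parameter sets cannot blow up
      dcap <- min(max(D), 20000L)
      rec$spectrum <- tabulate(pmin(D[lower.tri(D)], dcap) + 1L,
        nbins = dcap + 1L
      ) / choose(n, 2)
      rec$D <- D
    }
    out[[r]] <- rec
  }
  out
}
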