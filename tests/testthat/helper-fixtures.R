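# Fixture builders shared across the suite; everything is generated in
# code so the repository ships no binary data.

makeAln <- function(seqs, pops = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (is.null(pops)) pops <- rep("X", length(seqs))
  if (is.null(names(pops))) names(pops) <- names(seqs)
  PopAlignment(seqs, pops)
}

# Random gap-free alignment with i.i.d. sites.
randomAln <- function(n, L, seed = 1, pops = NULL) {
  set.seed(seed)
  chars <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  makeAln(apply(chars, 1, paste0, collapse = ""), pops)
}

# Low-divergence alignment: clones of one random ancestor, each carrying
# `subs` random substitutions (keeps K2P well inside its domain).
divergedAln <- function(n, L, subs = 5, seed = 1, pops = NULL) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    at <- sample(L, subs)
    s[at] <- vapply(s[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    paste0(s, collapse = "")
  }, "")
  names(seqs) <- paste0("s", seq_len(n))
  makeAln(seqs, pops)
}

# Write alignment + popmap to temp files; returns the two paths.
writeFixture <- function(seqs, pops) {
  fa <- tempfile(fileext = ".fasta")
  pm <- tempfile(fileext = ".tsv")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fa)
  writeLines(paste(names(pops), pops, sep = "\t"), pm)
  list(fasta = fa, popmap = pm)
}

# Mean pairwise Hamming distance by brute-force double loop.
bruteMeanPairwise <- function(seqs) {
  split_ <- strsplit(seqs, "")
  n <- length(split_)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(split_[[i]] != split_[[j]])
  }
  tot / choose(n, 2)
}

# Unsigned Stirling numbers of the first kind by exact integer recurrence
# (n small enough that doubles are exact).
exactStirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in 1:n) {
    for (k in 1:m) {
      s[m + 1, k + 1] <- s[m, k] + (m - 1) * s[m, k + 1]
    }
  }
  s[n + 1, 2:(n + 1)]
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(length(a), 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# Exhaustive Steiner search for tiny binary (A/T) instances: the minimum
# total edge length of any connected graph spanning the observed
# haplotypes plus any subset of additional 0/1 vectors.
steinerMinimum <- function(obs) {
  L <- nchar(obs[1])
  all <- apply(
    expand.grid(rep(list(c("A", "T")), L)), 1,
    paste0,
    collapse = ""
  )
  extra <- setdiff(all, obs)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  mstLen <- function(nodes) {
    k <- length(nodes)
    if (k < 2) {
      return(0)
    }
    d <- outer(nodes, nodes, Vectorize(ham))
    g <- igraph::graph_from_adjacency_matrix(d,
      mode = "undirected",
      weighted = TRUE, diag = FALSE
    )
    sum(igraph::E(igraph::mst(g))$weight)
  }
  best <- mstLen(obs)
  for (k in seq_len(min(length(extra), 3))) {
    combos <- utils::combn(extra, k, simplify = FALSE)
    for (cmb in combos) best <- min(best, mstLen(c(obs, cmb)))
  }
  best
}

# Cost at which the finished network connects the observed haplotypes:
# the MST over the network's shortest-path metric restricted to observed
# nodes. This is bounded below by the Steiner minimum (the union of the
# chosen paths spans the observed set) and must not exceed the
# observed-only MST length (median vectors may only shorten routes).
# The raw edge-set total is not comparable: it grows with every retained
# tie and every median node.
networkSpanningLength <- function(net) {
  g <- net@graph
  sp <- igraph::distances(g, weights = igraph::E(g)$weight)
  obs <- which(net@nodes$type == "observed")
  cl <- igraph::graph_from_adjacency_matrix(sp[obs, obs, drop = FALSE],
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  sum(igraph::E(igraph::mst(cl))$weight)
}

bruteMstLength <- function(haps) {
  im <- HaploPop:::.intMatrix(haplotypes(haps))
  d <- HaploPop:::.hammingMatrix(im)
  g <- igraph::graph_from_adjacency_matrix(d,
    mode = "undirected",
    weighted = TRUE, diag = FALSE
  )
  sum(igraph::E(igraph::mst(g))$weight)
}
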