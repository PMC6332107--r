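# Minimax (bottleneck) distances between all vertices of an MST: the
# largest edge weight on the unique MST path joining each pair.
.minimaxFromMst <- function(d) {
  dimnames(d) <- NULL # keep igraph vertex handles numeric
  n <- nrow(d)
  g <- igraph::graph_from_adjacency_matrix(d,
    mode = "undirected",
    weighted = TRUE, diag = FALSE
  )
  mst <- igraph::mst(g)
  mm <- matrix(0, n, n)
  adj <- lapply(seq_len(n), function(v) {
    es <- igraph::incident(mst, v)
    ends <- igraph::ends(mst, es)
    other <- ifelse(ends[, 1L] == v, ends[, 2L], ends[, 1L])
    cbind(other, igraph::E(mst)$weight[as.integer(es)])
  })
  for (src in seq_len(n)) {
    # BFS over the tree carrying the running maximum edge weight
    visited <- logical(n)
    visited[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- adj[[v]]
      if (!is.null(nb) && nrow(nb)) {
        for (e in seq_len(nrow(nb))) {
          u <- nb[e, 1L]
          if (!visited[u]) {
            visited[u] <- TRUE
            mm[src, u] <- max(mm[src, v], nb[e, 2L])
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  mm
}

# epsilon-relaxed minimum spanning network: keep edge (u,v) when its
# distance does not exceed the bottleneck connection cost by more than
# epsilon. epsilon = 0 gives the classic MSN (union of all MSTs).
.msnEdges <- function(d, epsilon = 0) {
  mm <- .minimaxFromMst(d)
  keep <- d <= mm + epsilon & upper.tri(d)
  which(keep, arr.ind = TRUE)
}

# Quasi-medians of a state-vector triple: per-site majority, with all three
# states retained at fully heterogeneous sites (combinations capped).
.quasiMedians <- function(u, v, w, limit = 1000L) {
  L <- length(u)
  fixed <- integer(L)
  tieSites <- integer(0)
  for (s in seq_len(L)) {
    x <- c(u[s], v[s], w[s])
    tab <- sort(table(x), decreasing = TRUE)
    if (tab[1L] >= 2L) {
      fixed[s] <- as.integer(names(tab)[1L])
    } else {
      tieSites <- c(tieSites, s)
    }
  }
  if (!length(tieSites)) {
    return(matrix(fixed, nrow = 1L))
  }
  nComb <- 3^length(tieSites)
  if (nComb > limit) {
    warning(sprintf(
      "quasi-median combination count %d capped at %d", nComb, limit
    ), call. = FALSE)
    nComb <- limit
  }
  out <- matrix(rep(fixed, each = nComb), nrow = nComb)
  for (ti in seq_along(tieSites)) {
    s <- tieSites[ti]
    opts <- c(u[s], v[s], w[s])
    period <- 3^(ti - 1L)
    out[, s] <- opts[((seq_len(nComb) - 1L) %/% period) %% 3L + 1L]
  }
  out
}

#' Median-joining haplotype network
#'
#' Implements the Bandelt median-joining procedure on the segregating
#' columns of a haplotype table: iteratively build the epsilon-relaxed
#' minimum spanning network over the current node set, add quasi-median
#' (per-site majority) vectors for mutually connected triples, repeat to a
#' fixpoint, and finally prune median vectors that lie on no shortest path
#' between observed haplotypes. Edge weights are substitution counts;
#' character weights are uniform.
#'
#' @param haps a [HaplotypeTable] with >= 2 haplotypes over A/C/G/T (filter
#'   gaps first).
#' @param epsilon nonnegative integer relaxation parameter (0, the usual
#'   default, retains only minimum-spanning links).
#' @param medianLimit cap on quasi-median combinations per triple.
#' @param maxIter safety cap on median-addition rounds.
#' @return a [HaplotypeNetwork].
#' @export
buildMjNetwork <- function(haps, epsilon = 0L, medianLimit = 1000L,
                           maxIter = 25L) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  im <- .intMatrix(haps@haplotypes)
  if (anyNA(im)) {
    stop("network construction requires pure A/C/G/T haplotypes; filter sites first",
      call. = FALSE
    )
  }
  if (nrow(im) < 2L) stop("need at least two haplotypes", call. = FALSE)
  seg <- which(apply(im, 2L, function(col) length(unique(col)) > 1L))
  if (!length(seg)) seg <- 1L # identical haplotypes cannot occur post-collapse
  states <- im[, seg, drop = FALSE]
  nObs <- nrow(states)
  key <- function(m) apply(m, 1L, paste0, collapse = ",")
  nodeKeys <- key(states)
  for (iter in seq_len(maxIter)) {
    d <- .hammingMatrix(states)
    edges <- .msnEdges(d, epsilon)
    g <- igraph::make_empty_graph(n = nrow(states), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    tri <- igraph::triangles(g)
    newRows <- NULL
    if (length(tri)) {
      triM <- matrix(as.integer(tri), ncol = 3L, byrow = TRUE)
      for (r in seq_len(nrow(triM))) {
        qm <- .quasiMedians(
          states[triM[r, 1L], ], states[triM[r, 2L], ],
          states[triM[r, 3L], ], medianLimit
        )
        newRows <- rbind(newRows, qm)
      }
    }
    if (is.null(newRows)) break
    newRows <- newRows[!duplicated(key(newRows)) & !(key(newRows) %in% nodeKeys), , drop = FALSE]
    if (!nrow(newRows)) break
    states <- rbind(states, newRows)
    nodeKeys <- c(nodeKeys, key(newRows))
  }
  # final network over the augmented node set
  d <- .hammingMatrix(states)
  edges <- .msnEdges(d, epsilon)
  weights <- d[edges]
  labels <- c(
    rownames(im),
    if (nrow(states) > nObs) paste0("mv", seq_len(nrow(states) - nObs))
  )
  g <- igraph::make_empty_graph(n = nrow(states), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- weights
  igraph::V(g)$name <- labels
  # prune medians not on any shortest observed-to-observed path
  repeat {
    nNodes <- igraph::vcount(g)
    medIdx <- which(seq_len(nNodes) > nObs)
    if (!length(medIdx)) break
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    onPath <- vapply(medIdx, function(v) {
      any(outer(
        sp[seq_len(nObs), v], sp[v, seq_len(nObs)],
        "+"
      ) <= sp[seq_len(nObs), seq_len(nObs)] + 1e-9 &
        sp[seq_len(nObs), seq_len(nObs)] > 0)
    }, TRUE)
    drop <- medIdx[!onPath]
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
    states <- states[-drop, , drop = FALSE]
  }
  labels <- igraph::V(g)$name
  freq <- rowSums(haps@counts)[labels]
  freq[is.na(freq)] <- 0
  popFreq <- matrix(0L, length(labels), ncol(haps@counts),
    dimnames = list(labels, colnames(haps@counts))
  )
  obsRows <- labels %in% rownames(haps@counts)
  popFreq[obsRows, ] <- haps@counts[labels[obsRows], , drop = FALSE]
  nodes <- data.frame(
    id = labels,
    type = ifelse(obsRows, "observed", "median"),
    frequency = as.integer(freq),
    stringsAsFactors = FALSE
  )
  nodes <- cbind(nodes, as.data.frame(popFreq))
  methods::new("HaplotypeNetwork",
    graph = g, nodes = nodes,
    sequences = stats::setNames(apply(states, 1L, paste0, collapse = ","), labels)
  )
}

#' Export a haplotype network
#'
#' Writes the graph as GML, the edges as a TSV (`from`, `to`,
#' `substitutions`) and the node table (per-population frequencies, ready
#' for pie-chart plotting) as a TSV.
#'
#' @param net a [HaplotypeNetwork].
#' @param gmlPath,edgesPath,nodesPath output files (NULL to skip any).
#' @return invisible NULL.
#' @export
exportNetwork <- function(net, gmlPath = NULL, edgesPath = NULL,
                          nodesPath = NULL) {
  if (!is.null(gmlPath)) {
    igraph::write_graph(net@graph, gmlPath, format = "gml")
  }
  if (!is.null(edgesPath)) {
    ends <- igraph::ends(net@graph, igraph::E(net@graph))
    utils::write.table(
      data.frame(
        from = ends[, 1L], to = ends[, 2L],
        substitutions = igraph::E(net@graph)$weight
      ),
      edgesPath,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(nodesPath)) {
    utils::write.table(net@nodes, nodesPath,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  invisible(NULL)
}

#' Total substitution length of a network
#'
#' @param net a [HaplotypeNetwork].
#' @return sum of edge weights.
#' @export
networkLength <- function(net) sum(igraph::E(net@graph)$weight)
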