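#' Kimura two-parameter distance matrix
#'
#' For each sequence pair, with P the proportion of sites differing by a
#' transition and Q by a transversion,
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#' Pairs at or beyond the model's saturation boundary (1-2P-Q <= 0 or
#' 1-2Q <= 0) raise an error naming the pair.
#'
#' @param x a [HaplotypeTable] (distances between haplotypes, the usual
#'   choice) or a [PopAlignment] (distances between individuals).
#' @return symmetric numeric matrix of distances in substitutions/site.
#' @export
k2pMatrix <- function(x) {
  seqs <- if (methods::is(x, "HaplotypeTable")) x@haplotypes else x@seqs
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  im <- .intMatrix(seqs)
  n <- nrow(im)
  L <- ncol(im)
  labels <- rownames(im)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  isPurine <- function(b) b == 1L | b == 3L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- im[i, ]
      b <- im[j, ]
      diff <- a != b
      if (!any(diff)) next
      ts <- sum(diff & (isPurine(a) == isPurine(b)))
      tv <- sum(diff) - ts
      P <- ts / L
      Q <- tv / L
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) {
        stop(sprintf(
          "K2P distance undefined (saturation) for pair %s / %s",
          labels[i], labels[j]
        ), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Studier-Keppler criterion, as implemented
#' in ape). Negative branch lengths, which NJ can produce on non-additive
#' matrices, are truncated to zero; the returned tree then carries
#' attribute `truncated = TRUE`.
#'
#' @param dm symmetric distance matrix with labels (>= 2 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("neighbor joining needs at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);",
      rownames(dm)[1L], dm[1L, 2L] / 2, rownames(dm)[2L], dm[1L, 2L] / 2
    ))
    return(tr)
  }
  tr <- ape::nj(dm)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths truncated to zero", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "truncated") <- TRUE
  }
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and reports for each internal edge of the point-estimate
#' tree the percentage of replicates containing that bipartition.
#' Replicates whose resampled K2P distances are undefined are dropped (and
#' counted; a warning is raised past 5% drops).
#'
#' @param haps a [HaplotypeTable] (or [PopAlignment]).
#' @param reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return the NJ tree with `node.label` holding supports in percent
#'   (NA for the root), plus attributes `dropped` and `reps`.
#' @export
bootstrapSupport <- function(haps, reps = 1000, seed = 1L) {
  reps <- .checkCount(reps, "reps")
  seqs <- if (methods::is(haps, "HaplotypeTable")) haps@haplotypes else haps@seqs
  im <- .intMatrix(seqs)
  if (all(apply(im, 2L, function(col) length(unique(col)) == 1L))) {
    warning("alignment has no variation: bootstrap supports undefined",
      call. = FALSE
    )
    tr <- ape::stree(nrow(im), tip.label = rownames(im))
    tr$node.label <- rep(NA_real_, tr$Nnode)
    return(tr)
  }
  point <- neighborJoining(.k2pFromInt(im, rownames(im)))
  set.seed(seed)
  trees <- vector("list", reps)
  dropped <- 0L
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(im), ncol(im), replace = TRUE)
    tr <- tryCatch(
      suppressWarnings(neighborJoining(.k2pFromInt(im[, cols, drop = FALSE], rownames(im)))),
      error = function(e) NULL
    )
    if (is.null(tr)) dropped <- dropped + 1L else trees[[r]] <- tr
  }
  trees <- Filter(Negate(is.null), trees)
  if (dropped > 0.05 * reps) {
    warning(sprintf(
      "%d of %d bootstrap replicates dropped (undefined distances)",
      dropped, reps
    ), call. = FALSE)
  }
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  support <- 100 * counts / length(trees)
  point$node.label <- support
  attr(point, "dropped") <- dropped
  attr(point, "reps") <- reps
  point
}

# K2P on an integer-coded matrix without rebuilding DNAStringSets.
.k2pFromInt <- function(im, labels) {
  n <- nrow(im)
  L <- ncol(im)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  pur <- im == 1L | im == 3L
  for (i in seq_len(n - 1L)) {
    ai <- im[i, ]
    pi_ <- pur[i, ]
    for (j in (i + 1L):n) {
      diff <- ai != im[j, ]
      nd <- sum(diff)
      if (nd == 0L) next
      ts <- sum(diff & (pi_ == pur[j, ]))
      P <- ts / L
      Q <- (nd - ts) / L
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) {
        stop("saturated pair in bootstrap replicate", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
    }
  }
  d
}

#' Serialize a tree to newick
#'
#' Bootstrap supports stored in `node.label` become internal node labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path output file (NULL returns the newick string).
#' @return the newick string, invisibly when written to file.
#' @export
writeNewick <- function(tree, path = NULL) {
  if (is.null(path)) {
    return(ape::write.tree(tree))
  }
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname writeNewick
#' @param text newick string (alternative to `path`).
#' @export
readNewick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param dm symmetric labelled distance matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhylipDistances <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(
      formatC(rownames(dm)[i], width = -10),
      paste(sprintf("%.6f", dm[i, ]), collapse = " ")
    ), con)
  }
  invisible(path)
}
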