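#' Construct a PopAlignment from sequences and a population assignment
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) of
#'   aligned, equal-length sequences. `U` is mapped to `T` and letters are
#'   upcased. Ambiguity codes other than `N` are rejected: the downstream
#'   statistics have no defined handling for them.
#' @param population a named character vector or factor, one population
#'   label per sequence id. Order of first appearance fixes the population
#'   ordering unless a factor with explicit levels is given.
#' @return a validated [PopAlignment].
#' @export
PopAlignment <- function(seqs, population) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", seqs)))
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  if (is.null(names(population))) {
    if (length(population) != length(seqs)) {
      stop("unnamed population vector must match sequence count", call. = FALSE)
    }
    names(population) <- ids
  }
  missingIds <- setdiff(ids, names(population))
  if (length(missingIds)) {
    stop(sprintf(
      "population map is missing sequence id(s): %s",
      paste(utils::head(missingIds, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  extraIds <- setdiff(names(population), ids)
  if (length(extraIds)) {
    stop(sprintf(
      "population map id(s) absent from the alignment: %s",
      paste(utils::head(extraIds, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  pop <- population[ids]
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(unname(pop)))
  names(pop) <- ids
  w <- Biostrings::width(seqs)
  if (length(seqs) && length(unique(w)) > 1L) {
    bad <- ids[w != stats::median(w)]
    if (!length(bad)) bad <- ids[w != w[1L]]
    stop(sprintf(
      "sequences are not aligned; offending id(s): %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  methods::new("PopAlignment", seqs = seqs, population = pop)
}

#' Read an aligned FASTA plus a population map
#'
#' Reads a standard multi-FASTA of aligned sequences and a two-column
#' tab-separated population map (`id<TAB>population`, `#` comments and blank
#' lines allowed), validates the pairing, and returns a [PopAlignment].
#'
#' @param fastaPath path to the aligned multi-FASTA file.
#' @param popmapPath path to the population map TSV.
#' @return a [PopAlignment].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' pm <- tempfile(fileext = ".tsv")
#' writeLines(c(">a", "ACGTT", ">b", "ACGAT"), fa)
#' writeLines(c("a\tNorth", "b\tSouth"), pm)
#' aln <- readAlignment(fa, pm)
#' @export
readAlignment <- function(fastaPath, popmapPath) {
  if (!file.exists(fastaPath)) {
    stop(sprintf("FASTA file not found: %s", fastaPath), call. = FALSE)
  }
  if (!file.exists(popmapPath)) {
    stop(sprintf("population map not found: %s", popmapPath), call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences", call. = FALSE)
  # first whitespace-delimited token of the header is the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pm <- readPopmap(popmapPath)
  PopAlignment(Biostrings::DNAStringSet(toupper(seqs)), pm)
}

#' @rdname readAlignment
#' @export
readPopmap <- function(popmapPath) {
  lines <- readLines(popmapPath, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("population map is empty", call. = FALSE)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) {
    stop("population map rows must have two tab-separated columns", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  pops <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "duplicated id(s) in population map: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ), call. = FALSE)
  }
  stats::setNames(pops, ids)
}

#' Remove alignment columns with gaps or missing data
#'
#' Under the `"complete"` policy every column containing `-` or `N` in any
#' sequence is dropped before statistics are computed, so all downstream
#' distances and site counts refer to the same set of fully resolved sites.
#'
#' @param aln a [PopAlignment].
#' @param policy `"complete"` (complete deletion, the default) or `"none"`.
#' @return a [PopAlignment] on the retained columns, with an integer
#'   attribute `siteMap` giving the original 1-based position of every kept
#'   column.
#' @export
filterSites <- function(aln, policy = c("complete", "none")) {
  policy <- match.arg(policy)
  cm <- .charMatrix(aln@seqs)
  keep <- if (policy == "none") {
    rep(TRUE, ncol(cm))
  } else {
    colSums(cm == "-" | cm == "N") == 0L
  }
  if (!any(keep)) {
    stop("no columns remain after removing gapped/missing sites", call. = FALSE)
  }
  out <- aln
  if (!all(keep)) {
    kept <- cm[, keep, drop = FALSE]
    seqs <- Biostrings::DNAStringSet(apply(kept, 1L, paste0, collapse = ""))
    names(seqs) <- rownames(cm)
    out <- methods::new("PopAlignment", seqs = seqs, population = aln@population)
  }
  attr(out, "siteMap") <- which(keep)
  out
}

#' Collapse identical sequences into haplotypes
#'
#' Identity is exact string equality over the (filtered) alignment columns.
#' Haplotypes are ordered by first occurrence and named H1, H2, ...;
#' per-population carrier counts are recorded.
#'
#' @param aln a [PopAlignment], normally after [filterSites()].
#' @return a [HaplotypeTable].
#' @export
collapseHaplotypes <- function(aln) {
  s <- as.character(aln@seqs)
  first <- !duplicated(s)
  hapSeq <- s[first]
  idx <- match(s, hapSeq)
  hapIds <- paste0("H", seq_along(hapSeq))
  haps <- Biostrings::DNAStringSet(hapSeq)
  names(haps) <- hapIds
  counts <- table(
    factor(idx, levels = seq_along(hapSeq)),
    aln@population
  )
  counts <- matrix(as.integer(counts),
    nrow = length(hapSeq),
    dimnames = list(hapIds, levels(aln@population))
  )
  methods::new("HaplotypeTable",
    haplotypes = haps, counts = counts,
    membership = stats::setNames(idx, names(aln@seqs))
  )
}

#' Classify variable sites and count substitution types
#'
#' A variable column is parsimony-informative when at least two distinct
#' bases are each carried by at least two sequences; otherwise it is a
#' singleton site. Transitions and transversions are counted over the
#' unordered pairs of distinct bases observed at each variable site
#' (A-G and C-T are transitions). Base frequencies are pooled over all
#' cells of the alignment.
#'
#' @param aln a [PopAlignment] after [filterSites()]; needs at least two
#'   sequences.
#' @return a list with elements `polymorphicSites`, `singletonSites`,
#'   `informativeSites`, `transitions`, `transversions`, `tvTsRatio`,
#'   `baseFreqs` and a per-site data.frame `sites` (1-based positions via
#'   the filter's site map when present).
#' @export
classifySites <- function(aln) {
  if (length(aln@seqs) < 2L) {
    stop("site classification needs at least two sequences", call. = FALSE)
  }
  cm <- .charMatrix(aln@seqs)
  siteMap <- attr(aln, "siteMap")
  if (is.null(siteMap)) siteMap <- seq_len(ncol(cm))
  ts <- 0L
  tv <- 0L
  cls <- character(ncol(cm))
  basesAt <- character(ncol(cm))
  for (j in seq_len(ncol(cm))) {
    tab <- table(cm[, j])
    tab <- tab[names(tab) %in% BASES]
    basesAt[j] <- paste(names(tab), collapse = "/")
    if (length(tab) < 2L) {
      cls[j] <- "constant"
      next
    }
    pairs <- utils::combn(names(tab), 2L)
    isTs <- .isTransition(pairs[1L, ], pairs[2L, ])
    ts <- ts + sum(isTs)
    tv <- tv + sum(!isTs)
    cls[j] <- if (sum(tab >= 2L) >= 2L) "informative" else "singleton"
  }
  np <- sum(cls != "constant")
  freqTab <- table(factor(cm[cm %in% BASES], levels = BASES))
  baseFreqs <- as.numeric(freqTab) / sum(freqTab)
  names(baseFreqs) <- BASES
  list(
    polymorphicSites = np,
    singletonSites = sum(cls == "singleton"),
    informativeSites = sum(cls == "informative"),
    transitions = ts,
    transversions = tv,
    tvTsRatio = if (ts > 0L) tv / ts else NA_real_,
    baseFreqs = baseFreqs,
    sites = data.frame(
      site = siteMap, class = cls, bases = basesAt,
      stringsAsFactors = FALSE
    )
  )
}

#' Write collapsed haplotypes to FASTA / site classes to TSV
#'
#' @param haps a [HaplotypeTable].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeFasta <- function(haps, path) {
  Biostrings::writeXStringSet(haps@haplotypes, path)
  invisible(path)
}

#' @rdname writeHaplotypeFasta
#' @param siteSummary the list returned by [classifySites()].
#' @export
writeSiteClasses <- function(siteSummary, path) {
  utils::write.table(siteSummary$sites, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
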