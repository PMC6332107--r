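# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Transition partners under the standard purine/pyrimidine classification.
.isTransition <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
    (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
.subSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(offset)) %%
    2147483629)
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Character matrix (sequences x sites) from a DNAStringSet alignment.
.charMatrix <- function(seqs) {
  m <- as.matrix(seqs)
  rownames(m) <- names(seqs)
  m
}

# Integer coding A=1 C=2 G=3 T=4; anything else (gap/N) becomes NA.
.intMatrix <- function(seqs) {
  cm <- .charMatrix(seqs)
  im <- matrix(match(cm, BASES), nrow = nrow(cm), dimnames = dimnames(cm))
  im
}

# Hamming distance matrix over the rows of an integer-coded alignment
# (no missing data expected after complete-deletion filtering).
.hammingMatrix <- function(im) {
  n <- nrow(im)
  d <- matrix(0L, n, n, dimnames = list(rownames(im), rownames(im)))
  if (n < 2L) {
    return(d)
  }
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    di <- colSums(im[i, ] != t(im[rest, , drop = FALSE]))
    d[i, rest] <- di
    d[rest, i] <- di
  }
  d
}

# All pairwise difference counts as a condensed vector (lower triangle).
.condensed <- function(m) m[lower.tri(m)]

.checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %d", name, min),
      call. = FALSE
    )
  }
  as.integer(x)
}
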