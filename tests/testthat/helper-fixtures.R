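## Shared fixtures and independent oracle implementations. Oracles here are
## deliberately naive (brute force / step-by-step) and independent of the
## package's code paths.

BASES <- c("A", "C", "G", "T")

rDNA <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

## Brute-force Hamming distance between equal-length strings.
hammingOracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

## All-pairs minimum Hamming distance of a barcode set.
minPairwiseHamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  best <- Inf
  for (i in seq_len(nrow(m) - 1L))
    for (j in seq(i + 1L, nrow(m)))
      best <- min(best, sum(m[i, ] != m[j, ]))
  best
}

## Step-by-step reference implementation of greedy count-ordered clustering,
## using utils::adist (independent of the package's C++ distance core).
greedyClusterOracle <- function(counts, maxDist) {
  ord <- order(-counts, names(counts), method = "radix")
  seqs <- names(counts)[ord]
  cnts <- unname(counts[ord])
  centroids <- character(0)
  membership <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in seq_along(centroids)) {
      if (utils::adist(seqs[i], centroids[c]) <= maxDist) { hit <- c; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, seqs[i])
      hit <- length(centroids)
    }
    membership[i] <- hit
  }
  list(centroids = centroids, membership = membership, seqs = seqs,
       counts = cnts)
}

## Substitution-only mutation, independent of the package's simulator.
mutateSubsOracle <- function(s, nSubs, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(v), nSubs)
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1)
  paste(v, collapse = "")
}

rcOracle <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
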