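## Binning reads by (sample, position) and splitting heterogeneous wells by
## read-length mixture modelling.

#' Filter reads by length
#'
#' @param reads character vector or \link[Biostrings]{DNAStringSet}.
#' @param minLen,maxLen inclusive length bounds.
#' @return The retained reads (same container type as the input).
#' @examples
#' filterReadsBySize(c(a = "ACGT", b = "ACGTACGTACGT"), 5, 100)
#' @export
filterReadsBySize <- function(reads, minLen = 0, maxLen = Inf) {
  stopifnot(minLen >= 0, minLen <= maxLen)
  len <- if (is(reads, "DNAStringSet")) width(reads) else nchar(reads)
  reads[len >= minLen & len <= maxLen]
}

#' Bin reads by (sample, position) address
#'
#' Reads whose sample or position is unassigned are diverted to an
#' "unbinned" sink rather than dropped, so the read multiset is preserved
#' across bins plus sink.
#'
#' @param reads named character vector (or \link[Biostrings]{DNAStringSet})
#'   of read sequences.
#' @param sampleIds character vector of per-read sample ids (NA = unassigned).
#' @param positionIds character vector of per-read position ids
#'   (NA = unassigned).
#' @return List with \code{bins} (list of \linkS4class{ReadBin}, named
#'   \code{sample/position}) and \code{sink} (named character vector of
#'   unassigned reads).
#' @examples
#' binReads(c(r1 = "ACGT", r2 = "ACGT"), c("s1", "s1"), c("P1_A01", NA))
#' @export
binReads <- function(reads, sampleIds, positionIds) {
  if (is(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  stopifnot(length(sampleIds) == length(reads),
            length(positionIds) == length(reads))
  ok <- !is.na(sampleIds) & !is.na(positionIds)
  sink <- reads[!ok]
  key <- paste(sampleIds[ok], positionIds[ok], sep = "/")
  idx <- split(which(ok), key)
  bins <- lapply(names(idx), function(k) {
    i <- idx[[k]]
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    readBin_(parts[1L], parts[2L], reads[i])
  })
  names(bins) <- names(idx)
  list(bins = bins, sink = sink)
}

## One-dimensional Gaussian mixture by EM with quantile initialisation.
## Returns NULL when the fit is invalid (degenerate or empty component).
fitGMM1D <- function(x, k, tol = 1e-6, maxIter = 200L) {
  n <- length(x)
  if (k == 1L) {
    s <- max(sd(x) * sqrt((n - 1) / n), 1e-8)
    ll <- sum(dnorm(x, mean(x), s, log = TRUE))
    return(list(k = 1L, weight = 1, mean = mean(x), sd = s,
                logLik = ll, assignment = rep(1L, n)))
  }
  mu <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                            names = FALSE))
  s <- rep(max(sd(x) / k, 1e-8), k)
  w <- rep(1 / k, k)
  minSD <- max(diff(range(x)) * 1e-6, 1e-8)
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    rowTot <- rowSums(dens)
    if (any(rowTot <= 0) || any(!is.finite(rowTot))) return(NULL)
    resp <- dens / rowTot
    newLL <- sum(log(rowTot))
    nk <- colSums(resp)
    if (any(nk < 1)) return(NULL)  # effectively empty component
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, minSD^2))
    if (is.finite(ll) && abs(newLL - ll) < tol) { ll <- newLL; break }
    ll <- newLL
  }
  dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                 numeric(n))
  assignment <- max.col(dens, ties.method = "first")
  if (length(unique(assignment)) < k) return(NULL)  # empty hard component
  list(k = k, weight = w, mean = mu, sd = s, logLik = ll,
       assignment = assignment)
}

gmmBIC <- function(fit, n) -2 * fit$logLik + (3 * fit$k - 1) * log(n)

#' Split a read bin into plasmid species by read-length mixture modelling
#'
#' Fits 1..\code{maxComponents} one-dimensional Gaussian mixtures to the read
#' lengths by EM (quantile-based initialisation, tolerance 1e-6, at most 200
#' iterations), selects the component count by BIC among fits without empty
#' components, and assigns each read to its maximum-responsibility component.
#' Bins below \code{minReadsToSplit} reads, or with identical lengths, are
#' returned unsplit.
#'
#' @param bin a \linkS4class{ReadBin}.
#' @param maxComponents maximum mixture components (default 3).
#' @param minReadsToSplit minimum bin size to attempt a split (default 10).
#' @param seed unused placeholder for interface stability; the fit is fully
#'   deterministic (quantile initialisation), so no randomness is consumed.
#' @return List of \linkS4class{ReadBin}, one per selected component (in
#'   ascending component-mean order), each with \code{lengthCluster} set.
#' @examples
#' b <- ReadBin("s1", "P1_A01",
#'              setNames(strrep("ACGT", c(5, 5, 250, 250, 251)),
#'                       paste0("r", 1:5)))
#' length(splitByLengthGMM(b, minReadsToSplit = 2))
#' @export
splitByLengthGMM <- function(bin, maxComponents = 3L, minReadsToSplit = 10L,
                             seed = NULL) {
  stopifnot(is(bin, "ReadBin"))
  n <- nReads(bin)
  if (n == 0L) stop("cannot split an empty bin")
  lens <- width(bin@reads)
  if (n < minReadsToSplit || length(unique(lens)) == 1L) {
    bin@lengthCluster <- 1L
    return(list(bin))
  }
  fits <- list()
  for (k in seq_len(min(maxComponents, length(unique(lens))))) {
    f <- fitGMM1D(lens, k)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  bics <- vapply(fits, gmmBIC, numeric(1), n = n)
  best <- fits[[which.min(bics)]]
  ord <- order(best$mean[seq_len(best$k)])
  relabel <- match(best$assignment, ord)
  lapply(seq_len(best$k), function(comp) {
    sel <- relabel == comp
    readBin_(bin@sampleId, bin@positionId, bin@reads[sel],
             lengthCluster = comp)
  })
}
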