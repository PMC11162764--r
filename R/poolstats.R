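## Pool dispersion and demultiplexing expectation statistics.

#' Gini coefficient of a design abundance vector
#'
#' Population mean-absolute-difference form,
#' G = sum_ij |x_i - x_j| / (2 n^2 xbar), computed via the sorted-vector
#' identity. A uniform abundance vector has G exactly 0; a single-spike
#' vector attains the upper bound (n - 1)/n. G is invariant to positive
#' scaling, so counts and frequencies give the same value.
#'
#' @param x an \linkS4class{AbundanceVector} or a non-negative numeric
#'   vector with a positive sum.
#' @return Gini coefficient in [0, 1).
#' @examples
#' giniCoefficient(c(5, 5, 5, 5))   # 0
#' giniCoefficient(c(0, 0, 0, 1))   # 0.75
#' @export
setGeneric("giniCoefficient", function(x) standardGeneric("giniCoefficient"))

#' @rdname giniCoefficient
#' @export
setMethod("giniCoefficient", "numeric", function(x) {
  n <- length(x)
  if (n < 1L) stop("need at least one abundance")
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("Gini is undefined for an all-zero vector")
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
})

#' @rdname giniCoefficient
#' @export
setMethod("giniCoefficient", "AbundanceVector",
          function(x) giniCoefficient(counts(x)))

#' Change in pool dispersion between two protocol stages
#'
#' @param before,after abundance vectors (\linkS4class{AbundanceVector} or
#'   numeric) at the earlier and later stage.
#' @return G_after - G_before.
#' @examples
#' deltaGini(c(1, 1, 1, 1), c(0, 0, 0, 1))  # 0.75
#' @export
deltaGini <- function(before, after) {
  giniCoefficient(after) - giniCoefficient(before)
}

#' Expected fraction of designs recovered at a clone sampling depth
#'
#' Assumes the probability of sampling one design equals its empirical pool
#' frequency: with N = samplingDepth * n independent draws (sampling with
#' replacement), the expected recovered fraction is
#' mean_i [1 - (1 - p_i)^N].
#'
#' @param frequencies an \linkS4class{AbundanceVector} or numeric abundances
#'   (normalised internally).
#' @param samplingDepth average clones picked per design.
#' @return Expected recovered fraction in [0, 1].
#' @examples
#' expectedRecovery(rep(1 / 100, 100), 7)  # 1 - 0.99^700
#' @export
expectedRecovery <- function(frequencies, samplingDepth) {
  if (is(frequencies, "AbundanceVector")) frequencies <- counts(frequencies)
  stopifnot(samplingDepth >= 0)
  p <- frequencies / sum(frequencies)
  N <- round(samplingDepth * length(p))
  mean(1 - (1 - p)^N)
}

#' Expected fraction of sequences carrying at least one synthesis error
#'
#' 1 - (1 - rate)^length. At the vendor-reported rate of 4e-4 errors/nt and
#' 300 nt, about 11.3\% of pool molecules are predicted to carry an error.
#'
#' @param perBaseErrorRate per-base error probability in [0, 1].
#' @param length sequence length in nt.
#' @return Fraction in [0, 1].
#' @examples
#' expectedErrorFraction(4e-4, 300)
#' @export
expectedErrorFraction <- function(perBaseErrorRate, length) {
  assertProb(perBaseErrorRate, "perBaseErrorRate")
  stopifnot(length >= 0)
  1 - (1 - perBaseErrorRate)^length
}

#' Base substitution error rate from consensus-reference alignments
#'
#' Total substitution count over total aligned reference bases, across all
#' supplied pairs.
#'
#' @param consensus character vector of consensus sequences.
#' @param reference character vector of matched reference sequences
#'   (parallel to \code{consensus}).
#' @return Substitution errors per reference nt.
#' @examples
#' substitutionErrorRate("ACGA", "ACGT")  # 1/4
#' @export
substitutionErrorRate <- function(consensus, reference) {
  stopifnot(length(consensus) == length(reference), length(consensus) >= 1L)
  denom <- sum(nchar(reference))
  if (denom == 0L) stop("zero aligned reference bases")
  subs <- vapply(seq_along(consensus), function(i)
    attr(adist(reference[i], consensus[i], counts = TRUE),
         "counts")[1L, 1L, "sub"], numeric(1))
  sum(subs) / denom
}

#' Pearson correlation of design abundances between two stages
#'
#' Standard product-moment correlation on the per-design counts (raw
#' abundances, no log transform), with two-sided significance from the
#' t-distribution. Inputs are matched by design id when both carry names.
#'
#' @param stageA,stageB \linkS4class{AbundanceVector}s or numeric vectors.
#' @return List: \code{r}, \code{p.value}, \code{n}.
#' @examples
#' abundanceCorrelation(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 7))
#' @export
abundanceCorrelation <- function(stageA, stageB) {
  if (is(stageA, "AbundanceVector")) stageA <- counts(stageA)
  if (is(stageB, "AbundanceVector")) stageB <- counts(stageB)
  if (!is.null(names(stageA)) && !is.null(names(stageB))) {
    shared <- intersect(names(stageA), names(stageB))
    stageA <- stageA[shared]
    stageB <- stageB[shared]
  }
  if (length(stageA) != length(stageB))
    stop("stages must cover the same designs")
  if (length(stageA) < 3L) stop("need at least 3 matched designs")
  if (sd(stageA) == 0 || sd(stageB) == 0)
    stop("correlation undefined for a zero-variance stage")
  ct <- stats::cor.test(stageA, stageB, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(stageA))
}

#' Multiplexing capacity of an indexed barcode array
#'
#' The number of positions addressable in parallel: sample indices times
#' positional barcodes. With 96 library indices and a 768-barcode array this
#' is 73728.
#'
#' @param nIndices number of sample indices (default 96).
#' @param nBarcodes number of positional barcodes (default 768).
#' @return Integer capacity.
#' @examples
#' multiplexingCapacity()  # 73728
#' @export
multiplexingCapacity <- function(nIndices = 96L, nBarcodes = 768L) {
  as.integer(nIndices) * as.integer(nBarcodes)
}
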