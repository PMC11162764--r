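## Accessor generics for the S4 data objects.

#' Number of reads behind an object
#' @param x a \linkS4class{ReadBin} or \linkS4class{ConsensusCall}.
#' @return integer read count.
#' @examples
#' nReads(ReadBin("s1", "P1_A01", c(r1 = "ACGT")))
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname nReads
#' @export
setMethod("nReads", "ReadBin", function(x) length(x@reads))

#' @rdname nReads
#' @export
setMethod("nReads", "ConsensusCall", function(x) x@nReads)

#' Consensus sequence of a call
#' @param x a \linkS4class{ConsensusCall}.
#' @return character consensus sequence.
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname consensusSequence
#' @export
setMethod("consensusSequence", "ConsensusCall", function(x) x@sequence)

#' Per-read end-to-end identities of a consensus call
#' @param x a \linkS4class{ConsensusCall}.
#' @return numeric vector of identities in [0, 1].
#' @export
setGeneric("perReadIdentity", function(x) standardGeneric("perReadIdentity"))

#' @rdname perReadIdentity
#' @export
setMethod("perReadIdentity", "ConsensusCall", function(x) x@perReadIdentity)

#' Correctness category of a call
#' @param x a \linkS4class{CorrectnessCall}.
#' @return character scalar category.
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname category
#' @export
setMethod("category", "CorrectnessCall", function(x) x@category)

#' Design counts of an abundance vector
#' @param x an \linkS4class{AbundanceVector}.
#' @return named numeric counts.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "AbundanceVector", function(x) x@counts)

#' Protocol stage label of an abundance vector
#' @param x an \linkS4class{AbundanceVector}.
#' @return character stage label (possibly NA).
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname stage
#' @export
setMethod("stage", "AbundanceVector", function(x) x@stage)

#' Design frequencies of an abundance vector
#' @param x an \linkS4class{AbundanceVector} (or bare numeric counts).
#' @return named numeric frequencies summing to 1.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname frequencies
#' @export
setMethod("frequencies", "AbundanceVector", function(x) {
  s <- sum(x@counts)
  if (s <= 0) stop("cannot normalise an all-zero abundance vector")
  x@counts / s
})

#' @rdname frequencies
#' @export
setMethod("frequencies", "numeric", function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot normalise an all-zero abundance vector")
  x / s
})

#' Reads held by a bin
#' @param x a \linkS4class{ReadBin}.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
setGeneric("binReadsSet", function(x) standardGeneric("binReadsSet"))

#' @rdname binReadsSet
#' @export
setMethod("binReadsSet", "ReadBin", function(x) x@reads)

#' Construct a ReadBin
#'
#' @param sampleId,positionId the bin address.
#' @param reads named character vector or \link[Biostrings]{DNAStringSet}.
#' @param lengthCluster optional length-mixture component index.
#' @return A \linkS4class{ReadBin}.
#' @examples
#' ReadBin("s1", "P1_A01", c(r1 = "ACGTACGT", r2 = "ACGTACGT"))
#' @export
ReadBin <- function(sampleId, positionId, reads,
                    lengthCluster = NA_integer_) {
  if (is.character(reads) && is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  readBin_(sampleId, positionId, reads, lengthCluster)
}
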