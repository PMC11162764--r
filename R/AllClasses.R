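## S4 classes for the central data objects.

#' BarcodeSetSpec: specification of a random barcode set
#'
#' Describes a set of random DNA barcodes with a minimum pairwise Hamming
#' distance, as used for positional barcode plates (donor barcodes are 15-mers,
#' recipient barcodes 20-mers with pairwise Hamming distance > 5 in the
#' reference design).
#'
#' @slot nBarcodes number of barcodes to generate.
#' @slot length barcode length in nucleotides.
#' @slot minHamming minimum pairwise Hamming distance between any two barcodes.
#' @slot alphabet character vector of allowed bases.
#' @slot seed integer RNG seed (NA for unseeded).
#' @exportClass BarcodeSetSpec
setClass("BarcodeSetSpec",
  representation(nBarcodes = "integer", length = "integer",
                 minHamming = "integer", alphabet = "character",
                 seed = "integer"),
  prototype(nBarcodes = 1L, length = 20L, minHamming = 0L,
            alphabet = c("A", "C", "G", "T"), seed = NA_integer_))

setValidity("BarcodeSetSpec", function(object) {
  msg <- character(0)
  if (object@nBarcodes < 1L) msg <- c(msg, "nBarcodes must be >= 1")
  if (object@length < 1L) msg <- c(msg, "length must be >= 1")
  if (object@minHamming < 0L || object@minHamming > object@length)
    msg <- c(msg, "minHamming must be in [0, length]")
  if (length(object@alphabet) < 2L)
    msg <- c(msg, "alphabet must contain at least two symbols")
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeSetSpec
#'
#' @param nBarcodes number of barcodes.
#' @param length barcode length in nt (recipient positional barcodes: 20;
#'   donor barcodes: 15).
#' @param minHamming minimum pairwise Hamming distance (reference design: 6,
#'   i.e. "distance > 5").
#' @param alphabet allowed bases.
#' @param seed integer seed, or NULL.
#' @return A \linkS4class{BarcodeSetSpec}.
#' @examples
#' barcodeSetSpec(96, length = 20, minHamming = 6, seed = 1)
#' @export
barcodeSetSpec <- function(nBarcodes, length = 20L, minHamming = 6L,
                           alphabet = c("A", "C", "G", "T"), seed = NULL) {
  new("BarcodeSetSpec", nBarcodes = as.integer(nBarcodes),
      length = as.integer(length), minHamming = as.integer(minHamming),
      alphabet = alphabet,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "BarcodeSetSpec", function(object) {
  cat("BarcodeSetSpec:", object@nBarcodes, "barcodes of", object@length,
      "nt, pairwise Hamming >=", object@minHamming, "\n")
})

#' SimConfig: parameters of the synthetic array-run generator
#'
#' Collects the stated world of the simulator: pool composition, synthesis
#' error rate, long-read error profile, per-position sequencing depth, and the
#' contamination/chimera processes.
#'
#' @slot nDesigns number of distinct DNA designs in the pool.
#' @slot designLength design (insert) length in nt.
#' @slot synthesisErrorRate per-base synthesis error probability (default 4e-4).
#' @slot abundanceDispersion log-normal sigma of design abundances (0 = uniform).
#' @slot readErrorRates named numeric: substitution, insertion, deletion
#'   per-base probabilities of the simulated long reads.
#' @slot meanDepth Poisson mean reads per array position (default 130).
#' @slot contaminationProb probability that a well carries two clones.
#' @slot chimeraProb probability that a read carries a barcode from another well.
#' @slot samplingDepth average clones picked per design.
#' @slot seed integer RNG seed (NA for unseeded).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nDesigns = "integer", designLength = "integer",
                 synthesisErrorRate = "numeric", abundanceDispersion = "numeric",
                 readErrorRates = "numeric", meanDepth = "numeric",
                 contaminationProb = "numeric", chimeraProb = "numeric",
                 samplingDepth = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nDesigns < 0L) msg <- c(msg, "nDesigns must be >= 0")
  if (object@designLength < 1L) msg <- c(msg, "designLength must be >= 1")
  p <- c(object@synthesisErrorRate, object@readErrorRates,
         object@contaminationProb, object@chimeraProb)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (!identical(sort(names(object@readErrorRates)),
                 c("deletion", "insertion", "substitution")))
    msg <- c(msg, "readErrorRates must be named substitution/insertion/deletion")
  if (object@meanDepth < 0) msg <- c(msg, "meanDepth must be >= 0")
  if (object@abundanceDispersion < 0)
    msg <- c(msg, "abundanceDispersion must be >= 0")
  if (object@samplingDepth < 0) msg <- c(msg, "samplingDepth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults mirror the reference protocol: 4e-4/nt synthesis errors, 300 nt
#' designs, Poisson(130) reads per position, and an ONT-simplex-like error
#' profile of 2\% substitutions, 1.5\% insertions and 2.5\% deletions per base.
#'
#' @param nDesigns,designLength pool composition.
#' @param synthesisErrorRate per-base synthesis error probability.
#' @param abundanceDispersion log-normal sigma for design abundances
#'   (0 gives a perfectly uniform pool).
#' @param readErrorRates numeric of length 3, named
#'   \code{c(substitution=, insertion=, deletion=)}.
#' @param meanDepth Poisson mean reads per position.
#' @param contaminationProb probability a well holds two clones.
#' @param chimeraProb probability a read carries a swapped barcode.
#' @param samplingDepth clones picked per design.
#' @param seed integer seed or NULL.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(nDesigns = 8, designLength = 300, seed = 1)
#' @export
simConfig <- function(nDesigns, designLength = 300L,
                      synthesisErrorRate = 4e-4, abundanceDispersion = 0,
                      readErrorRates = c(substitution = 0.02,
                                         insertion = 0.015, deletion = 0.025),
                      meanDepth = 130, contaminationProb = 0,
                      chimeraProb = 0, samplingDepth = 20, seed = NULL) {
  new("SimConfig", nDesigns = as.integer(nDesigns),
      designLength = as.integer(designLength),
      synthesisErrorRate = synthesisErrorRate,
      abundanceDispersion = abundanceDispersion,
      readErrorRates = readErrorRates, meanDepth = meanDepth,
      contaminationProb = contaminationProb, chimeraProb = chimeraProb,
      samplingDepth = samplingDepth,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nDesigns, "designs of", object@designLength, "nt\n",
      " synthesis error", object@synthesisErrorRate, "/nt; read errors",
      paste(sprintf("%s=%.3g", names(object@readErrorRates),
                    object@readErrorRates), collapse = " "), "\n",
      " mean depth", object@meanDepth,
      "; contamination", object@contaminationProb,
      "; chimera", object@chimeraProb, "\n")
})

#' BarcodeDefinition: fuzzy sequence context of a barcode
#'
#' Defines where a barcode sits in a read: an upstream and a downstream flank
#' (located allowing a bounded number of edits each), the admissible core
#' length range, and optional internal motif constraints (e.g. fixed AA/TT
#' anchors at given core positions).
#'
#' @slot upstreamFlank,downstreamFlank flanking DNA sequences.
#' @slot coreLengthMin,coreLengthMax admissible barcode core length (nt).
#' @slot maxFlankEdits maximum Levenshtein edits tolerated per flank.
#' @slot internalMotifs list of \code{list(motif=, window=c(lo, hi))}
#'   constraints on the core (1-based start window), possibly empty.
#' @exportClass BarcodeDefinition
setClass("BarcodeDefinition",
  representation(upstreamFlank = "character", downstreamFlank = "character",
                 coreLengthMin = "integer", coreLengthMax = "integer",
                 maxFlankEdits = "integer", internalMotifs = "list"))

setValidity("BarcodeDefinition", function(object) {
  msg <- character(0)
  ok <- function(x) length(x) == 1L && !is.na(x) && grepl("^[ACGT]+$", x)
  if (!ok(object@upstreamFlank) || !ok(object@downstreamFlank))
    msg <- c(msg, "flanks must be non-empty strings over {A,C,G,T}")
  if (object@coreLengthMin < 0L || object@coreLengthMin > object@coreLengthMax)
    msg <- c(msg, "need 0 <= coreLengthMin <= coreLengthMax")
  if (object@maxFlankEdits < 0L) msg <- c(msg, "maxFlankEdits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeDefinition
#'
#' @param upstreamFlank,downstreamFlank flank sequences over ACGT.
#' @param coreLengthMin,coreLengthMax admissible core length range.
#' @param maxFlankEdits per-flank edit budget (default 2; the reference
#'   pipeline's fuzzy-regex budget is unstated, so this is configurable).
#' @param internalMotifs optional list of
#'   \code{list(motif = "AA", window = c(5, 7))} constraints.
#' @return A \linkS4class{BarcodeDefinition}.
#' @examples
#' barcodeDefinition("ACGGTCTGAGCTGCCATGGA", "TGGTCCAGTCTTCAGGAACC",
#'                   coreLengthMin = 18, coreLengthMax = 22)
#' @export
barcodeDefinition <- function(upstreamFlank, downstreamFlank,
                              coreLengthMin, coreLengthMax,
                              maxFlankEdits = 2L, internalMotifs = list()) {
  new("BarcodeDefinition", upstreamFlank = upstreamFlank,
      downstreamFlank = downstreamFlank,
      coreLengthMin = as.integer(coreLengthMin),
      coreLengthMax = as.integer(coreLengthMax),
      maxFlankEdits = as.integer(maxFlankEdits),
      internalMotifs = internalMotifs)
}

setMethod("show", "BarcodeDefinition", function(object) {
  cat("BarcodeDefinition: ", object@upstreamFlank, " [",
      object@coreLengthMin, "-", object@coreLengthMax, " nt] ",
      object@downstreamFlank, " (<= ", object@maxFlankEdits,
      " edits/flank)\n", sep = "")
})

#' ReadBin: reads attributed to one (sample, position) address
#'
#' @slot sampleId sample index label.
#' @slot positionId known positional barcode id (e.g. "P1_A01").
#' @slot reads a \link[Biostrings]{DNAStringSet} of member reads (names are
#'   read ids).
#' @slot lengthCluster integer length-mixture component index, NA when the bin
#'   has not been split.
#' @exportClass ReadBin
setClass("ReadBin",
  representation(sampleId = "character", positionId = "character",
                 reads = "DNAStringSet", lengthCluster = "integer"),
  prototype(lengthCluster = NA_integer_))

setValidity("ReadBin", function(object) {
  msg <- character(0)
  if (length(object@sampleId) != 1L || length(object@positionId) != 1L)
    msg <- c(msg, "sampleId and positionId must be scalars")
  if (length(object@reads) > 0L && is.null(names(object@reads)))
    msg <- c(msg, "reads must be named by read id")
  if (length(msg)) msg else TRUE
})

readBin_ <- function(sampleId, positionId, reads, lengthCluster = NA_integer_) {
  if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
  new("ReadBin", sampleId = as.character(sampleId),
      positionId = as.character(positionId), reads = reads,
      lengthCluster = as.integer(lengthCluster))
}

setMethod("show", "ReadBin", function(object) {
  cat("ReadBin ", object@sampleId, "/", object@positionId, ": ",
      length(object@reads), " reads",
      if (!is.na(object@lengthCluster))
        paste0(" (length cluster ", object@lengthCluster, ")") else "",
      "\n", sep = "")
})

#' ConsensusCall: a polished per-position consensus
#'
#' @slot sequence the polished consensus sequence.
#' @slot nReads number of reads that informed the call.
#' @slot perReadIdentity end-to-end identity of each read to the consensus.
#' @slot rotationOffset 0-based rotation applied for circular canonicalisation.
#' @slot converged whether polishing reached a fixed point within the
#'   iteration budget.
#' @exportClass ConsensusCall
setClass("ConsensusCall",
  representation(sequence = "character", nReads = "integer",
                 perReadIdentity = "numeric", rotationOffset = "integer",
                 converged = "logical"),
  prototype(rotationOffset = 0L, converged = NA))

setValidity("ConsensusCall", function(object) {
  msg <- character(0)
  if (length(object@perReadIdentity) != object@nReads)
    msg <- c(msg, "perReadIdentity must have one entry per read")
  if (object@nReads >= 1L &&
      (length(object@sequence) != 1L || !nzchar(object@sequence)))
    msg <- c(msg, "sequence must be non-empty when nReads >= 1")
  if (any(object@perReadIdentity < 0 | object@perReadIdentity > 1))
    msg <- c(msg, "perReadIdentity values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusCall", function(object) {
  cat("ConsensusCall: ", nchar(object@sequence), " nt from ", object@nReads,
      " reads; median identity ",
      if (object@nReads) round(median(object@perReadIdentity), 3) else NA,
      "; converged: ", object@converged, "\n", sep = "")
})

#' CorrectnessCall: classification of a consensus against references
#'
#' Categories follow the reference workflow's classes: \code{perfect} (exact
#' match to a reference), \code{error} (maps to a reference with point
#' mutations or indels), \code{off_target} (maps only to the host genome),
#' \code{other} (maps to nothing), and \code{mixed} (position failed the
#' purity rule).
#'
#' @slot category one of perfect/error/off_target/other/mixed.
#' @slot matchedRef id of the best-matching reference, or NA.
#' @slot nSubstitutions,nInsertions,nDeletions edit counts of the consensus
#'   relative to the matched reference.
#' @exportClass CorrectnessCall
setClass("CorrectnessCall",
  representation(category = "character", matchedRef = "character",
                 nSubstitutions = "integer", nInsertions = "integer",
                 nDeletions = "integer"),
  prototype(matchedRef = NA_character_, nSubstitutions = 0L,
            nInsertions = 0L, nDeletions = 0L))

setValidity("CorrectnessCall", function(object) {
  msg <- character(0)
  cats <- c("perfect", "error", "off_target", "other", "mixed")
  if (!(object@category %in% cats))
    msg <- c(msg, paste("category must be one of:", paste(cats, collapse = ", ")))
  edits <- c(object@nSubstitutions, object@nInsertions, object@nDeletions)
  if (object@category == "perfect" &&
      (any(edits != 0L) || is.na(object@matchedRef)))
    msg <- c(msg, "a perfect call must have zero edits and a matched reference")
  if (any(edits < 0L)) msg <- c(msg, "edit counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrectnessCall", function(object) {
  cat("CorrectnessCall:", object@category,
      if (!is.na(object@matchedRef)) paste0("(ref ", object@matchedRef, ")") else "",
      sprintf("subs=%d ins=%d dels=%d\n", object@nSubstitutions,
              object@nInsertions, object@nDeletions))
})

#' AbundanceVector: design-indexed counts at one protocol stage
#'
#' @slot counts named non-negative numeric vector of per-design counts.
#' @slot stage label of the protocol stage the counts were measured at
#'   (e.g. "original dsDNA", "amplicon", "plated clones", "arrayed clones").
#' @exportClass AbundanceVector
setClass("AbundanceVector",
  representation(counts = "numeric", stage = "character"),
  prototype(stage = NA_character_))

setValidity("AbundanceVector", function(object) {
  msg <- character(0)
  if (length(object@counts) == 0L) msg <- c(msg, "counts must be non-empty")
  if (any(is.na(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by design id")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceVector
#'
#' @param counts named non-negative numeric vector (design id -> count).
#' @param stage optional protocol stage label.
#' @return An \linkS4class{AbundanceVector}.
#' @examples
#' abundanceVector(c(d1 = 5, d2 = 5, d3 = 5), stage = "amplicon")
#' @export
abundanceVector <- function(counts, stage = NA_character_) {
  if (is.null(names(counts)))
    names(counts) <- paste0("design_", seq_along(counts))
  new("AbundanceVector",
      counts = setNames(as.numeric(counts), names(counts)),
      stage = as.character(stage))
}

setMethod("show", "AbundanceVector", function(object) {
  cat("AbundanceVector:", length(object@counts), "designs",
      if (!is.na(object@stage)) paste0("[", object@stage, "]") else "",
      "; total", sum(object@counts), "\n")
})
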