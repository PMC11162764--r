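## Per-bin consensus building: trim reads to the insert, star-align to a
## medoid read, per-column plurality vote, iterative polish, and canonical
## rotation for circular sequences.

#' Trim reads to the insert between two flanking reference sequences
#'
#' Locates the two trimming flanks with the same fuzzy machinery as
#' \code{\link{extractBarcodeFuzzy}} and returns the enclosed subsequence,
#' orientation-normalised to the forward strand of the flank pair. Reads
#' missing either flank yield NA.
#'
#' @param reads character vector (or \link[Biostrings]{DNAStringSet}).
#' @param flankRefs character vector of length 2: upstream and downstream
#'   trimming sequence.
#' @param maxEdits per-flank edit budget (default 2).
#' @return Character vector of trimmed inserts (NA where a flank is absent).
#' @examples
#' trimToInsert(paste0(arrayContext[["insUp"]], "ACGTACGTAC",
#'                     arrayContext[["insDown"]]),
#'              c(arrayContext[["insUp"]], arrayContext[["insDown"]]))
#' @export
trimToInsert <- function(reads, flankRefs, maxEdits = 2L) {
  stopifnot(length(flankRefs) == 2L)
  assertDNA(flankRefs, "flankRefs")
  def <- barcodeDefinition(flankRefs[1L], flankRefs[2L],
                           coreLengthMin = 0L, coreLengthMax = .Machine$integer.max,
                           maxFlankEdits = maxEdits)
  extractBarcodeFuzzy(reads, def)$barcode
}

## Align reads to a template (unit-cost global alignment via adist trafos)
## and apply a gap-aware per-column plurality vote. Ties break toward the
## current template base, then lexicographically (gap last). Insertions are
## accepted at a junction when a strict majority of reads inserts there; the
## inserted base is the plurality base among the inserting reads.
voteOnTemplate <- function(template, reads) {
  L <- nchar(template)
  n <- length(reads)
  trafos <- attr(adist(template, reads, counts = TRUE), "trafos")[1L, ]
  tplChars <- strsplit(template, "", fixed = TRUE)[[1]]
  symbols <- c(DNA_BASES, "-")
  tally <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, symbols))
  insKey <- character(0)
  for (j in seq_len(n)) {
    o <- strsplit(trafos[j], "", fixed = TRUE)[[1]]
    rchars <- strsplit(reads[j], "", fixed = TRUE)[[1]]
    tpos <- cumsum(o != "I")
    rpos <- cumsum(o != "D")
    colOps <- o != "I"
    colIdx <- tpos[colOps]
    ch <- rep("-", length(colIdx))
    nonGap <- o[colOps] != "D"
    ch[nonGap] <- rchars[rpos[colOps][nonGap]]
    sym <- match(ch, symbols)
    counted <- tabulate(colIdx + (sym - 1L) * L, nbins = 5L * L)
    tally <- tally + matrix(counted, nrow = L, ncol = 5L)
    isIns <- o == "I"
    if (any(isIns)) {
      at <- tpos[isIns]
      base <- rchars[rpos[isIns]]
      ## one vote per read per junction (first inserted base)
      first <- !duplicated(at)
      insKey <- c(insKey, paste(at[first], base[first], sep = ":"))
    }
  }
  score <- tally
  ## half-vote bonus implements "tie toward the current template base"
  score[cbind(seq_len(L), match(tplChars, symbols))] <-
    score[cbind(seq_len(L), match(tplChars, symbols))] + 0.5
  winner <- symbols[max.col(score, ties.method = "first")]
  out <- winner[winner != "-"]
  ## insertions supported by a strict majority of reads
  if (length(insKey)) {
    keyTab <- table(insKey)
    byJunction <- do.call(rbind, strsplit(names(keyTab), ":", fixed = TRUE))
    junc <- as.integer(byJunction[, 1L])
    base <- byJunction[, 2L]
    cnt <- as.integer(keyTab)
    totalAt <- tapply(cnt, junc, sum)
    accepted <- integer(0)
    acceptedBase <- character(0)
    for (u in as.integer(names(totalAt))) {
      if (totalAt[as.character(u)] > n / 2) {
        sel <- junc == u
        bmax <- base[sel][order(-cnt[sel], base[sel])][1L]
        accepted <- c(accepted, u)
        acceptedBase <- c(acceptedBase, bmax)
      }
    }
    if (length(accepted)) {
      ## map template junctions to positions in the gap-stripped output
      keepPos <- cumsum(winner != "-")
      outChars <- strsplit(paste(out, collapse = ""), "", fixed = TRUE)[[1]]
      for (i in order(accepted, decreasing = TRUE)) {
        u <- accepted[i]
        insAt <- if (u == 0L) 0L else keepPos[u]
        outChars <- append(outChars, acceptedBase[i], after = insAt)
      }
      out <- outChars
    }
  }
  paste(out, collapse = "")
}

#' Draft consensus by star alignment to a medoid read
#'
#' Picks the medoid read (the read minimising summed edit distance to a
#' deterministic subsample of the others), aligns every read to it, and takes
#' a gap-aware per-column plurality vote over \{A, C, G, T, gap\}; gaps are
#' removed from the result.
#'
#' @param reads character vector (or \link[Biostrings]{DNAStringSet}) of
#'   reads; at least one.
#' @param medoidSample number of reads used to score medoid candidates
#'   (default 15; evenly spaced across the bin for determinism).
#' @return Character draft consensus.
#' @examples
#' draftConsensus(rep("ACGTACGT", 5))
#' @export
draftConsensus <- function(reads, medoidSample = 15L) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!length(reads)) stop("cannot build a consensus from an empty bin")
  if (length(reads) == 1L) return(unname(reads[1L]))
  m <- min(length(reads), medoidSample)
  sub <- reads[unique(as.integer(round(seq(1L, length(reads),
                                           length.out = m))))]
  dm <- .levDistMatrix(sub)
  medoid <- sub[which.min(rowSums(dm))]
  voteOnTemplate(medoid, unname(reads))
}

#' Polish a consensus by iterative realignment and plurality voting
#'
#' Realigns all reads to the current consensus and applies the gap-aware
#' per-column plurality vote (including insertion columns), iterating until
#' the sequence is unchanged or \code{maxIter} is reached.
#'
#' @param draft starting consensus sequence.
#' @param reads character vector (or \link[Biostrings]{DNAStringSet}) of
#'   reads.
#' @param maxIter maximum polishing iterations (default 5); 0 returns the
#'   draft unchanged with \code{converged = FALSE}.
#' @return A \linkS4class{ConsensusCall} whose \code{perReadIdentity} holds
#'   each read's end-to-end identity to the final consensus.
#' @examples
#' polishConsensus("ACGTACGT", rep("ACGTACGT", 4))
#' @export
polishConsensus <- function(draft, reads, maxIter = 5L) {
  assertDNA(draft, "draft")
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- unname(reads)
  cur <- draft
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    nxt <- voteOnTemplate(cur, reads)
    if (identical(nxt, cur)) { converged <- TRUE; break }
    cur <- nxt
  }
  ident <- seqIdentity(reads, cur)
  new("ConsensusCall", sequence = cur, nReads = length(reads),
      perReadIdentity = ident, rotationOffset = 0L, converged = converged)
}

#' Canonical rotation of a circular sequence
#'
#' With an anchor, the rotation starts at the (fuzzily located) anchor start;
#' without one, the lexicographically minimal rotation is chosen. Applying
#' the operation to any rotation of the same sequence yields identical
#' output.
#'
#' @param sequence circular sequence to canonicalise.
#' @param anchor optional anchor sequence (located with the same fuzzy
#'   machinery as flank matching; falls back to the lexicographic rule when
#'   absent).
#' @param maxEdits anchor edit budget (default 2).
#' @return List with \code{sequence} (rotated) and \code{offset} (0-based
#'   rotation applied).
#' @examples
#' rotateCanonical("CGTA")
#' @export
rotateCanonical <- function(sequence, anchor = NULL, maxEdits = 2L) {
  assertDNA(sequence, "sequence")
  L <- nchar(sequence)
  doubled <- paste0(sequence, sequence)
  if (!is.null(anchor)) {
    hit <- locateFlank(substr(doubled, 1L, 2L * L - 1L), anchor, maxEdits)
    if (!is.na(hit$start[1L])) {
      off <- ((hit$start[1L] - 1L) %% L)
      return(list(sequence = substr(doubled, off + 1L, off + L),
                  offset = as.integer(off)))
    }
  }
  rots <- substring(doubled, seq_len(L), seq_len(L) + L - 1L)
  off <- which(rots == min(rots))[1L] - 1L
  list(sequence = rots[off + 1L], offset = as.integer(off))
}

#' End-to-end sequence identity
#'
#' Defined as 1 - Levenshtein(a, b) / max(nchar(a), nchar(b)); two empty
#' sequences have identity 1, and exactly one empty sequence gives 0. This is
#' the identity entering the purity rule.
#'
#' @param a character vector of sequences (vectorised).
#' @param b a single comparison sequence, or a vector recycled against
#'   \code{a}.
#' @return Numeric identities in [0, 1].
#' @examples
#' seqIdentity(c("ACGT", "ACGA"), "ACGT")
#' @export
seqIdentity <- function(a, b) {
  if (length(b) == 1L) {
    d <- .levDistance(a, b)
    denom <- pmax(nchar(a), nchar(b))
  } else {
    k <- max(length(a), length(b))
    a <- rep_len(a, k)
    b <- rep_len(b, k)
    d <- vapply(seq_len(k), function(i) .levDistance(a[i], b[i]), integer(1))
    denom <- pmax(nchar(a), nchar(b))
  }
  out <- ifelse(denom == 0L, 1, 1 - d / denom)
  ifelse(nchar(a) == 0L | nchar(b) == 0L,
         ifelse(denom == 0L, 1, 0), out)
}
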