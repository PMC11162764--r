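## Purity scoring, pure/impure calls, correctness classification against
## references, and recovery/accuracy with bootstrap standard errors.

#' Purity score of a position
#'
#' The fraction of a position's reads that are end-to-end identical to the
#' position's consensus at or above \code{idThreshold} (default 0.90). The
#' threshold is applied inclusively; the reference workflow states it both as
#' "at least 90\%" and as ">90\%", and the inclusive reading is used
#' consistently here.
#'
#' @param consensus consensus sequence, or a \linkS4class{ConsensusCall}
#'   (whose stored per-read identities are then reused).
#' @param reads character vector of (trimmed) reads; at least one.
#' @param idThreshold identity threshold in [0, 1].
#' @return Purity fraction in [0, 1].
#' @examples
#' purityScore("ACGTACGTACGT", rep("ACGTACGTACGT", 10))
#' @export
purityScore <- function(consensus, reads, idThreshold = 0.90) {
  if (is(consensus, "ConsensusCall")) {
    if (consensus@nReads == 0L) stop("purity is undefined for zero reads")
    return(mean(consensus@perReadIdentity >= idThreshold))
  }
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!length(reads)) stop("purity is undefined for zero reads")
  mean(seqIdentity(unname(reads), consensus) >= idThreshold)
}

#' Call a position pure or impure
#'
#' A position is pure iff it has at least \code{minReads} reads and a purity
#' score at or above \code{purityThreshold}: the conservative
#' 5-read / 0.9-purity rule.
#'
#' @param purity purity score in [0, 1].
#' @param nReads number of reads at the position.
#' @param minReads read floor (default 5).
#' @param purityThreshold purity floor (default 0.90).
#' @return Logical flag.
#' @examples
#' callPure(1.0, 5)   # TRUE
#' callPure(1.0, 4)   # FALSE: below the read floor
#' callPure(0.89, 100) # FALSE: below the purity floor
#' @export
callPure <- function(purity, nReads, minReads = 5L, purityThreshold = 0.90) {
  nReads >= minReads & purity >= purityThreshold
}

#' Classify a consensus against a reference set
#'
#' The consensus is matched to its best reference by end-to-end identity.
#' Exact equality gives \code{perfect}; identity at or above
#' \code{mapThreshold} gives \code{error} with substitution/insertion/deletion
#' counts from the alignment (edits of the consensus relative to the
#' reference); otherwise the consensus is \code{off_target} if it maps to the
#' host genome at \code{mapThreshold} (local alignment), else \code{other}.
#' Positions that failed the purity rule should be passed with
#' \code{pure = FALSE} and come back as \code{mixed}.
#'
#' @param consensus consensus sequence.
#' @param referenceSet named character vector of reference sequences.
#' @param hostGenome optional host genome sequence for off-target calls.
#' @param mapThreshold identity floor separating \code{error} from
#'   off-target/other (default 0.80).
#' @param pure set FALSE for positions that failed the purity rule.
#' @return A \linkS4class{CorrectnessCall}.
#' @examples
#' classifyCorrectness("ACGTACGTACGT", c(ref1 = "ACGTACGTACGT"))
#' @export
classifyCorrectness <- function(consensus, referenceSet, hostGenome = NULL,
                                mapThreshold = 0.80, pure = TRUE) {
  if (!length(referenceSet)) stop("reference set must be non-empty")
  if (is.null(names(referenceSet)))
    names(referenceSet) <- paste0("ref_", seq_along(referenceSet))
  if (!pure)
    return(new("CorrectnessCall", category = "mixed",
               matchedRef = NA_character_))
  ident <- seqIdentity(unname(referenceSet), consensus)
  best <- which.max(ident)
  if (ident[best] == 1) {
    return(new("CorrectnessCall", category = "perfect",
               matchedRef = names(referenceSet)[best]))
  }
  if (ident[best] >= mapThreshold) {
    cnt <- attr(adist(unname(referenceSet[best]), consensus,
                      counts = TRUE), "counts")[1L, 1L, ]
    return(new("CorrectnessCall", category = "error",
               matchedRef = names(referenceSet)[best],
               nSubstitutions = as.integer(cnt[["sub"]]),
               nInsertions = as.integer(cnt[["ins"]]),
               nDeletions = as.integer(cnt[["del"]])))
  }
  if (!is.null(hostGenome)) {
    aln <- Biostrings::pairwiseAlignment(DNAString(consensus),
                                         DNAString(hostGenome),
                                         type = "local")
    if (Biostrings::nmatch(aln) / nchar(consensus) >= mapThreshold)
      return(new("CorrectnessCall", category = "off_target",
                 matchedRef = NA_character_))
  }
  new("CorrectnessCall", category = "other", matchedRef = NA_character_)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples the values with replacement \code{B} times, recomputes the
#' statistic, and returns the standard deviation of the bootstrap
#' distribution.
#'
#' @param values numeric (or logical) vector; at least one value.
#' @param statistic function of a vector (default \code{mean}).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed or NULL.
#' @return Numeric standard error.
#' @examples
#' bootstrapSE(rep(1, 20), seed = 1)  # 0
#' @export
bootstrapSE <- function(values, statistic = mean, B = 1000L, seed = NULL) {
  if (!length(values)) stop("need at least one value")
  withSeed(seed, {
    n <- length(values)
    stats <- vapply(seq_len(B), function(b)
      statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    sd(stats)
  })
}

#' Recovery and accuracy over known array positions
#'
#' Recovery is the percentage of known positions that were detected (a
#' position counts as detected when it yielded a pure consensus call);
#' accuracy is the percentage of detections that were sequence correct.
#' Standard errors come from bootstrapping positions.
#'
#' @param calls data.frame with columns \code{position_id}, \code{detected}
#'   (logical), \code{correct} (logical). Positions absent from \code{calls}
#'   count as undetected.
#' @param knownPositions character vector of all known position ids.
#' @param B bootstrap replicates for the standard errors.
#' @param seed integer seed or NULL.
#' @return List: \code{recovery_pct}, \code{accuracy_pct}, \code{recovery_se},
#'   \code{accuracy_se}, \code{n_known_positions}, \code{n_detected},
#'   \code{n_correct}, \code{accuracy_defined} (FALSE when nothing was
#'   detected, in which case accuracy is reported as 0).
#' @examples
#' calls <- data.frame(position_id = c("a", "b"), detected = TRUE,
#'                     correct = c(TRUE, FALSE))
#' recoveryAccuracy(calls, c("a", "b", "c"), B = 100, seed = 1)
#' @export
recoveryAccuracy <- function(calls, knownPositions, B = 1000L, seed = NULL) {
  stopifnot(all(c("position_id", "detected", "correct") %in% names(calls)))
  knownPositions <- unique(as.character(knownPositions))
  n <- length(knownPositions)
  if (!n) stop("no known positions supplied")
  detected <- setNames(rep(FALSE, n), knownPositions)
  correct <- setNames(rep(FALSE, n), knownPositions)
  hit <- calls$position_id %in% knownPositions
  detected[calls$position_id[hit]] <- calls$detected[hit]
  correct[calls$position_id[hit]] <- calls$detected[hit] & calls$correct[hit]
  nDet <- sum(detected)
  nCor <- sum(correct)
  recovery <- 100 * nDet / n
  accuracy <- if (nDet > 0L) 100 * nCor / nDet else 0
  withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    recB <- rowMeans(matrix(detected[idx], nrow = B)) * 100
    accB <- apply(idx, 1L, function(i) {
      d <- sum(detected[i])
      if (d > 0L) 100 * sum(correct[i]) / d else NA_real_
    })
    list(recovery_pct = recovery, accuracy_pct = accuracy,
         recovery_se = sd(recB),
         accuracy_se = if (all(is.na(accB))) NA_real_
                       else sd(accB[!is.na(accB)]),
         n_known_positions = n, n_detected = nDet, n_correct = nCor,
         accuracy_defined = nDet > 0L)
  })
}
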