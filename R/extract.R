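## Index demultiplexing, fuzzy flank-anchored barcode extraction, verbatim
## regex extraction for the short-read path, and UMI extraction.

#' Printed barcode extraction patterns for the short-read path
#'
#' The two regular expressions used to pull donor and recipient barcodes out
#' of demultiplexed short reads. They anchor on fuzzified 4-mer flanks (one
#' mismatch tolerated via the alternation groups) and fixed AA/TT internal
#' anchors; \code{\\D} deliberately matches any non-digit, hence any base.
#' Applied verbatim, without further fuzzification.
#'
#' @format Named character vector with elements \code{donor} and
#'   \code{recipient}.
#' @export
barcodePatterns <- c(
  donor = "\\D*?(.GGC|T.GC|TG.C|TGG.)\\D{4,7}?AA\\D{4,7}?TT\\D{4,7}?(.CGG|G.GG|GC.G|GCG.)\\D*",
  recipient = "\\D*?(.ACA|G.CA|GA.A|GAC.)\\D{4,7}?AA\\D{4,7}?AA\\D{4,7}?TT\\D{4,7}?(.TCG|C.CG|CT.G|CTC.)\\D*"
)

#' Demultiplex reads by exact sample-index match
#'
#' Assigns each read to a sample when the index sequence at the expected
#' offset matches an index in the table exactly; anything else is unassigned
#' (NA). Reads are also checked on the reverse-complement strand, since long
#' reads are sequenced in either orientation.
#'
#' @param reads character vector of read sequences.
#' @param indexTable data.frame with columns \code{sample} and \code{index}
#'   (distinct index sequences), or a named character vector
#'   (names = sample ids, values = index sequences).
#' @param offset 0-based offset of the index on the read (default 0).
#' @return Character vector of sample ids, NA where unassigned.
#' @examples
#' demuxSampleIndex(c("ACGTACGTTTTT", "CCGTACGTTTTT"),
#'                  c(s1 = "ACGTACGT"))
#' @export
demuxSampleIndex <- function(reads, indexTable, offset = 0L) {
  if (is.data.frame(indexTable)) {
    stopifnot(all(c("sample", "index") %in% names(indexTable)))
    idx <- setNames(as.character(indexTable$index),
                    as.character(indexTable$sample))
  } else {
    idx <- indexTable
  }
  if (anyDuplicated(idx))
    stop("duplicate index sequences in index table")
  if (anyDuplicated(names(idx)))
    stop("duplicate sample ids in index table")
  lens <- nchar(idx)
  lookup <- setNames(names(idx), idx)
  out <- rep(NA_character_, length(reads))
  for (L in unique(lens)) {
    sub <- substr(reads, offset + 1L, offset + L)
    hit <- sub %in% idx[lens == L]
    out[hit & is.na(out)] <- lookup[sub[hit & is.na(out)]]
  }
  if (anyNA(out)) {
    rc <- revComp(reads[is.na(out)])
    rcAssign <- rep(NA_character_, length(rc))
    for (L in unique(lens)) {
      sub <- substr(rc, offset + 1L, offset + L)
      hit <- sub %in% idx[lens == L]
      rcAssign[hit & is.na(rcAssign)] <- lookup[sub[hit & is.na(rcAssign)]]
    }
    out[is.na(out)] <- rcAssign
  }
  out
}

## Locate a flank in reads at the smallest edit budget that yields a hit,
## leftmost among hits at that budget. `searchFrom` (1-based, recycled) caps
## the search to a suffix of each read. Returns start/end (1-based,
## inclusive) and edits used; NA where absent. TRE's approximate matcher
## does the sliding-window alignment at C level.
locateFlank <- function(reads, flank, maxEdits, searchFrom = 1L) {
  n <- length(reads)
  searchFrom <- rep_len(as.integer(searchFrom), n)
  start <- end <- edits <- rep(NA_integer_, n)
  pending <- seq_len(n)
  region <- substr(reads, searchFrom, nchar(reads))
  for (k in 0:maxEdits) {
    if (!length(pending)) break
    m <- if (k == 0L) regexpr(flank, region[pending], fixed = TRUE)
         else aregexec(flank, region[pending],
                       max.distance = list(cost = k, insertions = k,
                                           deletions = k, substitutions = k),
                       fixed = TRUE)
    if (k == 0L) {
      st <- as.integer(m)
      len <- attr(m, "match.length")
    } else {
      st <- vapply(m, function(x) as.integer(x[1]), integer(1))
      len <- vapply(m, function(x) attr(x, "match.length")[1], integer(1))
    }
    hit <- !is.na(st) & st > 0L
    if (any(hit)) {
      i <- pending[hit]
      start[i] <- st[hit] + searchFrom[i] - 1L
      end[i] <- start[i] + len[hit] - 1L
      edits[i] <- k
      pending <- pending[!hit]
    }
  }
  ## report the true edit count of the matched window (TRE guarantees <= k,
  ## the realised distance can be smaller)
  ok <- which(!is.na(start))
  if (length(ok)) {
    matched <- substr(reads[ok], start[ok], end[ok])
    edits[ok] <- as.integer(adist(matched, flank)[, 1L])
  }
  data.frame(start = start, end = end, edits = edits)
}

checkMotifs <- function(core, motifs) {
  if (!length(motifs)) return(rep(TRUE, length(core)))
  ok <- rep(TRUE, length(core))
  for (m in motifs) {
    pos <- vapply(core, function(s) {
      hits <- gregexpr(m$motif, s, fixed = TRUE)[[1]]
      any(hits >= m$window[1] & hits <= m$window[2])
    }, logical(1), USE.NAMES = FALSE)
    ok <- ok & pos
  }
  ok
}

## Single-strand flank-pair location. Returns barcode core + span per read.
extractOneStrand <- function(reads, def) {
  up <- locateFlank(reads, def@upstreamFlank, def@maxFlankEdits)
  res <- data.frame(barcode = rep(NA_character_, length(reads)),
                    start = NA_integer_, end = NA_integer_,
                    edits = NA_integer_)
  has <- which(!is.na(up$start))
  if (!length(has)) return(res)
  ## search the downstream flank only after the upstream match
  down <- data.frame(start = rep(NA_integer_, length(reads)),
                     end = NA_integer_, edits = NA_integer_)
  down[has, ] <- locateFlank(reads[has], def@downstreamFlank,
                             def@maxFlankEdits, searchFrom = up$end[has] + 1L)
  ok <- which(!is.na(down$start))
  if (!length(ok)) return(res)
  coreStart <- up$end[ok] + 1L
  coreEnd <- down$start[ok] - 1L
  core <- substr(reads[ok], coreStart, coreEnd)
  lenOK <- nchar(core) >= def@coreLengthMin &
           nchar(core) <= def@coreLengthMax
  motifOK <- checkMotifs(core, def@internalMotifs)
  keep <- ok[lenOK & motifOK]
  if (length(keep)) {
    sel <- lenOK & motifOK
    res$barcode[keep] <- core[sel]
    res$start[keep] <- coreStart[sel] - 1L      # 0-based
    res$end[keep] <- coreEnd[sel]               # half-open
    res$edits[keep] <- up$edits[keep] + down$edits[keep]
  }
  res
}

#' Extract barcodes from reads by fuzzy flank-anchored matching
#'
#' Locates the upstream and downstream flanks of a
#' \linkS4class{BarcodeDefinition} allowing up to \code{maxFlankEdits}
#' Levenshtein edits (substitutions and indels) per flank, on the forward
#' strand first and on the reverse complement if the forward search fails,
#' and returns the intervening core when its length lies in the admissible
#' range and any internal motifs are satisfied. Each flank is located at the
#' smallest edit budget that yields a hit, leftmost among those hits; the
#' forward strand wins ties.
#'
#' @param reads character vector (or \link[Biostrings]{DNAStringSet}) of reads.
#' @param definition a \linkS4class{BarcodeDefinition}.
#' @return data.frame with one row per read: \code{barcode} (NA when no
#'   match), \code{start}, \code{end} (0-based half-open core span on the
#'   searched orientation), \code{strand} ("+"/"-"), and \code{edits}
#'   (total flank edits used).
#' @examples
#' def <- arrayBarcodeDefinition()
#' read <- paste0("AAAT", arrayContext[["bcUp"]],
#'                "ACGTACGTACGTACGTACGT", arrayContext[["bcDown"]], "GGTT")
#' extractBarcodeFuzzy(read, def)
#' @export
extractBarcodeFuzzy <- function(reads, definition) {
  stopifnot(is(definition, "BarcodeDefinition"))
  validObject(definition)
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!length(reads))
    return(data.frame(barcode = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      edits = integer(0)))
  fwd <- extractOneStrand(reads, definition)
  strand <- rep("+", length(reads))
  miss <- which(is.na(fwd$barcode))
  if (length(miss)) {
    rev <- extractOneStrand(revComp(reads[miss]), definition)
    got <- !is.na(rev$barcode)
    fwd[miss[got], ] <- rev[got, ]
    strand[miss[got]] <- "-"
  }
  strand[is.na(fwd$barcode)] <- NA_character_
  data.frame(barcode = fwd$barcode, start = fwd$start, end = fwd$end,
             strand = strand, edits = fwd$edits)
}

#' Extract barcodes with the printed short-read regular expressions
#'
#' Applies one of the two verbatim patterns in \code{\link{barcodePatterns}}
#' and returns the matched core, spanning from the start of the first flank
#' group to the end of the second flank group. No fuzzification beyond what
#' the patterns themselves encode is applied.
#'
#' @param reads character vector of read sequences.
#' @param pattern \code{"donor"} or \code{"recipient"}.
#' @return Character vector of barcode cores, NA where the pattern does not
#'   match.
#' @examples
#' extractBarcodeRegex("TTTGGCACGTAACGTGTTCTAGGCGGTT", "donor")
#' @export
extractBarcodeRegex <- function(reads, pattern = c("donor", "recipient")) {
  pattern <- match.arg(pattern)
  rx <- barcodePatterns[[pattern]]
  m <- regexpr(rx, reads, perl = TRUE)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  out <- rep(NA_character_, length(reads))
  hit <- !is.na(m) & m > 0L
  if (any(hit)) {
    ng <- ncol(cs)
    out[hit] <- substr(reads[hit], cs[hit, 1L],
                       cs[hit, ng] + cl[hit, ng] - 1L)
  }
  out
}

#' Extract a fixed-position UMI
#'
#' Returns the random-mer at a fixed position on the read; reads too short to
#' contain it yield NA.
#'
#' @param reads character vector of read sequences.
#' @param offset 0-based offset of the UMI.
#' @param length UMI length in nt.
#' @return Character vector of UMIs (NA where the read is too short).
#' @examples
#' extractUMI("ACGTACGTTTTTTT", offset = 0, length = 8)
#' @export
extractUMI <- function(reads, offset, length) {
  stopifnot(offset >= 0L, length >= 1L)
  out <- substr(reads, offset + 1L, offset + length)
  out[nchar(reads) < offset + length] <- NA_character_
  out
}
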