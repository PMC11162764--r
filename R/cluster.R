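## Edit-distance collapse of barcode observations, assignment to known
## barcode lists, UMI deduplication, and the low-count chimera filter.

#' Greedy count-ordered barcode clustering
#'
#' Collapses error-bearing barcode observations into clusters: unique
#' sequences are sorted by descending count (ties broken lexicographically)
#' and each joins the first existing cluster whose centroid is within
#' \code{maxDist} Levenshtein edits, else founds a new cluster. Centroids are
#' the founding (highest-count) members. This is the greedy scheme of the
#' common barcode clusterers, re-implemented; their exact message-passing or
#' sphere-removal variants are deliberately not reproduced.
#'
#' @param observations either a named numeric vector (sequence -> count) or a
#'   bare character vector of observations (tabulated internally).
#' @param maxDist maximum Levenshtein distance to a centroid (default 2 for
#'   cores up to 16 nt, 3 for longer cores).
#' @return data.frame with one row per cluster, ordered by founding:
#'   \code{centroid}, \code{total_count}, and a list-column \code{members}
#'   of named member counts.
#' @examples
#' clusterBarcodes(c(ACGTACGTACGTACG = 100, ACGTACGAACGTACG = 1), maxDist = 2)
#' @export
clusterBarcodes <- function(observations, maxDist = NULL) {
  if (is.character(observations)) {
    tab <- table(observations)
    observations <- setNames(as.numeric(tab), names(tab))
  }
  if (!length(observations))
    return(data.frame(centroid = character(0), total_count = numeric(0),
                      members = I(list())))
  if (is.null(names(observations)) || anyDuplicated(names(observations)))
    stop("observations must be uniquely named by sequence")
  if (is.null(maxDist))
    maxDist <- if (max(nchar(names(observations))) <= 16L) 2L else 3L
  if (maxDist < 0L) stop("maxDist must be >= 0")
  ord <- order(-observations, names(observations), method = "radix")
  seqs <- names(observations)[ord]
  cnts <- unname(observations[ord])
  founder <- .greedyCluster(seqs, as.integer(maxDist))
  grp <- split(seq_along(seqs), founder)
  grp <- grp[order(as.integer(names(grp)))]  # founding order
  data.frame(
    centroid = vapply(grp, function(i) seqs[i[1L]], character(1)),
    total_count = vapply(grp, function(i) sum(cnts[i]), numeric(1)),
    members = I(lapply(grp, function(i) setNames(cnts[i], seqs[i]))),
    row.names = NULL)
}

#' Assign barcode clusters to a list of known barcodes
#'
#' Each cluster centroid is assigned to the unique nearest known barcode when
#' that distance is at most \code{maxDist}; centroids with no qualifying
#' known barcode, or whose minimum distance is tied between two known
#' barcodes, stay unassigned (ties are flagged).
#'
#' @param clusters output of \code{\link{clusterBarcodes}}, or a character
#'   vector of centroids.
#' @param knownBarcodes named character vector (id -> barcode) or a plate-map
#'   data.frame with columns \code{plate}, \code{well}, \code{barcode}
#'   (position ids are then \code{plate_well}).
#' @param maxDist maximum assignment distance (default as in
#'   \code{\link{clusterBarcodes}}).
#' @return data.frame: \code{centroid}, \code{assigned_id} (NA when
#'   unassigned), \code{distance}, \code{tie} (logical).
#' @examples
#' assignToKnown("ACGTACGTACGTACGTACGT",
#'               c(P1_A01 = "ACGTACGTACGTACGTACGT"), maxDist = 2)
#' @export
assignToKnown <- function(clusters, knownBarcodes, maxDist = NULL) {
  centroids <- if (is.data.frame(clusters)) clusters$centroid
               else as.character(clusters)
  if (is.data.frame(knownBarcodes)) {
    stopifnot(all(c("plate", "well", "barcode") %in% names(knownBarcodes)))
    knownBarcodes <- setNames(as.character(knownBarcodes$barcode),
                              paste(knownBarcodes$plate, knownBarcodes$well,
                                    sep = "_"))
  }
  if (anyDuplicated(knownBarcodes))
    stop("duplicate sequences in known barcode list")
  if (is.null(names(knownBarcodes)))
    names(knownBarcodes) <- paste0("known_", seq_along(knownBarcodes))
  if (is.null(maxDist))
    maxDist <- if (max(nchar(knownBarcodes)) <= 16L) 2L else 3L
  maxDist <- as.integer(maxDist)
  known <- unname(knownBarcodes)
  ids <- names(knownBarcodes)
  out <- data.frame(centroid = centroids,
                    assigned_id = rep(NA_character_, length(centroids)),
                    distance = rep(NA_integer_, length(centroids)),
                    tie = rep(FALSE, length(centroids)))
  for (i in seq_along(centroids)) {
    d <- .levDistance(known, centroids[i], cap = maxDist)
    dmin <- min(d)
    if (dmin > maxDist) next
    hits <- which(d == dmin)
    if (length(hits) > 1L) {
      out$tie[i] <- TRUE
      out$distance[i] <- dmin
    } else {
      out$assigned_id[i] <- ids[hits]
      out$distance[i] <- dmin
    }
  }
  out
}

#' Deduplicate UMIs within barcode pairs
#'
#' PCR duplicates share a unique molecular identifier; the deduplicated count
#' of a barcode pair is its number of distinct UMIs. UMIs are scoped within
#' each pair (the same UMI under two different pairs counts once in each) and
#' collapse is exact-match only.
#'
#' @param pairs character vector of barcode-pair keys (one per record).
#' @param umis character vector of UMIs, parallel to \code{pairs}.
#' @return Named numeric vector: pair -> deduplicated count.
#' @examples
#' dedupUMIs(c("p1", "p1", "p1", "p2"), c("AAAA", "AAAA", "CCCC", "AAAA"))
#' @export
dedupUMIs <- function(pairs, umis) {
  if (length(pairs) != length(umis))
    stop("'pairs' and 'umis' must have the same length")
  if (!length(pairs)) return(setNames(numeric(0), character(0)))
  uniq <- !duplicated(paste(pairs, umis, sep = "\r"))
  tab <- table(pairs[uniq])
  setNames(as.numeric(tab), names(tab))
}

#' Filter barcode-pair counts below a read floor
#'
#' Pairs supported by fewer than \code{minReads} reads are removed as
#' putative PCR chimeras; the threshold is strict, so a pair with exactly
#' \code{minReads} reads is kept.
#'
#' @param counts named numeric vector of pair counts.
#' @param minReads minimum count to keep (default 20).
#' @return The retained subset of \code{counts}.
#' @examples
#' filterPairCounts(c(a = 19, b = 20, c = 1000))
#' @export
filterPairCounts <- function(counts, minReads = 20) {
  stopifnot(minReads >= 0)
  counts[counts >= minReads]
}
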