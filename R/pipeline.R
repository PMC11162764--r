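## End-to-end pipeline: size filter -> demux -> extract -> cluster -> assign
## -> bin -> length-split -> trim -> consensus -> assess -> summary, with a
## per-stage read-accounting audit (silent read loss is the main failure mode
## of a pipeline with this many filters).

#' Validated configuration for \code{\link{runArrayPipeline}}
#'
#' Collects input paths and all stage parameters, with the defaults used
#' throughout the package. Unknown arguments are rejected. Input paths are
#' checked at construction time.
#'
#' @param fastq path to the input FASTQ.
#' @param plateMap path to a plate-map TSV (\code{plate\\twell\\tbarcode}) or
#'   a data.frame of the same shape.
#' @param references optional reference FASTA path or named character vector.
#' @param hostGenome optional host genome FASTA path or sequence.
#' @param truthWells optional truth table (path or data.frame with
#'   \code{position_id} and \code{design_ids}) for scoring correctness
#'   against per-position expected designs.
#' @param outDir optional output directory for report/summary/consensus files.
#' @param sampleIndexTable optional index table (see
#'   \code{\link{demuxSampleIndex}}); NULL treats all reads as one sample.
#' @param minLen,maxLen read size filter bounds.
#' @param barcodeDef \linkS4class{BarcodeDefinition} for positional barcode
#'   extraction (default \code{\link{arrayBarcodeDefinition}()}).
#' @param trimFlanks length-2 character vector of trimming sequences
#'   enclosing the insert (default: the simulated array context).
#' @param clusterMaxDist,assignMaxDist Levenshtein radii for clustering and
#'   known-barcode assignment (default: 2 for barcodes up to 16 nt, else 3).
#' @param minReads,purityThreshold,idThreshold the purity rule parameters.
#' @param mapThreshold error-vs-off-target identity floor.
#' @param gmmMaxComponents,gmmMinReads read-length mixture controls.
#' @param subsampleCap maximum reads used to build a consensus (default 100;
#'   the most length-concordant reads are kept).
#' @param medoidSample reads scored when picking the medoid.
#' @param maxIter polishing iteration cap.
#' @param seed integer seed or NULL (drives bootstrap resampling).
#' @return A validated configuration list of class \code{pipelineConfig}.
#' @examples
#' \dontrun{
#' cfg <- pipelineConfig(fastq = "reads.fastq", plateMap = "plate_map.tsv")
#' }
#' @export
pipelineConfig <- function(fastq, plateMap, references = NULL,
                           hostGenome = NULL, truthWells = NULL,
                           outDir = NULL, sampleIndexTable = NULL,
                           minLen = 0, maxLen = Inf,
                           barcodeDef = arrayBarcodeDefinition(),
                           trimFlanks = c(arrayContext[["insUp"]],
                                          arrayContext[["insDown"]]),
                           clusterMaxDist = NULL, assignMaxDist = NULL,
                           minReads = 5L, purityThreshold = 0.90,
                           idThreshold = 0.90, mapThreshold = 0.80,
                           gmmMaxComponents = 3L, gmmMinReads = 10L,
                           subsampleCap = 100L, medoidSample = 15L,
                           maxIter = 5L, seed = NULL) {
  if (is.character(fastq) && !file.exists(fastq))
    stop("FASTQ not found: ", fastq)
  if (is.character(plateMap) && !file.exists(plateMap))
    stop("plate map not found: ", plateMap)
  for (p in c(references, hostGenome)) {
    if (is.character(p) && length(p) == 1L && grepl("\\.(fa|fasta)$", p) &&
        !file.exists(p))
      stop("input not found: ", p)
  }
  stopifnot(is(barcodeDef, "BarcodeDefinition"), length(trimFlanks) == 2L)
  assertProb(c(purityThreshold, idThreshold, mapThreshold), "thresholds")
  cfg <- list(fastq = fastq, plateMap = plateMap, references = references,
              hostGenome = hostGenome, truthWells = truthWells,
              outDir = outDir, sampleIndexTable = sampleIndexTable,
              minLen = minLen, maxLen = maxLen, barcodeDef = barcodeDef,
              trimFlanks = trimFlanks, clusterMaxDist = clusterMaxDist,
              assignMaxDist = assignMaxDist, minReads = minReads,
              purityThreshold = purityThreshold, idThreshold = idThreshold,
              mapThreshold = mapThreshold,
              gmmMaxComponents = gmmMaxComponents, gmmMinReads = gmmMinReads,
              subsampleCap = subsampleCap, medoidSample = medoidSample,
              maxIter = maxIter, seed = seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

readPlateMap <- function(plateMap) {
  pm <- if (is.data.frame(plateMap)) plateMap
        else read.delim(plateMap, stringsAsFactors = FALSE)
  stopifnot(all(c("plate", "well", "barcode") %in% names(pm)))
  pm$position_id <- paste(pm$plate, pm$well, sep = "_")
  pm
}

readReferences <- function(references) {
  if (is.null(references)) return(NULL)
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    x <- readDNAStringSet(references)
    return(setNames(as.character(x), names(x)))
  }
  references
}

## Keep the `cap` most length-concordant reads (closest to the median length).
subsampleByLength <- function(reads, cap) {
  if (length(reads) <= cap) return(reads)
  lens <- nchar(reads)
  reads[order(abs(lens - median(lens)))[seq_len(cap)]]
}

#' Run the full demultiplex-to-consensus pipeline
#'
#' Executes size filtering, sample demultiplexing, fuzzy barcode extraction,
#' barcode clustering and assignment to the plate map, per-position binning,
#' read trimming, read-length mixture splitting, consensus polishing, and
#' purity/correctness assessment, and summarises recovery, accuracy (with
#' bootstrap standard errors) and coverage dispersion (Gini of per-position
#' read counts).
#'
#' The per-position consensus is built from the largest length cluster of the
#' trimmed reads; purity is scored over all trimmed reads at the position, so
#' mixed wells surface as impure. A position counts as detected when it
#' passes the pure call; a detection is correct when its consensus matches a
#' reference perfectly (and, when a truth table is supplied, the matched
#' reference is the expected design for that position).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return List: \code{report} (per-position data.frame), \code{summary}
#'   (recovery/accuracy/SEs/Gini), \code{audit} (per-stage read accounting),
#'   \code{consensus} (named character vector), \code{config}.
#' @examples
#' \dontrun{
#' run <- buildArrayRun(simConfig(nDesigns = 8, meanDepth = 20, seed = 1),
#'                      generateBarcodeSet(barcodeSetSpec(8, 20, 6, seed = 2)),
#'                      outDir = tempdir())
#' res <- runArrayPipeline(pipelineConfig(run$fastq, run$plateMap,
#'                                        references = run$referenceFasta))
#' }
#' @export
runArrayPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  reads <- if (is.character(config$fastq)) readFastqSeqs(config$fastq)
           else config$fastq
  pm <- readPlateMap(config$plateMap)
  refs <- readReferences(config$references)
  host <- readReferences(config$hostGenome)
  if (!is.null(host) && length(host)) host <- unname(host[1L])
  truth <- config$truthWells
  if (!is.null(truth) && is.character(truth))
    truth <- read.delim(truth, stringsAsFactors = FALSE)

  audit <- list(input = length(reads))
  if (!length(reads)) {
    return(list(report = emptyReport(), summary = emptySummary(pm),
                audit = data.frame(stage = "input", reads = 0L),
                consensus = character(0), config = config))
  }

  ## 1. size filter
  kept <- filterReadsBySize(reads, config$minLen, config$maxLen)
  audit$size_filtered_out <- length(reads) - length(kept)
  audit$size_kept <- length(kept)

  ## 2. sample demultiplexing
  samples <- if (is.null(config$sampleIndexTable))
    rep("sample1", length(kept))
  else demuxSampleIndex(kept, config$sampleIndexTable)
  audit$demux_unassigned <- sum(is.na(samples))

  ## 3. fuzzy barcode extraction
  ext <- extractBarcodeFuzzy(kept, config$barcodeDef)
  audit$barcode_extracted <- sum(!is.na(ext$barcode))

  ## 4. cluster observed barcodes, 5. assign to plate map
  known <- setNames(pm$barcode, pm$position_id)
  if (anyDuplicated(known)) stop("duplicate barcodes in plate map")
  obs <- ext$barcode[!is.na(ext$barcode)]
  position <- rep(NA_character_, length(kept))
  if (length(obs)) {
    clusters <- clusterBarcodes(obs, maxDist = config$clusterMaxDist)
    assignment <- assignToKnown(clusters, known,
                                maxDist = config$assignMaxDist)
    ## member sequence -> assigned position
    memberMap <- unlist(lapply(seq_len(nrow(clusters)), function(i) {
      m <- names(clusters$members[[i]])
      setNames(rep(assignment$assigned_id[i], length(m)), m)
    }))
    position[!is.na(ext$barcode)] <- memberMap[obs]
  }
  audit$barcode_assigned <- sum(!is.na(position))

  ## 6. bin by (sample, position)
  binned <- binReads(kept, samples, position)
  audit$binned <- sum(vapply(binned$bins, nReads, integer(1)))
  audit$sink <- length(binned$sink)

  missingPM <- setdiff(unique(position[!is.na(position)]), pm$position_id)
  if (length(missingPM))
    warning("positions absent from the plate map routed to sink: ",
            paste(missingPM, collapse = ", "))

  ## 7-9. per-bin trim, split, consensus, assess
  rows <- lapply(binned$bins, function(bin) {
    processBin(bin, config, refs, host, truth)
  })
  report <- do.call(rbind, c(rows, list(emptyReport())))
  rownames(report) <- NULL

  consensus <- setNames(report$consensus, report$position_key)

  ## 10. summary over known positions
  summary <- summariseRun(report, pm, config)

  auditDF <- data.frame(stage = names(audit),
                        reads = unlist(audit, use.names = FALSE))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(report[, setdiff(names(report), "consensus")],
                file.path(config$outDir, "per_position_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ok <- !is.na(consensus) & nzchar(consensus)
    if (any(ok))
      writeXStringSet(DNAStringSet(consensus[ok]),
                      file.path(config$outDir, "consensus.fasta"))
    jsonlite::write_json(summary,
                         file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(auditDF, file.path(config$outDir, "read_audit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(report = report, summary = summary, audit = auditDF,
       consensus = consensus, config = config)
}

emptyReport <- function() {
  data.frame(sample = character(0), position_id = character(0),
             position_key = character(0), n_reads = integer(0),
             n_trimmed = integer(0), purity = numeric(0), pure = logical(0),
             category = character(0), matched_ref = character(0),
             subs = integer(0), ins = integer(0), dels = integer(0),
             consensus = character(0), stringsAsFactors = FALSE)
}

emptySummary <- function(pm) {
  list(recovery_pct = 0, accuracy_pct = 0, recovery_se = NA_real_,
       accuracy_se = NA_real_, n_known_positions = nrow(readPlateMap(pm)),
       n_detected = 0L, n_correct = 0L, accuracy_defined = FALSE,
       coverage_gini = NA_real_)
}

processBin <- function(bin, config, refs, host, truth) {
  sampleId <- bin@sampleId
  positionId <- bin@positionId
  raw <- as.character(bin@reads)
  trimmed <- trimToInsert(raw, config$trimFlanks,
                          maxEdits = config$barcodeDef@maxFlankEdits)
  trimmed <- trimmed[!is.na(trimmed) & nzchar(trimmed)]
  base <- data.frame(sample = sampleId, position_id = positionId,
                     position_key = paste(sampleId, positionId, sep = "/"),
                     n_reads = length(raw), n_trimmed = length(trimmed),
                     stringsAsFactors = FALSE)
  if (!length(trimmed)) {
    return(cbind(base, data.frame(purity = NA_real_, pure = FALSE,
                                  category = "other",
                                  matched_ref = NA_character_, subs = NA_integer_,
                                  ins = NA_integer_, dels = NA_integer_,
                                  consensus = NA_character_)))
  }
  ## consensus from the dominant length cluster; purity over all trimmed reads
  tbin <- readBin_(sampleId, positionId,
                   setNames(trimmed, paste0("t", seq_along(trimmed))))
  parts <- splitByLengthGMM(tbin, maxComponents = config$gmmMaxComponents,
                            minReadsToSplit = config$gmmMinReads)
  sizes <- vapply(parts, nReads, integer(1))
  core <- as.character(parts[[which.max(sizes)]]@reads)
  core <- subsampleByLength(core, config$subsampleCap)
  draft <- draftConsensus(core, medoidSample = config$medoidSample)
  call <- polishConsensus(draft, core, maxIter = config$maxIter)
  cons <- consensusSequence(call)
  purity <- purityScore(cons, trimmed, idThreshold = config$idThreshold)
  pure <- callPure(purity, length(trimmed), minReads = config$minReads,
                   purityThreshold = config$purityThreshold)
  cc <- if (is.null(refs))
    new("CorrectnessCall", category = if (pure) "other" else "mixed",
        matchedRef = NA_character_)
  else classifyCorrectness(cons, refs, hostGenome = host,
                           mapThreshold = config$mapThreshold, pure = pure)
  cbind(base, data.frame(purity = purity, pure = pure,
                         category = category(cc),
                         matched_ref = cc@matchedRef,
                         subs = cc@nSubstitutions, ins = cc@nInsertions,
                         dels = cc@nDeletions, consensus = cons,
                         stringsAsFactors = FALSE))
}

summariseRun <- function(report, pm, config) {
  expected <- NULL
  truth <- config$truthWells
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read.delim(truth,
                                                 stringsAsFactors = FALSE)
    if (all(c("position_id", "design_ids") %in% names(truth)))
      expected <- setNames(truth$design_ids, truth$position_id)
  }
  correct <- report$category == "perfect"
  if (!is.null(expected)) {
    exp1 <- vapply(strsplit(as.character(expected[report$position_id]), ";",
                            fixed = TRUE),
                   function(x) x[1L], character(1))
    correct <- correct & !is.na(report$matched_ref) &
      report$matched_ref == exp1
  }
  calls <- data.frame(position_id = report$position_id,
                      detected = report$pure, correct = correct)
  ra <- recoveryAccuracy(calls, pm$position_id,
                         seed = childSeed(config$seed, 17L))
  cov <- setNames(rep(0, nrow(pm)), pm$position_id)
  inPM <- report$position_id %in% pm$position_id
  covAgg <- tapply(report$n_reads[inPM], report$position_id[inPM], sum)
  cov[names(covAgg)] <- covAgg
  ra$coverage_gini <- if (sum(cov) > 0) giniCoefficient(unname(cov))
                      else NA_real_
  ra
}
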