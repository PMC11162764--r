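## Synthetic barcoded-array runs with full ground truth.
##
## The simulated read layout mirrors a barcoded recombinant plasmid fragment:
##
##   backbone .. [bcUp] BARCODE [bcDown] .. spacer .. [insUp] INSERT [insDown] .. backbone
##
## The four bracketed flanks are fixed "known sequence context": the barcode
## flanks anchor fuzzy barcode extraction, the insert flanks are the trimming
## sequences used to cut reads down to the insert before consensus building.

#' Fixed sequence context of simulated array reads
#'
#' Constant flanking/backbone sequences used by \code{\link{buildArrayRun}}.
#' Exposed so that extraction and trimming definitions can be built against
#' the same context.
#'
#' @format Named character vector with elements \code{bbLeft}, \code{bcUp},
#'   \code{bcDown}, \code{spacer}, \code{insUp}, \code{insDown}, \code{bbRight}.
#' @export
arrayContext <- c(
  bbLeft  = "GTTCGAGATCCACTAGTGACGGATC",
  bcUp    = "ACGGTCTGAGCTGCCATGGA",
  bcDown  = "TGGTCCAGTCTTCAGGAACC",
  spacer  = "CAGTTCGAGG",
  insUp   = "GCTTATTCGTGCCGTGTTAT",
  insDown = "GGGCACAGCAATCAAAAGTA",
  bbRight = "CCTGAACTGGTTACCTGCAGGCATG"
)

#' Default barcode extraction context for simulated runs
#'
#' @param maxFlankEdits per-flank edit budget.
#' @param coreLengthMin,coreLengthMax admissible barcode core lengths.
#' @return A \linkS4class{BarcodeDefinition} anchored on
#'   \code{arrayContext[["bcUp"]]} / \code{arrayContext[["bcDown"]]}.
#' @examples
#' arrayBarcodeDefinition()
#' @export
arrayBarcodeDefinition <- function(maxFlankEdits = 2L,
                                   coreLengthMin = 18L, coreLengthMax = 22L) {
  barcodeDefinition(arrayContext[["bcUp"]], arrayContext[["bcDown"]],
                    coreLengthMin, coreLengthMax, maxFlankEdits)
}

#' Generate a random barcode set with a minimum pairwise Hamming distance
#'
#' Rejection sampling: candidate barcodes are drawn uniformly and kept only if
#' their Hamming distance to every already-accepted barcode is at least
#' \code{minHamming}. The attempt budget is 1000 times the requested set size;
#' an unreachable constraint fails loudly (reporting the achieved count)
#' rather than silently relaxing the distance requirement.
#'
#' @param spec a \linkS4class{BarcodeSetSpec}.
#' @return Character vector of \code{nBarcodes} barcode sequences.
#' @examples
#' bcs <- generateBarcodeSet(barcodeSetSpec(24, length = 20, minHamming = 6,
#'                                          seed = 1))
#' @export
generateBarcodeSet <- function(spec) {
  stopifnot(is(spec, "BarcodeSetSpec"))
  validObject(spec)
  n <- spec@nBarcodes
  L <- spec@length
  minH <- spec@minHamming
  seed <- if (is.na(spec@seed)) NULL else spec@seed
  withSeed(seed, {
    accepted <- matrix(integer(0), nrow = 0L, ncol = L)
    budget <- 1000L * n
    attempts <- 0L
    while (nrow(accepted) < n && attempts < budget) {
      attempts <- attempts + 1L
      cand <- sample.int(length(spec@alphabet), L, replace = TRUE)
      if (nrow(accepted) == 0L ||
          min(rowSums(accepted != matrix(cand, nrow(accepted), L,
                                         byrow = TRUE))) >= minH) {
        accepted <- rbind(accepted, cand)
      }
    }
    if (nrow(accepted) < n)
      stop("barcode set constraint unreachable: achieved ", nrow(accepted),
           " of ", n, " barcodes within ", budget, " attempts")
    apply(accepted, 1L, function(v)
      paste(spec@alphabet[v], collapse = ""))
  })
}

## Apply i.i.d. per-base substitution errors (synthesis error model).
applySynthesisErrors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    v <- seqToInt(s)
    hit <- which(runif(length(v)) < rate)
    if (length(hit))
      v[hit] <- ((v[hit] - 1L + sample.int(3L, length(hit),
                                           replace = TRUE)) %% 4L) + 1L
    intToSeq(v)
  }, character(1), USE.NAMES = FALSE)
}

## Log-normal design frequencies with sigma = dispersion (0 => exactly uniform).
designFrequencies <- function(n, dispersion) {
  if (dispersion == 0) return(rep(1 / n, n))
  w <- exp(rnorm(n, mean = 0, sd = dispersion))
  w / sum(w)
}

#' Generate a dispersed design pool with synthesis errors
#'
#' Draws \code{nDesigns} reference sequences, assigns them log-normal
#' abundances with sigma \code{abundanceDispersion} (0 gives a perfectly
#' uniform pool), and picks \code{samplingDepth * nDesigns} clones from the
#' pool, each carrying i.i.d. per-base synthesis errors at
#' \code{synthesisErrorRate}. With the vendor-reported rate of 4e-4/nt and
#' 300 nt designs, about 11.3\% of clones are expected to carry at least one
#' error (1 - 0.9996^300).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return List with \code{designs} (named character vector of reference
#'   sequences), \code{clones} (data.frame: clone_id, design_id, sequence),
#'   and \code{abundance} (an \linkS4class{AbundanceVector} of design
#'   frequencies).
#' @examples
#' pool <- generateDesignPool(simConfig(nDesigns = 5, designLength = 60,
#'                                      samplingDepth = 3, seed = 1))
#' @export
generateDesignPool <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nDesigns == 0L) stop("empty pool: nDesigns must be >= 1")
  seed <- if (is.na(config@seed)) NULL else config@seed
  withSeed(seed, {
    ids <- sprintf("design_%04d", seq_len(config@nDesigns))
    designs <- setNames(randomDNA(config@nDesigns, config@designLength), ids)
    freqs <- designFrequencies(config@nDesigns, config@abundanceDispersion)
    nClones <- max(0L, as.integer(round(config@samplingDepth * config@nDesigns)))
    pick <- if (nClones > 0L)
      sample.int(config@nDesigns, nClones, replace = TRUE, prob = freqs)
    else integer(0)
    clones <- data.frame(
      clone_id = sprintf("clone_%06d", seq_len(nClones)),
      design_id = ids[pick],
      sequence = applySynthesisErrors(unname(designs[pick]),
                                      config@synthesisErrorRate),
      stringsAsFactors = FALSE)
    list(designs = designs, clones = clones,
         abundance = abundanceVector(setNames(freqs, ids),
                                     stage = "pool design frequencies"))
  })
}

## Vectorised error process for n reads off one template.
## Per original base: deleted w.p. del; else substituted w.p. sub (always to a
## different base); independently, one random base is inserted after the
## original position w.p. ins.
mutateTemplate <- function(tplInt, n, sub, ins, del) {
  L <- length(tplInt)
  if (n == 0L) return(character(0))
  if (sub == 0 && ins == 0 && del == 0)
    return(rep.int(intToSeq(tplInt), n))
  tot <- rep.int(tplInt, n)
  N <- n * L
  isDel <- runif(N) < del
  isSub <- runif(N) < sub
  isIns <- runif(N) < ins
  base <- tot
  hit <- which(isSub & !isDel)
  if (length(hit))
    base[hit] <- ((base[hit] - 1L + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L) + 1L
  emit <- (!isDel) + isIns
  pos <- cumsum(emit)
  out <- integer(pos[N])
  kept <- which(!isDel)
  out[pos[kept] - isIns[kept]] <- base[kept]
  insAt <- which(isIns)
  if (length(insAt))
    out[pos[insAt]] <- sample.int(4L, length(insAt), replace = TRUE)
  readLens <- colSums(matrix(emit, nrow = L))
  big <- paste(DNA_BASES[out], collapse = "")
  ends <- cumsum(readLens)
  substring(big, ends - readLens + 1L, ends)
}

#' Simulate noisy long reads from a template
#'
#' Passes the template through independent per-base substitution, insertion
#' and deletion events (an ONT-simplex-like error process without homopolymer
#' or signal-level structure). Reads carry a constant placeholder Q20 quality
#' string, matching the identity-based (not quality-based) purity rule used
#' downstream.
#'
#' @param template template sequence (character scalar over ACGT).
#' @param n number of reads.
#' @param errorRates numeric of length 3 named
#'   \code{c(substitution=, insertion=, deletion=)}.
#' @param seed integer seed or NULL.
#' @return data.frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @examples
#' simulateReads("ACGTACGTACGT", 3,
#'               c(substitution = 0, insertion = 0, deletion = 0), seed = 1)
#' @export
simulateReads <- function(template, n,
                          errorRates = c(substitution = 0.02,
                                         insertion = 0.015, deletion = 0.025),
                          seed = NULL) {
  assertDNA(template, "template")
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be >= 0")
  assertProb(errorRates, "errorRates")
  if (!all(c("substitution", "insertion", "deletion") %in% names(errorRates)))
    stop("errorRates must be named substitution/insertion/deletion")
  withSeed(seed, {
    seqs <- mutateTemplate(seqToInt(template), as.integer(n),
                           errorRates[["substitution"]],
                           errorRates[["insertion"]],
                           errorRates[["deletion"]])
    data.frame(
      read_id = sprintf("read_%06d", seq_len(length(seqs))),
      sequence = seqs,
      quality = vapply(nchar(seqs), function(w)
        paste(rep("5", w), collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  })
}

## 96-well plate coordinates: A01..H12 on plates of 96.
plateLayout <- function(nWells) {
  wells <- paste0(rep(LETTERS[1:8], each = 12),
                  sprintf("%02d", rep(1:12, times = 8)))
  plate <- (seq_len(nWells) - 1L) %/% 96L + 1L
  well <- wells[((seq_len(nWells) - 1L) %% 96L) + 1L]
  data.frame(plate = paste0("P", plate), well = well,
             position_id = paste0("P", plate, "_", well),
             stringsAsFactors = FALSE)
}

#' Build a complete simulated array run on disk
#'
#' Generates a design pool, assigns clones to barcoded wells, simulates
#' per-well Poisson-depth long reads (forward or reverse-complement with equal
#' probability), and writes a FASTQ file, a plate-map TSV, reference FASTA,
#' and ground-truth tables. Contaminated wells mix reads of two clones at a
#' ratio drawn uniformly from [0.1, 0.9]; chimeric reads carry the positional
#' barcode of a different well. Sample indices are emitted error-free (they
#' stand in for instrument-side demultiplexing tags, which the pipeline
#' consumes as called).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param barcodes character vector of positional barcodes (at least
#'   \code{nWells} of them).
#' @param outDir output directory (created if needed).
#' @param nWells number of array positions (default: one per barcode).
#' @param designAssignment \code{"arrayed"} places design i in well i
#'   (requires \code{nDesigns >= nWells}; emulates a verified arrayed test
#'   set), \code{"pooled"} samples designs by their pool frequency (shotgun
#'   demultiplexing), \code{"auto"} picks arrayed iff
#'   \code{nDesigns == nWells}.
#' @param sampleIndex optional index sequence prepended to every read
#'   (default: none).
#' @param sampleId sample label used in truth tables.
#' @return Invisibly, a list: \code{fastq}, \code{plateMap} (path),
#'   \code{referenceFasta}, \code{truthWells}, \code{truthReads} (paths),
#'   plus in-memory \code{wells}, \code{reads} (truth data.frames),
#'   \code{designs}, and \code{abundance}.
#' @examples
#' run <- buildArrayRun(simConfig(nDesigns = 4, designLength = 40,
#'                                meanDepth = 10, seed = 1),
#'                      barcodes = generateBarcodeSet(
#'                        barcodeSetSpec(4, 20, 6, seed = 2)),
#'                      outDir = tempfile("arrayrun"))
#' @export
buildArrayRun <- function(config, barcodes, outDir,
                          nWells = length(barcodes),
                          designAssignment = c("auto", "arrayed", "pooled"),
                          sampleIndex = NULL, sampleId = "sample1") {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  assertDNA(barcodes, "barcodes")
  designAssignment <- match.arg(designAssignment)
  if (nWells > length(barcodes))
    stop("more wells (", nWells, ") than barcodes (", length(barcodes), ")")
  if (!is.null(sampleIndex)) assertDNA(sampleIndex, "sampleIndex")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.na(config@seed)) NULL else config@seed

  withSeed(seed, {
    n <- config@nDesigns
    ids <- sprintf("design_%04d", seq_len(n))
    designs <- setNames(randomDNA(n, config@designLength), ids)
    freqs <- designFrequencies(n, config@abundanceDispersion)

    if (designAssignment == "auto")
      designAssignment <- if (n == nWells) "arrayed" else "pooled"
    if (designAssignment == "arrayed" && n < nWells)
      stop("arrayed assignment needs nDesigns >= nWells")

    layout <- plateLayout(nWells)
    layout$barcode <- barcodes[seq_len(nWells)]

    primary <- switch(designAssignment,
      arrayed = seq_len(nWells),
      pooled = sample.int(n, nWells, replace = TRUE, prob = freqs))
    contaminated <- runif(nWells) < config@contaminationProb
    secondary <- rep(NA_integer_, nWells)
    if (any(contaminated)) {
      secondary[contaminated] <- vapply(which(contaminated), function(i) {
        repeat {
          j <- sample.int(n, 1L, prob = freqs)
          if (j != primary[i] || n == 1L) return(j)
        }
      }, integer(1))
    }
    mixRatio <- ifelse(contaminated, runif(nWells, 0.1, 0.9), 1)

    cloneSeq1 <- applySynthesisErrors(unname(designs[primary]),
                                      config@synthesisErrorRate)
    cloneSeq2 <- rep(NA_character_, nWells)
    if (any(contaminated))
      cloneSeq2[contaminated] <- applySynthesisErrors(
        unname(designs[secondary[contaminated]]), config@synthesisErrorRate)

    depth <- rpois(nWells, config@meanDepth)
    rates <- config@readErrorRates
    ctx <- arrayContext

    allSeqs <- vector("list", nWells)
    truthReads <- vector("list", nWells)
    for (i in seq_len(nWells)) {
      d <- depth[i]
      if (d == 0L) {
        allSeqs[[i]] <- character(0)
        next
      }
      d1 <- if (contaminated[i]) rbinom(1L, d, mixRatio[i]) else d
      d2 <- d - d1
      cloneOf <- c(rep.int(1L, d1), rep.int(2L, d2))
      isChim <- runif(d) < config@chimeraProb
      seqs <- character(d)
      for (cl in 1:2) {
        sel <- which(cloneOf == cl & !isChim)
        if (!length(sel)) next
        tpl <- paste0(ctx[["bbLeft"]], ctx[["bcUp"]], layout$barcode[i],
                      ctx[["bcDown"]], ctx[["spacer"]], ctx[["insUp"]],
                      if (cl == 1L) cloneSeq1[i] else cloneSeq2[i],
                      ctx[["insDown"]], ctx[["bbRight"]])
        seqs[sel] <- mutateTemplate(seqToInt(tpl), length(sel),
                                    rates[["substitution"]],
                                    rates[["insertion"]], rates[["deletion"]])
      }
      for (r in which(isChim)) {
        other <- if (nWells > 1L)
          sample(setdiff(seq_len(nWells), i), 1L) else i
        tpl <- paste0(ctx[["bbLeft"]], ctx[["bcUp"]], layout$barcode[other],
                      ctx[["bcDown"]], ctx[["spacer"]], ctx[["insUp"]],
                      if (cloneOf[r] == 1L) cloneSeq1[i] else cloneSeq2[i],
                      ctx[["insDown"]], ctx[["bbRight"]])
        seqs[r] <- mutateTemplate(seqToInt(tpl), 1L,
                                  rates[["substitution"]],
                                  rates[["insertion"]], rates[["deletion"]])
      }
      flip <- runif(d) < 0.5
      if (any(flip)) seqs[flip] <- revComp(seqs[flip])
      if (!is.null(sampleIndex)) seqs <- paste0(sampleIndex, seqs)
      allSeqs[[i]] <- seqs
      truthReads[[i]] <- data.frame(
        source_position = layout$position_id[i],
        clone_index = cloneOf, is_chimera = isChim,
        strand = ifelse(flip, "-", "+"), stringsAsFactors = FALSE)
    }

    reads <- unlist(allSeqs, use.names = FALSE)
    readTruth <- do.call(rbind, truthReads[!vapply(truthReads, is.null,
                                                   logical(1))])
    if (is.null(readTruth))
      readTruth <- data.frame(source_position = character(0),
                              clone_index = integer(0),
                              is_chimera = logical(0), strand = character(0))
    readTruth <- cbind(read_id = sprintf("read_%07d", seq_len(length(reads))),
                       sample = rep(sampleId, length(reads)), readTruth,
                       stringsAsFactors = FALSE)

    wells <- data.frame(
      plate = layout$plate, well = layout$well,
      position_id = layout$position_id, sample = sampleId,
      barcode = layout$barcode,
      design_ids = ifelse(contaminated,
                          paste(ids[primary], ids[secondary], sep = ";"),
                          ids[primary]),
      clone_sequences = ifelse(contaminated,
                               paste(cloneSeq1, cloneSeq2, sep = ";"),
                               cloneSeq1),
      is_contaminated = contaminated, mix_ratio = mixRatio,
      depth = depth, stringsAsFactors = FALSE)

    fastq <- file.path(outDir, "reads.fastq")
    writeFastqSeqs(setNames(reads, readTruth$read_id), fastq)
    plateMapPath <- file.path(outDir, "plate_map.tsv")
    write.table(layout[, c("plate", "well", "barcode")], plateMapPath,
                sep = "\t", quote = FALSE, row.names = FALSE)
    refPath <- file.path(outDir, "references.fasta")
    writeXStringSet(DNAStringSet(designs), refPath)
    truthWellsPath <- file.path(outDir, "truth_wells.tsv")
    write.table(wells, truthWellsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    truthReadsPath <- file.path(outDir, "truth_reads.tsv")
    write.table(readTruth, truthReadsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)

    invisible(list(fastq = fastq, plateMap = plateMapPath,
                   referenceFasta = refPath, truthWells = truthWellsPath,
                   truthReads = truthReadsPath, wells = wells,
                   reads = readTruth, designs = designs,
                   abundance = abundanceVector(setNames(freqs, ids),
                                               stage = "design pool")))
  })
}
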