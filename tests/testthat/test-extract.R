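mkRead <- function(core, up = arrayContext[["bcUp"]],
                   down = arrayContext[["bcDown"]],
                   pre = "AATTC", post = "GGATC") {
  paste0(pre, up, core, down, post)
}

test_that("sample index demux is exact-match only", {
  tab <- data.frame(sample = c("s1", "s2"),
                    index = c("ACGTACGT", "TTGGCCAA"))
  expect_identical(demuxSampleIndex("ACGTACGTAAAA", tab), "s1")
  # one mismatch in the index -> unassigned
  expect_identical(demuxSampleIndex("ACGAACGTAAAA", tab), NA_character_)
  # reverse-complemented read still demuxes
  expect_identical(demuxSampleIndex(rcOracle("ACGTACGTAAAA"), tab), "s1")
  dup <- data.frame(sample = c("s1", "s2"), index = c("ACGT", "ACGT"))
  expect_error(demuxSampleIndex("ACGTAAAA", dup), "duplicate")
})

test_that("fuzzy extraction returns the exact core with exact flanks", {
  core <- "ACGTACGTACGTACG"
  def <- barcodeDefinition(arrayContext[["bcUp"]], arrayContext[["bcDown"]],
                           15, 15, maxFlankEdits = 2)
  res <- extractBarcodeFuzzy(mkRead(core), def)
  expect_identical(res$barcode, core)
  expect_identical(res$edits, 0L)
  expect_identical(res$strand, "+")
  # 0-based half-open span covers exactly the core
  expect_identical(res$end - res$start, 15L)
})

test_that("fuzzy extraction tolerates flank edits up to the budget", {
  core <- "ACGTACGTACGTACG"
  up <- arrayContext[["bcUp"]]
  # one substitution in the upstream flank
  upMut <- paste0(substr(up, 1, 9), "A", substr(up, 11, 20))
  expect_false(upMut == up)
  def <- barcodeDefinition(up, arrayContext[["bcDown"]], 15, 15,
                           maxFlankEdits = 2)
  res <- extractBarcodeFuzzy(mkRead(core, up = upMut), def)
  expect_identical(res$barcode, core)
  expect_identical(res$edits, 1L)
  # the oracle confirms no closer window exists: the flank's best
  # alignment anywhere in the read has edit distance 1
  read <- mkRead(core, up = upMut)
  wins <- vapply(seq_len(nchar(read) - nchar(up) + 1L), function(i)
    utils::adist(substr(read, i, i + nchar(up) - 1L), up), numeric(1))
  expect_identical(min(wins), 1)
  # beyond the budget the read is dropped
  def0 <- barcodeDefinition(up, arrayContext[["bcDown"]], 15, 15,
                            maxFlankEdits = 0)
  expect_true(is.na(extractBarcodeFuzzy(mkRead(core, up = upMut), def0)$barcode))
})

test_that("strand symmetry: reverse-complement reads yield the same barcode", {
  set.seed(41)
  def <- arrayBarcodeDefinition()
  for (i in 1:20) {
    core <- rDNA(1, 20)
    read <- mkRead(core)
    fwd <- extractBarcodeFuzzy(read, def)
    rev <- extractBarcodeFuzzy(rcOracle(read), def)
    expect_identical(fwd$barcode, core)
    expect_identical(rev$barcode, core)
    expect_identical(rev$strand, "-")
  }
})

test_that("zero-edit matches are preserved under larger edit budgets", {
  set.seed(43)
  cores <- rDNA(25, 20)
  reads <- vapply(cores, mkRead, character(1), USE.NAMES = FALSE)
  d0 <- barcodeDefinition(arrayContext[["bcUp"]], arrayContext[["bcDown"]],
                          18, 22, maxFlankEdits = 0)
  d2 <- barcodeDefinition(arrayContext[["bcUp"]], arrayContext[["bcDown"]],
                          18, 22, maxFlankEdits = 2)
  r0 <- extractBarcodeFuzzy(reads, d0)
  r2 <- extractBarcodeFuzzy(reads, d2)
  expect_identical(r0$barcode, cores)
  expect_identical(r2$barcode, r0$barcode)
})

test_that("extraction recall is high on substitution-noisy reads", {
  # <= 2% substitutions, edit budget 2: recall floor 95%
  set.seed(47)
  def <- arrayBarcodeDefinition()
  core <- rDNA(1, 20)
  tpl <- mkRead(core, pre = rDNA(1, 30), post = rDNA(1, 30))
  reads <- simulateReads(tpl, 400, c(substitution = 0.02, insertion = 0,
                                     deletion = 0), seed = 48)$sequence
  flip <- seq_along(reads) %% 2 == 0
  reads[flip] <- vapply(reads[flip], rcOracle, character(1),
                        USE.NAMES = FALSE)
  got <- extractBarcodeFuzzy(reads, def)
  # recall: a core was extracted (the core may itself carry read errors;
  # absorbing those is the clustering stage's job)
  recall <- mean(!is.na(got$barcode))
  expect_gte(recall, 0.95)
  ok <- !is.na(got$barcode)
  expect_true(all(utils::adist(got$barcode[ok], core) <= 3))
})

test_that("extracted cores feed clustering back to the true barcode", {
  set.seed(49)
  def <- arrayBarcodeDefinition()
  core <- rDNA(1, 20)
  tpl <- mkRead(core, pre = rDNA(1, 25), post = rDNA(1, 25))
  reads <- simulateReads(tpl, 300, c(substitution = 0.02, insertion = 0,
                                     deletion = 0), seed = 50)$sequence
  got <- extractBarcodeFuzzy(reads, def)
  cl <- clusterBarcodes(got$barcode[!is.na(got$barcode)], maxDist = 2)
  expect_identical(cl$centroid[which.max(cl$total_count)], core)
})

test_that("internal motif constraints gate the core", {
  def <- barcodeDefinition(arrayContext[["bcUp"]], arrayContext[["bcDown"]],
                           10, 10, maxFlankEdits = 1,
                           internalMotifs = list(list(motif = "AA",
                                                      window = c(3, 5))))
  expect_identical(extractBarcodeFuzzy(mkRead("GGAATTCCGG"), def)$barcode,
                   "GGAATTCCGG")
  expect_true(is.na(extractBarcodeFuzzy(mkRead("GGGGTTCCGG"), def)$barcode))
})

test_that("printed regex patterns behave as independently verified", {
  # expectations frozen from an independent regex engine
  expect_identical(extractBarcodeRegex("TTTGGCACGTAACGTGTTCTAGGCGGTT",
                                       "donor"),
                   "TGGCACGTAACGTGTTCTAGGCGG")
  expect_identical(extractBarcodeRegex(strrep("A", 30), "donor"),
                   NA_character_)
  recipRead <- "TTGACACGTGCAAGTCAAACTGTCTTGACTGCTCGTT"
  expect_identical(extractBarcodeRegex(recipRead, "recipient"),
                   "GACACGTGCAAGTCAAACTGTCTTGACTGCTCG")
  # a recipient-structured read does not match the donor pattern
  expect_identical(extractBarcodeRegex(recipRead, "donor"), NA_character_)
})

test_that("UMI extraction is positional and guards short reads", {
  read <- "ACGTACGTTTTTCCCC"
  expect_identical(extractUMI(read, 0, 8), "ACGTACGT")
  expect_identical(extractUMI(read, 0, 8), extractUMI(read, 0, 8))
  expect_identical(extractUMI("ACG", 0, 8), NA_character_)
  expect_identical(extractUMI(read, 20, 4), NA_character_)
})
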