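test_that("barcode sets honour length, count and pairwise Hamming floor", {
  # single unconstrained barcode
  one <- generateBarcodeSet(barcodeSetSpec(1, length = 15, minHamming = 0,
                                           seed = 1))
  expect_length(one, 1L)
  expect_match(one, "^[ACGT]{15}$")

  # small set, exhaustive pairwise check against the brute-force oracle
  four <- generateBarcodeSet(barcodeSetSpec(4, length = 4, minHamming = 2,
                                            seed = 7))
  expect_length(four, 4L)
  expect_gte(minPairwiseHamming(four), 2)

  # production-scale set: 768 20-mers at pairwise Hamming >= 6
  big <- generateBarcodeSet(barcodeSetSpec(768, length = 20, minHamming = 6,
                                           seed = 42))
  expect_length(big, 768L)
  expect_true(all(nchar(big) == 20L))
  expect_false(anyDuplicated(big) > 0)
  m <- do.call(rbind, strsplit(big, ""))
  dmin <- vapply(seq_len(767), function(i) {
    rest <- m[seq(i + 1L, 768L), , drop = FALSE]
    min(rowSums(rest != matrix(m[i, ], nrow(rest), 20, byrow = TRUE)))
  }, numeric(1))
  expect_gte(min(dmin), 6)  # exhaustive all-pairs verification
})

test_that("unreachable barcode constraints fail loudly", {
  expect_error(
    generateBarcodeSet(barcodeSetSpec(100, length = 2, minHamming = 2,
                                      seed = 1)),
    "unreachable")
})

test_that("barcode generation is deterministic given the seed", {
  a <- generateBarcodeSet(barcodeSetSpec(30, 20, 6, seed = 99))
  b <- generateBarcodeSet(barcodeSetSpec(30, 20, 6, seed = 99))
  expect_identical(a, b)
})

test_that("design pools: zero synthesis error copies designs verbatim", {
  cfg <- simConfig(nDesigns = 10, designLength = 80, synthesisErrorRate = 0,
                   samplingDepth = 5, seed = 3)
  pool <- generateDesignPool(cfg)
  expect_identical(unname(pool$clones$sequence),
                   unname(pool$designs[pool$clones$design_id]))
  expect_s4_class(pool$abundance, "AbundanceVector")
})

test_that("synthesis errors hit the predicted fraction of clones", {
  # 1 - (1 - 4e-4)^300 of 300-mers should carry >= 1 error
  cfg <- simConfig(nDesigns = 50, designLength = 300,
                   synthesisErrorRate = 4e-4, samplingDepth = 200,
                   abundanceDispersion = 0, seed = 21)
  pool <- generateDesignPool(cfg)
  errFrac <- mean(pool$clones$sequence !=
                  unname(pool$designs[pool$clones$design_id]))
  expected <- 1 - (1 - 4e-4)^300
  se <- sqrt(expected * (1 - expected) / nrow(pool$clones))
  expect_lt(abs(errFrac - expected), 3 * se)
})

test_that("dispersion knob: sigma 0 gives an exactly uniform pool", {
  cfg <- simConfig(nDesigns = 25, designLength = 40,
                   abundanceDispersion = 0, seed = 5)
  pool <- generateDesignPool(cfg)
  expect_equal(giniCoefficient(pool$abundance), 0)
  cfg2 <- simConfig(nDesigns = 25, designLength = 40,
                    abundanceDispersion = 1.5, seed = 5)
  expect_gt(giniCoefficient(generateDesignPool(cfg2)$abundance), 0.2)
})

test_that("read simulator: zero error rates reproduce the template", {
  r <- simulateReads("ACGTACGTACGTACGTACGT", 5,
                     c(substitution = 0, insertion = 0, deletion = 0),
                     seed = 1)
  expect_identical(r$sequence, rep("ACGTACGTACGTACGTACGT", 5))
  expect_identical(nchar(r$quality), nchar(r$sequence))
  expect_identical(nrow(simulateReads("ACGT", 0)), 0L)
})

test_that("read simulator recovers the configured substitution rate", {
  tpl <- rDNA(1, 1000, seed = 8)
  r <- simulateReads(tpl, 200, c(substitution = 0.01, insertion = 0,
                                 deletion = 0), seed = 9)
  ident <- seqIdentity(r$sequence, tpl)
  # per-read identity ~ 1 - rate; MC tolerance: 3 SEs of the mean
  se <- sqrt(0.01 * 0.99 / (200 * 1000))
  expect_lt(abs(mean(1 - ident) - 0.01), 3 * se)
  expect_error(simulateReads("ACGT", 5, c(substitution = -0.1,
                                          insertion = 0, deletion = 0)),
               "\\[0, 1\\]")
})

test_that("array runs: clean configs keep every read on its own barcode", {
  cfg <- simConfig(nDesigns = 6, designLength = 60, synthesisErrorRate = 0,
                   meanDepth = 15, contaminationProb = 0, chimeraProb = 0,
                   readErrorRates = c(substitution = 0, insertion = 0,
                                      deletion = 0),
                   seed = 31)
  bcs <- generateBarcodeSet(barcodeSetSpec(6, 20, 6, seed = 32))
  run <- buildArrayRun(cfg, bcs, outDir = withr::local_tempdir())
  expect_false(any(run$reads$is_chimera))
  seqs <- readLines(run$fastq)
  seqs <- seqs[seq(2, length(seqs), by = 4)]
  bcOf <- setNames(run$wells$barcode, run$wells$position_id)
  hasOwn <- mapply(function(s, pos) {
    grepl(bcOf[pos], s, fixed = TRUE) ||
      grepl(rcOracle(bcOf[pos]), s, fixed = TRUE)
  }, seqs, run$reads$source_position)
  expect_true(all(hasOwn))
})

test_that("chimera rate is honoured within Monte Carlo error", {
  cfg <- simConfig(nDesigns = 48, designLength = 50, meanDepth = 200,
                   chimeraProb = 0.05, seed = 77)
  bcs <- generateBarcodeSet(barcodeSetSpec(48, 20, 6, seed = 78))
  run <- buildArrayRun(cfg, bcs, outDir = withr::local_tempdir())
  n <- nrow(run$reads)
  expect_gt(n, 5000)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(run$reads$is_chimera) - 0.05), 3 * se)
})

test_that("identical config and seed give byte-identical runs", {
  cfg <- simConfig(nDesigns = 5, designLength = 50, meanDepth = 10,
                   contaminationProb = 0.2, chimeraProb = 0.02, seed = 13)
  bcs <- generateBarcodeSet(barcodeSetSpec(5, 20, 6, seed = 14))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- buildArrayRun(cfg, bcs, outDir = d1)
  r2 <- buildArrayRun(cfg, bcs, outDir = d2)
  expect_identical(readLines(r1$fastq), readLines(r2$fastq))
  expect_identical(readLines(r1$truthWells), readLines(r2$truthWells))
  # contaminated wells list two clones
  cont <- r1$wells[r1$wells$is_contaminated, ]
  if (nrow(cont))
    expect_true(all(grepl(";", cont$design_ids, fixed = TRUE)))
})

test_that("more wells than barcodes is rejected", {
  cfg <- simConfig(nDesigns = 5, designLength = 30, seed = 1)
  expect_error(buildArrayRun(cfg, rDNA(3, 20, seed = 2), tempfile(),
                             nWells = 5), "more wells")
})
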