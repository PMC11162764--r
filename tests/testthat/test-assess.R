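test_that("purity score counts reads at or above the identity threshold", {
  cons <- rDNA(1, 100, seed = 101)
  expect_identical(purityScore(cons, rep(cons, 10)), 1)
  # 9 of 10 reads >= 0.90 identity -> purity 0.9
  bad <- mutateSubsOracle(cons, 15, seed = 102)
  expect_lt(seqIdentity(bad, cons), 0.90)
  expect_identical(purityScore(cons, c(rep(cons, 9), bad)), 0.9)
  expect_error(purityScore(cons, character(0)), "zero reads")
  # monotonicity: lowering the threshold never decreases purity
  set.seed(103)
  reads <- vapply(1:20, function(i)
    mutateSubsOracle(cons, sample(0:20, 1), seed = 1000 + i), character(1))
  ths <- seq(1, 0.5, by = -0.05)
  ps <- vapply(ths, function(t) purityScore(cons, reads, idThreshold = t),
               numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("the pure call enforces the 5-read / 0.9-purity rule", {
  expect_true(callPure(1.0, 5))
  expect_false(callPure(1.0, 4))
  expect_false(callPure(0.89, 100))
  expect_true(callPure(0.90, 5))   # inclusive thresholds
})

test_that("correctness classification spans all categories", {
  refs <- setNames(rDNA(3, 120, seed = 104), c("r1", "r2", "r3"))
  perfect <- classifyCorrectness(refs[["r2"]], refs)
  expect_identical(category(perfect), "perfect")
  expect_identical(perfect@matchedRef, "r2")
  expect_identical(c(perfect@nSubstitutions, perfect@nInsertions,
                     perfect@nDeletions), c(0L, 0L, 0L))

  oneSub <- mutateSubsOracle(refs[["r1"]], 1, seed = 105)
  errCall <- classifyCorrectness(oneSub, refs)
  expect_identical(category(errCall), "error")
  expect_identical(errCall@matchedRef, "r1")
  expect_identical(errCall@nSubstitutions, 1L)
  expect_identical(errCall@nInsertions + errCall@nDeletions, 0L)

  # maps only to the host genome -> off_target
  host <- rDNA(1, 600, seed = 106)
  fromHost <- substr(host, 101, 220)
  offt <- classifyCorrectness(fromHost, refs, hostGenome = host)
  expect_identical(category(offt), "off_target")
  # maps nowhere -> other
  expect_identical(category(classifyCorrectness(rDNA(1, 120, seed = 107),
                                                refs)), "other")
  # impure positions are mixed by construction
  expect_identical(category(classifyCorrectness(refs[["r1"]], refs,
                                                pure = FALSE)), "mixed")
  expect_error(classifyCorrectness("ACGT", character(0)), "non-empty")
})

test_that("mixed wells score impure, clean wells score pure", {
  # 50/50 mixture of two inserts >= 10% divergent: purity < 0.9 almost always
  set.seed(108)
  impureCount <- 0L
  for (w in 1:12) {
    a <- rDNA(1, 200)
    b <- mutateSubsOracle(a, 30, seed = 2000 + w)  # 15% divergent
    reads <- c(simulateReads(a, 20, seed = 3000 + w)$sequence,
               simulateReads(b, 20, seed = 4000 + w)$sequence)
    cc <- polishConsensus(draftConsensus(reads), reads)
    p <- purityScore(consensusSequence(cc), reads)
    if (p < 0.9) impureCount <- impureCount + 1L
  }
  expect_gte(impureCount / 12, 0.95)

  # contamination-free wells with >= 5 reads are pure
  for (w in 1:5) {
    a <- rDNA(1, 200)
    reads <- simulateReads(a, 30, seed = 5000 + w)$sequence
    cc <- polishConsensus(draftConsensus(reads), reads)
    expect_true(callPure(purityScore(consensusSequence(cc), reads),
                         length(reads)))
  }
})

test_that("recovery and accuracy arithmetic matches the definitions", {
  mk <- function(n, det, cor) {
    ids <- sprintf("p%03d", seq_len(n))
    list(calls = data.frame(position_id = ids[seq_len(det)],
                            detected = TRUE,
                            correct = c(rep(TRUE, cor),
                                        rep(FALSE, det - cor))),
         known = ids)
  }
  x <- mk(100, 100, 100)
  ra <- recoveryAccuracy(x$calls, x$known, B = 50, seed = 1)
  expect_identical(ra$recovery_pct, 100)
  expect_identical(ra$accuracy_pct, 100)

  y <- mk(100, 95, 93)
  ra2 <- recoveryAccuracy(y$calls, y$known, B = 50, seed = 1)
  expect_identical(ra2$recovery_pct, 95)
  expect_equal(ra2$accuracy_pct, 100 * 93 / 95)

  z <- recoveryAccuracy(data.frame(position_id = character(0),
                                   detected = logical(0),
                                   correct = logical(0)),
                        sprintf("p%03d", 1:100), B = 50, seed = 1)
  expect_identical(z$recovery_pct, 0)
  expect_false(z$accuracy_defined)
  expect_identical(z$accuracy_pct, 0)
})

test_that("bootstrap standard errors behave like the binomial closed form", {
  expect_identical(bootstrapSE(rep(1, 50), seed = 1), 0)
  set.seed(109)
  x <- runif(768) < 0.9
  se <- bootstrapSE(as.numeric(x), B = 2000, seed = 2)
  closed <- sqrt(mean(x) * (1 - mean(x)) / 768)
  expect_lt(abs(se - closed) / closed, 0.2)
  expect_identical(bootstrapSE(as.numeric(x), B = 500, seed = 7),
                   bootstrapSE(as.numeric(x), B = 500, seed = 7))
})
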