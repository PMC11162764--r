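test_that("basic clustering: singletons, error halos, far pairs", {
  one <- clusterBarcodes(c(ACGTACGTACGTACG = 7), maxDist = 2)
  expect_identical(nrow(one), 1L)
  expect_identical(one$centroid, "ACGTACGTACGTACG")

  # a true barcode with five distinct 1-edit variants collapses to one cluster
  true <- "ACGTACGTACGTACG"
  vars <- c("CCGTACGTACGTACG", "AAGTACGTACGTACG", "ACGTACGTACGTACC",
            "ACGTACGAACGTACG", "ACGTCGTACGTACG")  # subs + one deletion
  expect_true(all(utils::adist(vars, true) <= 2))  # oracle membership check
  obs <- setNames(c(100, rep(1, 5)), c(true, vars))
  cl <- clusterBarcodes(obs, maxDist = 2)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$centroid, true)
  expect_identical(cl$total_count, 105)

  far <- clusterBarcodes(c(AAAAAAAAAA = 5, TTTTTTTTTT = 4), maxDist = 2)
  expect_identical(nrow(far), 2L)
})

test_that("count conservation holds over random observation sets", {
  set.seed(61)
  for (rep in 1:5) {
    seqs <- unique(rDNA(40, 12))
    obs <- setNames(sample.int(50, length(seqs), replace = TRUE), seqs)
    cl <- clusterBarcodes(obs, maxDist = 2)
    expect_equal(sum(cl$total_count), sum(obs))
    expect_true(all(vapply(seq_len(nrow(cl)), function(i)
      cl$centroid[i] %in% names(cl$members[[i]]), logical(1))))
  }
})

test_that("greedy clustering matches the step-by-step oracle", {
  set.seed(67)
  for (rep in 1:4) {
    base <- rDNA(6, 15)
    noisy <- unlist(lapply(base, function(b) {
      c(b, vapply(1:4, function(i) mutateSubsOracle(b, sample(1:3, 1),
                                                    seed = rep * 100 + i),
                  character(1)))
    }))
    obs <- table(sample(noisy, 200, replace = TRUE,
                        prob = rep(c(20, 1, 1, 1, 1), 6)))
    obs <- setNames(as.numeric(obs), names(obs))
    expect_lte(length(obs), 50)
    got <- clusterBarcodes(obs, maxDist = 2)
    ora <- greedyClusterOracle(obs, maxDist = 2)
    expect_identical(got$centroid, ora$centroids)
    gotCounts <- got$total_count
    oraCounts <- vapply(seq_along(ora$centroids), function(c)
      sum(ora$counts[ora$membership == c]), numeric(1))
    expect_identical(gotCounts, oraCounts)
  }
})

test_that("assignment to known barcodes: exact, too far, tied", {
  known <- c(P1_A01 = "AAAAA", P1_A02 = "AAAAT", P1_A03 = "GGGGG")
  exact <- assignToKnown("GGGGG", known, maxDist = 2)
  expect_identical(exact$assigned_id, "P1_A03")
  expect_identical(exact$distance, 0L)

  far <- assignToKnown("CCCCC", known, maxDist = 2)
  expect_true(is.na(far$assigned_id))

  # hand-built tie: AAAAC is one substitution from both AAAAA and AAAAT
  expect_equal(c(utils::adist("AAAAC", "AAAAA"),
                 utils::adist("AAAAC", "AAAAT")), c(1, 1))
  tie <- assignToKnown("AAAAC", known, maxDist = 2)
  expect_true(is.na(tie$assigned_id))
  expect_true(tie$tie)

  expect_error(assignToKnown("AAAAA", c(a = "ACGT", b = "ACGT")),
               "duplicate")
})

test_that("cluster-to-truth assignment is perfect on well-separated barcodes", {
  # true barcodes pairwise >= 6 apart, per-base error <= 2%
  truth <- generateBarcodeSet(barcodeSetSpec(40, 20, 6, seed = 71))
  names(truth) <- sprintf("bc%02d", seq_along(truth))
  set.seed(72)
  reads <- unlist(lapply(truth, function(b) {
    n <- 30
    muts <- rbinom(n, 20, 0.02)
    vapply(seq_len(n), function(i)
      if (muts[i] == 0) b else mutateSubsOracle(b, muts[i],
                                                seed = sample.int(1e6, 1)),
      character(1))
  }))
  cl <- clusterBarcodes(as.character(reads), maxDist = 2)
  asg <- assignToKnown(cl, truth, maxDist = 2)
  big <- asg[cl$total_count >= 5, ]
  expect_identical(length(unique(big$assigned_id)), 40L)
  # every read lands in a cluster assigned to its own barcode
  memberOf <- unlist(lapply(seq_len(nrow(cl)), function(i)
    setNames(rep(asg$assigned_id[i], length(cl$members[[i]])),
             names(cl$members[[i]]))))
  readSrc <- rep(names(truth), each = 30)
  readAsg <- unname(memberOf[as.character(reads)])
  ok <- !is.na(readAsg)
  expect_true(all(readAsg[ok] == readSrc[ok]))
  expect_gte(mean(ok), 0.95)
})

test_that("UMI deduplication counts distinct UMIs per pair", {
  expect_identical(dedupUMIs(rep("P", 3), rep("u1", 3)), c(P = 1))
  expect_identical(dedupUMIs(rep("P", 3), c("u1", "u2", "u3")), c(P = 3))
  # UMIs are scoped within pairs
  got <- dedupUMIs(c("P1", "P2", "P1"), c("u1", "u1", "u1"))
  expect_identical(got, c(P1 = 1, P2 = 1))
})

test_that("the chimera filter applies the strict <20 rule", {
  counts <- c(a = 19, b = 20, c = 21, d = 0)
  kept <- filterPairCounts(counts)
  expect_identical(names(kept), c("b", "c"))
  expect_identical(filterPairCounts(setNames(numeric(0), character(0))),
                   setNames(numeric(0), character(0)))
})
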