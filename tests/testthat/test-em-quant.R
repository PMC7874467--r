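test_that("compatibility weights follow the per-base error likelihood", {
  # single unique hit: weight (1-eps)^L over the 36 aligned bases of a
  # 2 x 18 bp fragment
  hits <- data.frame(read_id = "r1", feature_id = "A", m = 0L)
  C <- buildCompatibility(hits, locusIds = c("A", "B"), errorRate = 0.01,
                          readLength = 18L)
  expect_equal(compatWeights(C)["r1", "A"], 0.99^36)
  # 0 vs 2 mismatches at eps = 0.01 over 36 bases: ratio ~ 1.02e-4
  hits2 <- data.frame(read_id = c("r1", "r1"), feature_id = c("A", "B"),
                      m = c(0L, 2L))
  C2 <- buildCompatibility(hits2, c("A", "B"), errorRate = 0.01,
                           readLength = 18L)
  w <- compatWeights(C2)["r1", ]
  expect_equal(unname(w["B"] / w["A"]), (0.01 / 0.99)^2)
  expect_equal(unname(w["B"] / w["A"]), 1.02e-4, tolerance = 1e-3)
  # equal mismatches give equal weights
  hits3 <- data.frame(read_id = "r", feature_id = c("A", "B"), m = c(1L, 1L))
  w3 <- compatWeights(buildCompatibility(hits3, c("A", "B"), 0.01, 18L))
  expect_equal(w3[1, "A"], w3[1, "B"])
  # missing mismatch info is a hard error naming the record
  expect_error(buildCompatibility(
    data.frame(read_id = "rX", feature_id = "A", m = NA_integer_),
    c("A"), 0.01, 18L), "rX")
})

test_that("EM fixed points: unique reads, symmetric loci, and the 2/3 MLE", {
  # uniquely mapped reads: theta is the empirical fraction immediately
  W <- matrix(0, 5, 2); W[1:3, 1] <- 0.9; W[4:5, 2] <- 0.9
  est <- emQuantify(compatibilityMatrix(W))
  expect_equal(unname(theta(est)), c(0.6, 0.4), tolerance = 1e-12)
  expect_lte(est@iterations, 3L)
  # indistinguishable loci split evenly by symmetry
  W2 <- matrix(0.5, 4, 2)
  est2 <- emQuantify(compatibilityMatrix(W2))
  expect_equal(unname(theta(est2)), c(0.5, 0.5))
  # 2 unique to A, 1 unique to B, 1 ambiguous: MLE theta_A = 2/3
  W3 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  est3 <- emQuantify(compatibilityMatrix(W3), tol = 1e-12, maxIter = 10000L)
  g <- gridSearchMLE(W3, step = 0.001)
  expect_equal(unname(theta(est3)), c(2, 1) / 3, tolerance = 1e-3)
  expect_equal(unname(theta(est3)), g$theta, tolerance = 1e-3)
  expect_equal(unname(expectedCounts(est3)), c(8, 4) / 3, tolerance = 1e-2)
  expect_error(emQuantify(compatibilityMatrix(matrix(0, 0, 2))), "empty")
})

test_that("EM conserves mass and the log-likelihood never decreases", {
  set.seed(11)
  for (r in 1:20) {
    W <- randomCompat(K = sample(2:3, 1), n = sample(3:6, 1))
    est <- emQuantify(compatibilityMatrix(W))
    expect_equal(sum(theta(est)), 1, tolerance = 1e-9)
    expect_true(all(theta(est) >= -1e-12))
    expect_equal(sum(expectedCounts(est)), nrow(W), tolerance = 1e-6)
    if (est@iterations > 1)
      expect_true(all(diff(logLikTrace(est)) >= -1e-9 * abs(logLikTrace(est)[-1])))
  }
})

test_that("relabelling reads and loci permutes the EM output identically", {
  set.seed(13)
  W <- randomCompat(K = 3, n = 6)
  rownames(W) <- paste0("r", 1:6); colnames(W) <- paste0("L", 1:3)
  est <- emQuantify(compatibilityMatrix(W), tol = 1e-12, maxIter = 20000L)
  pr <- sample(6); pc <- sample(3)
  estP <- emQuantify(compatibilityMatrix(W[pr, pc]), tol = 1e-12,
                     maxIter = 20000L)
  expect_equal(theta(estP), theta(est)[pc], tolerance = 1e-6)
  expect_equal(expectedCounts(estP), expectedCounts(est)[pc], tolerance = 1e-6)
})

test_that("SAM round-trip of the compatibility matrix is lossless", {
  sim <- tinySim(); rs <- tinyReads(); aln <- tinyAln()
  sam <- file.path(withr::local_tempdir(), "aln.sam")
  writeSAM(aln$hits, rs, sim, sam)
  for (lib in c("input", "IP")) {
    direct <- buildCompatibility(aln$hits, sim@truth$locus_id,
                                 rs@errorRate, rs@readLength, library = lib)
    roundtrip <- buildCompatibility(sam, sim@truth$locus_id,
                                    rs@errorRate, rs@readLength)
    # the SAM holds both libraries; subset to this one
    keep <- readIds(roundtrip) %in% readIds(direct)
    Wrt <- compatWeights(roundtrip)[keep, , drop = FALSE]
    Wd <- compatWeights(direct)
    expect_identical(sort(rownames(Wrt)), sort(rownames(Wd)))
    Wrt <- Wrt[rownames(Wd), colnames(Wd)]
    expect_equal(as.matrix(Wrt), as.matrix(Wd), tolerance = 1e-12)
  }
})

test_that("class aggregation sums abundances and conserves the total", {
  est <- new("AbundanceEstimate",
             theta = c(L1 = 0.5, L2 = 0.3, L3 = 0.2),
             counts = c(L1 = 50, L2 = 30, L3 = 20),
             logLik = c(-10, -9), iterations = 2L, converged = TRUE,
             nReads = 100L)
  calls <- data.frame(locus_id = c("L1", "L2", "L3"),
                      class = c("FULLY_INTACT", "FULLY_INTACT", "ORF1_TRUNC"))
  agg <- aggregateByClass(est, calls)
  expect_equal(attr(agg, "intact_l1"), 0.8)
  expect_equal(sum(agg$theta), 1)
  expect_equal(sum(agg$counts), 100)
  calls$class[2] <- "ORF1_INTACT_ORF2_TRUNC"
  agg2 <- aggregateByClass(est, calls)
  expect_equal(attr(agg2, "intact_l1"), 0.5)
  expect_equal(attr(agg2, "intact_orf1"), 0.8)
  expect_error(aggregateByClass(est, calls[1:2, ]), "no intactness call")
})

test_that("unique-origin reads map only to their origin when loci differ and errors are off", {
  cfg <- simConfig(seed = 55L, nL1Loci = 3L, divergenceRate = 0.08,
                   errorRate = 0,
                   hostCategories = c(mRNA = 0L, histone = 0L, MT = 0L,
                                      rRNA = 0L, lncRNA = 0L, circRNA_host = 0L),
                   nReadsInput = 300L, nReadsIP = 0L)
  sim <- simulateGenome(cfg)
  rs <- simulateReads(sim)
  aln <- emulateAlignment(rs, sim, maxMismatches = 0L)
  hits <- as.data.frame(aln$hits)
  truthOrigin <- stats::setNames(rs@fragments$feature_id, rs@fragments$read_id)
  expect_true(all(hits$feature_id == truthOrigin[hits$read_id]))
  expect_true(all(hits$m1 + hits$m2 == 0))
})
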