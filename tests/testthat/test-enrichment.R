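library(GenomicRanges)

test_that("read-category assignment is hierarchical and fractions sum to one", {
  rRNA <- GRanges("chr1", IRanges::IRanges(1, 1000))
  exons <- GRanges("chr1", IRanges::IRanges(c(500, 2000), c(1500, 2500)))
  l1 <- GRanges("chr1", IRanges::IRanges(3000, 4000))
  # all reads inside rRNA
  reads <- GRanges("chr1", IRanges::IRanges(c(10, 500, 900), width = 50))
  expect_equal(unname(countReadCategories(reads, rRNA, exons, l1)[1:4]),
               c(1, 0, 0, 0))
  # a read overlapping both rRNA and an exon counts as rRNA only
  reads2 <- GRanges("chr1", IRanges::IRanges(c(990, 2100, 3500, 5000), width = 50))
  fr <- countReadCategories(reads2, rRNA, exons, l1)
  expect_equal(unname(fr[1:4]), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(fr), 1)
  expect_error(countReadCategories(GRanges(), rRNA, exons, l1), "no reads")
})

test_that("simulated primary alignments reproduce the true category fractions", {
  sim <- tinySim(); rs <- tinyReads(); aln <- tinyAln()
  hits <- as.data.frame(aln$hits)
  prim <- hits[hits$primary & hits$library == "input", ]
  rg <- GRanges(prim$feature_id,
                IRanges::IRanges(prim$w1s, prim$w2s + rs@readLength - 1L))
  g <- sim@genes
  fr <- countReadCategories(rg, rRNA = g[g$category == "rRNA"],
                            exons = g[g$category != "rRNA"], l1 = sim@loci)
  ft <- rs@featureTruth
  pR <- sum(ft$abundance_input[ft$category == "rRNA"])
  pL <- sum(ft$abundance_input[ft$feature_type == "locus"])
  n <- length(rg)
  expect_lt(abs(fr[["rRNA"]] - pR), 3 * sqrt(pR * (1 - pR) / n) + 0.01)
  expect_lt(abs(fr[["L1"]] - pL), 3 * sqrt(pL * (1 - pL) / n) + 0.01)
})

test_that("circRNA junction reads pool into a single feature", {
  expect_equal(unname(poolCircReads(c(3, 2, 0))), 5)
  expect_equal(unname(poolCircReads(numeric())), 0)
  m <- cbind(input = c(1, 0, 2), IP = c(4, 5, 6))
  expect_equal(poolCircReads(m), c(input = 3, IP = 15))
})

test_that("median-of-ratios size factors: identity, scaling, brute-force oracle", {
  counts <- matrix(rpois(300, 50), 100, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(medianRatioSizeFactors(cbind(a = counts[, 1],
                                                   b = counts[, 1]))),
               c(1, 1))
  sf <- medianRatioSizeFactors(cbind(a = counts[, 1], b = 2 * counts[, 1]))
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  # independent brute-force median-of-ratios (log-free arithmetic)
  set.seed(3)
  x <- matrix(rpois(80, 30) + 1, 20, 4)
  colnames(x) <- paste0("s", 1:4)
  geo <- apply(x, 1, function(r) prod(r)^(1 / length(r)))
  raw <- apply(x, 2, function(col) median(col / geo))
  oracle <- raw / prod(raw)^(1 / length(raw))
  expect_equal(unname(medianRatioSizeFactors(x)), unname(oracle),
               tolerance = 1e-10)
  expect_error(medianRatioSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)),
               "pseudocount")
})

test_that("fold enrichment is 1 for equal samples and invariant to library rescaling", {
  set.seed(8)
  x <- matrix(rpois(60, 40) + 1, 30, 2, dimnames = list(paste0("g", 1:30),
                                                        c("input", "IP")))
  eq <- foldEnrichment(cbind(input = x[, 1], IP = x[, 1]),
                       ipCols = "IP", inputCols = "input")
  expect_equal(eq$E, rep(1, 30))
  e1 <- foldEnrichment(x, "IP", "input")
  x2 <- x; x2[, "IP"] <- x2[, "IP"] * 7
  e2 <- foldEnrichment(x2, "IP", "input")
  expect_equal(e2$E, e1$E, tolerance = 1e-9)
  expect_error(foldEnrichment(x, character(), "input"), "declared")
})

test_that("fold enrichment with replicates uses the rank-sum path", {
  set.seed(9)
  x <- cbind(matrix(rpois(90, 20), 30, 3), matrix(rpois(90, 60), 30, 3))
  colnames(x) <- c(paste0("in", 1:3), paste0("ip", 1:3))
  rownames(x) <- paste0("g", 1:30)
  res <- foldEnrichment(x, ipCols = paste0("ip", 1:3),
                        inputCols = paste0("in", 1:3),
                        sizeFactors = stats::setNames(rep(1, 6), colnames(x)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$E > 1))
})

test_that("category summaries separate shifted categories and are symmetric", {
  set.seed(21)
  rec <- data.frame(E = c(rlnorm(200, 0, 0.3), rlnorm(200, log(2), 0.3)),
                    category = rep(c("x", "y"), each = 200))
  sx <- categorySummary(rec, "x")
  sy <- categorySummary(rec, "y")
  expect_equal(sx$p, sy$p)  # two-sided rank-sum is symmetric in the split
  expect_lt(sx$p, 0.01)
  expect_equal(sy$median, 2, tolerance = 0.15)
  expect_error(categorySummary(rec, "zz"), "empty category")
  # power at a 2x shift, n = 200: essentially always rejects at alpha 0.01
  rej <- vapply(1:20, function(i) {
    set.seed(100 + i)
    r <- data.frame(E = c(rlnorm(200, 0, 0.5), rlnorm(200, log(2), 0.5)),
                    category = rep(c("x", "y"), each = 200))
    categorySummary(r, "y")$p < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.9)
})

test_that("locus-set overlap: Jaccard percentages and Welch comparison", {
  expect_equal(unname(locusSetOverlap(
    list(A = c("a", "b", "c"), B = c("a", "b", "c")),
    withinPairs = list(c("A", "B")), betweenPairs = list(c("A", "B")))$overlap[1]),
    100)
  ov <- locusSetOverlap(list(A = c("a", "b", "c"), B = c("c", "d")),
                        withinPairs = list(c("A", "B")),
                        betweenPairs = list(c("A", "B")))
  expect_equal(unname(ov$within), 25)
  expect_true(!is.null(ov$note))  # < 2 values per group: t undefined
  # numeric sets respect the expression floor
  ovf <- locusSetOverlap(list(A = c(l1 = 5, l2 = 0.2, l3 = 2),
                              B = c(l1 = 3, l3 = 9, l4 = 1.5)),
                         withinPairs = list(c("A", "B")),
                         betweenPairs = list(c("A", "B")), floor = 1)
  expect_equal(unname(ovf$within), 100 * 2 / 3)
  # constructed 40% Jaccard with noisy thresholding recovered within 5 points
  set.seed(4)
  mk <- function(ids) stats::setNames(rpois(length(ids), 30) + 10, ids)
  shared <- sprintf("s%02d", 1:40)
  a <- mk(c(shared, sprintf("a%02d", 1:30)))
  b <- mk(c(shared, sprintf("b%02d", 1:30)))
  ov40 <- locusSetOverlap(list(A = a, B = b, C = mk(sprintf("c%02d", 1:40))),
                          withinPairs = list(c("A", "B")),
                          betweenPairs = list(c("A", "C")))
  expect_lt(abs(unname(ov40$within) - 40), 5)
  # family structure: within overlaps high, between low -> one-sided p small
  fam <- list(F1 = mk(c(shared, sprintf("x%d", 1:10))),
              F2 = mk(c(shared[1:35], sprintf("y%d", 1:12))),
              F3 = mk(c(shared[4:40], sprintf("z%d", 1:8))),
              OUT = mk(c(shared[1:3], sprintf("o%d", 1:50))),
              OUT2 = mk(c(shared[1:6], sprintf("q%d", 1:45))))
  res <- locusSetOverlap(fam,
                         withinPairs = list(c("F1", "F2"), c("F1", "F3"),
                                            c("F2", "F3")),
                         betweenPairs = list(c("F1", "OUT"), c("F2", "OUT"),
                                             c("F3", "OUT2"), c("F1", "OUT2")))
  expect_lt(res$p, 0.01)
  # degenerate constant overlaps report a note instead of failing
  same <- locusSetOverlap(list(A = mk(shared), B = mk(shared), C = mk(shared),
                               D = mk(sprintf("d%d", 1:10)),
                               E = mk(sprintf("e%d", 1:10))),
                          withinPairs = list(c("A", "B"), c("A", "C")),
                          betweenPairs = list(c("A", "D"), c("A", "E")))
  expect_true(is.na(same$p) && !is.null(same$note))
})

test_that("delta-delta-Ct relative quantification", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(22, 20, 24, 20), 4)
  expect_equal(ddct(24, 20, 22, 20), 0.25)
  expect_error(ddct(-1, 20, 20, 20))
})
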