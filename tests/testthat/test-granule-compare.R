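test_that("BH step-up adjustment matches brute force and is order-invariant", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bhFDR(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bhFDR(0.07), 0.07)
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  expect_error(bhFDR(c(0.5, NA)), "NA")
  set.seed(31)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bhFDR(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    pm <- sample(length(p))
    expect_equal(bhFDR(p[pm]), q[pm], tolerance = 1e-12)
  }
})

test_that("overlap test: odds ratio arithmetic, Haldane flag, subset contract", {
  # table (a,b,c,d) = (10,5,2,8): OR = ad/bc = 8
  u <- sprintf("g%02d", 1:25)
  A <- u[1:15]            # a + b = 15
  B <- c(u[1:10], u[16:17])  # a = 10, c = 2
  ot <- overlapTest(A, B, u)
  expect_equal(as.vector(ot$table), c(10, 2, 5, 8))
  expect_equal(ot$oddsRatio, 8)
  expect_false(ot$corrected)
  # identical sets: infinite OR without correction; corrected and flagged
  ot2 <- overlapTest(u[1:10], u[1:10], u)
  expect_true(ot2$corrected)
  expect_true(is.finite(ot2$oddsRatio))
  expect_error(overlapTest(c(u, "zz"), B, u), "subsets")
})

test_that("one-sided exact overlap p equals the hypergeometric tail and fisher.test", {
  set.seed(17)
  for (r in 1:50) {
    N <- sample(10:60, 1)
    u <- paste0("g", seq_len(N))
    A <- sample(u, sample(1:N, 1))
    B <- sample(u, sample(1:N, 1))
    ot <- overlapTest(A, B, u)
    a <- length(intersect(A, B))
    # enumeration of the tail pmf
    hi <- min(length(A), length(B))
    pEnum <- sum(stats::dhyper(a:hi, length(B), N - length(B), length(A)))
    expect_equal(ot$p, pEnum, tolerance = 1e-10)
    tab <- ot$table
    pf <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(ot$p, pf, tolerance = 1e-9)
  }
})

test_that("under independence the exact overlap p is uniform and OR centres at 1", {
  set.seed(23)
  ps <- numeric(400); ors <- numeric(400)
  u <- paste0("g", 1:80)
  for (r in 1:400) {
    A <- sample(u, 30); B <- sample(u, 40)
    ot <- overlapTest(A, B, u)
    a <- length(intersect(A, B))
    # the upper-tail p is discrete; its randomized version
    # P(X > a) + U * P(X = a) is exactly Uniform(0,1) under the null
    pStrict <- ot$p - stats::dhyper(a, 40, 40, 30)
    ps[r] <- pStrict + runif(1) * (ot$p - pStrict)
    ors[r] <- ot$oddsRatio
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(median(ors) - 1), 0.35)
})

test_that("Spearman: monotone limits, exact n = 6 permutation p, transform invariance", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearmanCor(x, x^3)$rho, 1)
  expect_equal(spearmanCor(x, -x)$rho, -1)
  expect_true(is.na(spearmanCor(x, rep(1, 5))$rho))
  set.seed(41)
  for (r in 1:5) {
    x6 <- rnorm(6); y6 <- rnorm(6)
    sp <- spearmanCor(x6, y6)
    # independent full 720-permutation enumeration
    perms <- permsOf(1:6)
    rx <- rank(x6); ry <- rank(y6)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    pEnum <- mean(abs(rhos) >= abs(sp$rho) - 1e-12)
    expect_equal(sp$p, pEnum, tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(43)
  x <- rnorm(30); y <- rnorm(30)
  s0 <- spearmanCor(x, y)
  s1 <- spearmanCor(exp(x), y)
  s2 <- spearmanCor(x, 3 * y + 100)
  expect_equal(s1$rho, s0$rho); expect_equal(s1$p, s0$p)
  expect_equal(s2$rho, s0$rho)
  # large-n t approximation agrees with cor.test
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s0$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s0$p, ct$p.value, tolerance = 1e-6)
})

test_that("partial Spearman removes shared-confounder structure", {
  set.seed(47)
  # z independent of (x, y): partial ~ marginal
  x <- rnorm(400); y <- 0.5 * x + rnorm(400); z <- rnorm(400)
  pm <- partialSpearmanCor(x, y, z)
  sm <- spearmanCor(x, y)
  expect_lt(abs(pm$rho - sm$rho), 3 / sqrt(397))
  # x and y both copies of z plus tiny noise: partial ~ 0 despite rho ~ 1
  z2 <- rnorm(400)
  x2 <- z2 + rnorm(400, sd = 0.05)
  y2 <- z2 + rnorm(400, sd = 0.05)
  expect_gt(spearmanCor(x2, y2)$rho, 0.95)
  expect_lt(abs(partialSpearmanCor(x2, y2, z2)$rho), 0.15)
  # degenerate control
  expect_true(is.na(partialSpearmanCor(z2, y2, z2)$rho))
  # monotone transform invariance
  p0 <- partialSpearmanCor(x, y, z)
  p1 <- partialSpearmanCor(exp(x), y, z^3)
  expect_equal(p1$rho, p0$rho)
})

test_that("partial Spearman agrees with the rank-residual method", {
  set.seed(53)
  for (r in 1:20) {
    n <- 60
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- 0.4 * z + 0.3 * x + rnorm(n)
    pf <- partialSpearmanCor(x, y, z)$rho
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    res <- stats::cor(stats::resid(stats::lm(rx ~ rz)),
                      stats::resid(stats::lm(ry ~ rz)))
    expect_lt(abs(pf - res), 0.02)
  }
})

test_that("join-and-compare: self-comparison, contract errors, latent recovery", {
  set.seed(59)
  enr <- data.frame(feature_id = sprintf("g%03d", 1:120),
                    E = rlnorm(120, 1, 1))
  enr$log2E <- log2(enr$E)
  enr$fdr <- runif(120, 0, 0.04)
  self <- data.frame(gene_id = enr$feature_id, value = enr$log2E)
  gc <- joinAndCompare(enr, self)
  expect_equal(gc@rho, 1)
  expect_equal(gc@n, 120L)
  # disjoint namespaces are a hard error with diagnostics
  bad <- data.frame(gene_id = sprintf("ENSG%03d", 1:120), value = rnorm(120))
  expect_error(joinAndCompare(enr, bad), "join too small")
  # latent factor: external loads 0.6 on the enrichment signal
  ext <- simulateGranuleTables(enr$feature_id, enr$log2E,
                               loadingPbody = 0.6, seed = 7)
  gc2 <- joinAndCompare(enr, ext$pbody, external2 = ext$sg)
  expect_lt(abs(gc2@rho - 0.6), 3 / sqrt(120 - 3))
  expect_false(is.na(gc2@partialRho))
})
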