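test_that("configuration validation enforces geometry and proportion invariants", {
  expect_error(simConfig(l1Length = 1000L), "too short to contain both ORFs")
  expect_error(simConfig(classProportions = c(FULLY_INTACT = 0.5,
                                              ORF1_INTACT_ORF2_TRUNC = 0.2,
                                              ORF1_TRUNC = 0.2)),
               "sum to 1")
  expect_error(simConfig(divergenceRate = 0.3), "0, 0.25")
  expect_error(simConfig(nReadsInput = -5L), "counts")
  expect_s4_class(tinyConfig(), "L1SimConfig")
})

test_that("genome simulation is deterministic and realises the engineered class mix", {
  cfg <- tinyConfig()
  s1 <- simulateGenome(cfg)
  s2 <- simulateGenome(cfg)
  expect_identical(as.character(s1@genome), as.character(s2@genome))
  expect_identical(s1@truth$class_true, s2@truth$class_true)
  tab <- table(factor(s1@truth$class_true,
                      levels = c("FULLY_INTACT", "ORF1_INTACT_ORF2_TRUNC",
                                 "ORF1_TRUNC")))
  # largest-remainder allocation of 6 loci over (0.4, 0.3, 0.3)
  expect_equal(as.integer(tab), c(2L, 2L, 2L))
  # truncated classes carry exactly one engineered stop, intact none
  expect_true(all(is.na(s1@truth$stop_codon[s1@truth$class_true == "FULLY_INTACT"])))
  expect_true(all(!is.na(s1@truth$stop_codon[s1@truth$class_true != "FULLY_INTACT"])))
})

test_that("zero divergence with all-intact proportions reproduces the consensus at every locus", {
  cfg <- simConfig(seed = 5L, nL1Loci = 4L, divergenceRate = 0,
                   classProportions = c(FULLY_INTACT = 1,
                                        ORF1_INTACT_ORF2_TRUNC = 0,
                                        ORF1_TRUNC = 0),
                   hostCategories = c(mRNA = 2L, histone = 0L, MT = 0L,
                                      rRNA = 1L, lncRNA = 0L, circRNA_host = 0L))
  sim <- simulateGenome(cfg)
  cons <- as.character(sim@consensus)
  for (id in sim@truth$locus_id)
    expect_identical(as.character(sim@genome[[id]]), cons)
  cl <- classifyLoci(sim)
  expect_true(all(cl$class == "FULLY_INTACT"))
  expect_equal(cl$orf1_coverage, rep(1, 4))
})

test_that("null enrichment leaves IP and input category fractions equal within binomial error", {
  null <- lapply(1:9, function(i) list(meanlog = 0, sdlog = 0))
  names(null) <- c("mRNA", "histone", "MT", "rRNA", "lncRNA", "circRNA_host",
                   "L1_FULLY_INTACT", "L1_ORF1_INTACT_ORF2_TRUNC",
                   "L1_ORF1_TRUNC")
  cfg <- tinyConfig(seed = 77L, enrichmentModel = null)
  rs <- simulateReads(simulateGenome(cfg))
  fr <- rs@fragments
  for (cat in c("mRNA", "rRNA", "L1_FULLY_INTACT")) {
    pIn <- mean(fr$category[fr$library == "input"] == cat)
    pIp <- mean(fr$category[fr$library == "IP"] == cat)
    se <- sqrt(pIn * (1 - pIn) * (1 / sum(fr$library == "input") +
                                    1 / sum(fr$library == "IP")))
    expect_lt(abs(pIn - pIp), 3.5 * se + 1e-9)
  }
})

test_that("a single strongly enriched gene shows the configured IP/input fraction ratio", {
  # one mRNA gene at exactly 10x among unenriched histone genes; the rRNA
  # bulk is unenriched so the IP renormalisation stays near 1
  model <- list(mRNA = list(meanlog = log(10), sdlog = 0),
                histone = list(meanlog = 0, sdlog = 0))
  cfg <- simConfig(seed = 303L, nL1Loci = 0L,
                   hostCategories = c(mRNA = 1L, histone = 10L, MT = 0L,
                                      rRNA = 2L, lncRNA = 0L, circRNA_host = 0L),
                   enrichmentModel = model,
                   nReadsInput = 150000L, nReadsIP = 150000L)
  rs <- simulateReads(simulateGenome(cfg))
  fr <- rs@fragments
  fIn <- mean(fr$feature_id[fr$library == "input"] == "mRNA_01")
  fIp <- mean(fr$feature_id[fr$library == "IP"] == "mRNA_01")
  sumPE <- sum(rs@featureTruth$abundance_input * rs@featureTruth$enrichment)
  expect_equal(fIp / fIn, 10 / sumPE, tolerance = 0.15)
  expect_equal(10 / sumPE, 10, tolerance = 0.1)
})

test_that("empty libraries are legal: FASTQ pair exists and truth is intact", {
  cfg <- tinyConfig(seed = 42L, nReadsInput = 0L, nReadsIP = 50L)
  rs <- simulateReads(simulateGenome(cfg))
  expect_equal(sum(rs@fragments$library == "input"), 0L)
  d <- withr::local_tempdir()
  paths <- writeReads(rs, d)
  expect_true(file.exists(paths[["input_R1"]]))
  expect_equal(length(readLines(paths[["input_R1"]])), 0L)
  expect_gt(nrow(rs@featureTruth), 0L)
})

test_that("every fragment appears exactly once, in exactly one library", {
  rs <- tinyReads()
  expect_false(any(duplicated(rs@fragments$read_id)))
  expect_setequal(names(rs@mate1), rs@fragments$read_id)
  expect_identical(names(rs@mate1), names(rs@mate2))
  tab <- table(rs@fragments$library)
  expect_equal(unname(tab[c("input", "IP")]), c(4000L, 4000L),
               ignore_attr = TRUE)
})

test_that("a fixed seed gives byte-identical FASTQ, SAM and TSV outputs", {
  cfg <- tinyConfig(seed = 911L, nReadsInput = 400L, nReadsIP = 400L)
  render <- function(dir) {
    sim <- simulateGenome(cfg)
    rs <- simulateReads(sim)
    writeSimulation(sim, dir)
    writeReads(rs, dir)
    aln <- emulateAlignment(rs, sim)
    writeSAM(aln$hits, rs, sim, file.path(dir, "aln.sam"))
    tools::md5sum(list.files(dir, full.names = TRUE))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- render(d1); m2 <- render(d2)
  names(m1) <- basename(names(m1)); names(m2) <- basename(names(m2))
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("category read fractions in the input converge to configured expression", {
  rs <- tinyReads()
  ft <- rs@featureTruth
  fr <- rs@fragments[rs@fragments$library == "input", ]
  n <- nrow(fr)
  for (cat in c("rRNA", "mRNA")) {
    pTrue <- sum(ft$abundance_input[ft$category == cat])
    pObs <- mean(fr$category == cat)
    se <- sqrt(pTrue * (1 - pTrue) / n)
    expect_lt(abs(pObs - pTrue), 3 * se + 1e-9)
  }
})
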