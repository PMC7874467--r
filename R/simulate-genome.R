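#' Build a simulation configuration
#'
#' Constructor for [L1SimConfig-class] with defaults that emulate the
#' statistical structure of an ORF1p RIP-seq experiment at toy-genome scale:
#' a panel of LINE-1 loci diverged from a shared full-length consensus and
#' split across the three intactness classes, host genes in six RNA
#' categories, and paired input/IP libraries whose per-feature pulldown
#' enrichments are drawn from per-category log-normal models.
#'
#' Default enrichment models (fold over input, log-normal): mRNA and lncRNA
#' median 10x; mitochondrial 25x; pooled circRNA ~34x; rRNA 1x; histone-like
#' (non-polyadenylated) fixed at exactly 1x; LINE-1 loci 60x for fully intact
#' elements, 25x for ORF1-intact/ORF2-truncated, 5x for ORF1-truncated,
#' reflecting the cis-preference of ORF1p for intact LINE-1 mRNA.
#'
#' @param seed master seed (integer).
#' @param nL1Loci number of LINE-1 loci.
#' @param l1Length element length in bp; must fit both ORFs.
#' @param orf1Aa,orf2Aa consensus ORF lengths in amino acids.
#' @param divergenceRate per-site substitution rate of each locus relative to
#'   the consensus, in \[0, 0.25\].
#' @param classProportions length-3 numeric summing to 1 (fully intact /
#'   ORF1-intact-ORF2-truncated / ORF1-truncated).
#' @param hostCategories named integer vector of gene counts; names must be
#'   `mRNA, histone, MT, rRNA, lncRNA, circRNA_host`.
#' @param geneLength host gene length in bp.
#' @param l1Fraction fraction of input expression in the LINE-1 compartment.
#' @param readLength,fragmentMean,fragmentSd read and fragment geometry (bp).
#' @param nReadsInput,nReadsIP fragments per library.
#' @param enrichmentModel named list of `list(meanlog=, sdlog=)` per category
#'   (`mRNA, histone, MT, rRNA, lncRNA, circRNA_host, L1_FULLY_INTACT,
#'   L1_ORF1_INTACT_ORF2_TRUNC, L1_ORF1_TRUNC`); missing entries take the
#'   defaults above.
#' @param errorRate per-base sequencing error probability.
#' @param minusStrand allow minus-strand loci (half the panel).
#' @param stranded record the libraries as stranded (metadata only).
#' @return A validated [L1SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nL1Loci = 6, nReadsInput = 2000, nReadsIP = 2000)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nL1Loci = 20L,
                      l1Length = 3600L,
                      orf1Aa = 340L,
                      orf2Aa = 450L,
                      divergenceRate = 0.02,
                      classProportions = c(FULLY_INTACT = 0.4,
                                           ORF1_INTACT_ORF2_TRUNC = 0.3,
                                           ORF1_TRUNC = 0.3),
                      hostCategories = c(mRNA = 30L, histone = 8L, MT = 4L,
                                         rRNA = 2L, lncRNA = 8L,
                                         circRNA_host = 4L),
                      geneLength = 1500L,
                      l1Fraction = 0.05,
                      readLength = 100L,
                      fragmentMean = 250,
                      fragmentSd = 40,
                      nReadsInput = 50000L,
                      nReadsIP = 50000L,
                      enrichmentModel = list(),
                      errorRate = 0.002,
                      minusStrand = FALSE,
                      stranded = FALSE) {
  defaults <- list(
    mRNA = list(meanlog = log(10), sdlog = 0.6),
    histone = list(meanlog = 0, sdlog = 0),
    MT = list(meanlog = log(25), sdlog = 0.4),
    rRNA = list(meanlog = 0, sdlog = 0),
    lncRNA = list(meanlog = log(10), sdlog = 0.6),
    circRNA_host = list(meanlog = log(34), sdlog = 0.4),
    L1_FULLY_INTACT = list(meanlog = log(60), sdlog = 0.3),
    L1_ORF1_INTACT_ORF2_TRUNC = list(meanlog = log(25), sdlog = 0.3),
    L1_ORF1_TRUNC = list(meanlog = log(5), sdlog = 0.3)
  )
  for (nm in names(enrichmentModel)) defaults[[nm]] <- enrichmentModel[[nm]]
  if (is.null(names(classProportions)))
    names(classProportions) <- .INTACT_CLASSES
  hc <- rep(0L, length(.HOST_CATEGORIES))
  names(hc) <- .HOST_CATEGORIES
  hc[names(hostCategories)] <- as.integer(hostCategories)
  new("L1SimConfig",
      seed = as.integer(seed), nL1Loci = as.integer(nL1Loci),
      l1Length = as.integer(l1Length), orf1Aa = as.integer(orf1Aa),
      orf2Aa = as.integer(orf2Aa), divergenceRate = divergenceRate,
      classProportions = classProportions, hostCategories = hc,
      geneLength = as.integer(geneLength), l1Fraction = l1Fraction,
      readLength = as.integer(readLength), fragmentMean = fragmentMean,
      fragmentSd = fragmentSd, nReadsInput = as.integer(nReadsInput),
      nReadsIP = as.integer(nReadsIP), enrichmentModel = defaults,
      errorRate = errorRate, minusStrand = minusStrand, stranded = stranded)
}

# Deterministic per-class locus counts from proportions (largest remainder).
.classCounts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Layout of the consensus element (1-based inclusive coordinates).
.elementLayout <- function(config) {
  utr5 <- 60L
  orf1Len <- 3L * (config@orf1Aa + 1L)
  spacer <- 30L
  orf2Len <- 3L * (config@orf2Aa + 1L)
  orf1Start <- utr5 + 1L
  orf2Start <- orf1Start + orf1Len + spacer
  list(orf1 = c(orf1Start, orf1Start + orf1Len - 1L),
       orf2 = c(orf2Start, orf2Start + orf2Len - 1L))
}

# Revert mutations that would break an ORF of an intact class: restore the
# start ATG, the terminal stop, and any codon that mutated into a premature
# stop. `bases`/`cons` are base vectors; `orf` is c(start, end).
.repairOrf <- function(bases, cons, orf) {
  idx <- seq(orf[1], orf[2])
  codStart <- seq(orf[1], orf[2] - 2L, by = 3L)
  ncod <- length(codStart)
  cods <- vapply(codStart, function(s) paste(bases[s:(s + 2L)], collapse = ""), "")
  if (cods[1] != "ATG") bases[codStart[1] + 0:2] <- c("A", "T", "G")
  if (!cods[ncod] %in% .STOP_CODONS)
    bases[codStart[ncod] + 0:2] <- cons[codStart[ncod] + 0:2]
  internal <- which(cods[-c(1, ncod)] %in% .STOP_CODONS) + 1L
  for (k in internal) bases[codStart[k] + 0:2] <- cons[codStart[k] + 0:2]
  bases
}

#' Simulate the toy genome, LINE-1 panel and host-gene annotation
#'
#' Builds a shared full-length LINE-1 consensus (5'UTR, ORF1, inter-ORF
#' spacer, ORF2, 3'UTR), derives each locus by substitution mutation at
#' `divergenceRate` (mutations that would create an accidental stop codon, or
#' destroy a start/stop, inside an ORF meant to stay intact are reverted),
#' and engineers one premature stop codon into ORF1 or ORF2 for loci of the
#' truncated classes. Host genes are random sequences, one contig each, with
#' annotated exons; histone-like genes are flagged non-polyadenylated and
#' circRNA-host genes carry a back-splice junction over their exon.
#'
#' @param config an [L1SimConfig-class].
#' @return An [L1Simulation-class] with the genome, annotations, consensus
#'   proteins and the engineered truth table.
#' @examples
#' sim <- simulateGenome(simConfig(seed = 7, nL1Loci = 4))
#' sim
#' @export
simulateGenome <- function(config) {
  validObject(config)
  set.seed(deriveSeed(config@seed, 1L))
  lay <- .elementLayout(config)

  # consensus: random UTRs/spacer around two stop-free coding regions; reject
  # the (vanishingly rare) draw where an extra long ORF arises by chance
  for (attempt in 1:20) {
    cons <- randomBases(config@l1Length)
    cons[seq(lay$orf1[1], lay$orf1[2])] <- randomCds(config@orf1Aa)
    cons[seq(lay$orf2[1], lay$orf2[2])] <- randomCds(config@orf2Aa)
    consSeq <- Biostrings::DNAString(paste(cons, collapse = ""))
    cand <- findOrfCandidates(consSeq, minOrfAa = 300L)
    if (nrow(cand) == 2L) break
  }
  orf1Prot <- Biostrings::translate(Biostrings::DNAString(
    paste(cons[seq(lay$orf1[1], lay$orf1[2] - 3L)], collapse = "")))
  orf2Prot <- Biostrings::translate(Biostrings::DNAString(
    paste(cons[seq(lay$orf2[1], lay$orf2[2] - 3L)], collapse = "")))
  consensusProteins <- Biostrings::AAStringSet(
    c(ORF1 = as.character(orf1Prot), ORF2 = as.character(orf2Prot)))

  n <- config@nL1Loci
  counts <- .classCounts(config@classProportions, n)
  classes <- sample(rep(.INTACT_CLASSES, counts))
  stopCodonIdx <- rep(NA_integer_, n)

  lociBases <- vector("list", n)
  for (i in seq_len(n)) {
    b <- cons
    nmut <- rbinom(1, config@l1Length, config@divergenceRate)
    pos <- sample.int(config@l1Length, nmut)
    b <- substituteBases(b, pos)
    # keep ORFs of the intended class clean of accidental damage
    b <- .repairOrf(b, cons, lay$orf1)
    b <- .repairOrf(b, cons, lay$orf2)
    if (classes[i] == "ORF1_TRUNC") {
      k <- sample(seq(floor(config@orf1Aa * 0.25), floor(config@orf1Aa * 0.75)), 1)
      s <- lay$orf1[1] + 3L * (k - 1L)
      b[s + 0:2] <- c("T", "A", "A")
      stopCodonIdx[i] <- k
    } else if (classes[i] == "ORF1_INTACT_ORF2_TRUNC") {
      k <- sample(seq(floor(config@orf2Aa * 0.25), floor(config@orf2Aa * 0.75)), 1)
      s <- lay$orf2[1] + 3L * (k - 1L)
      b[s + 0:2] <- c("T", "A", "A")
      stopCodonIdx[i] <- k
    }
    lociBases[[i]] <- b
  }

  locusIds <- sprintf("L1locus_%02d", seq_len(n))
  strands <- rep("+", n)
  if (config@minusStrand && n > 1)
    strands[sample.int(n, floor(n / 2))] <- "-"
  lociSeqGenomic <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
    s <- paste(lociBases[[i]], collapse = "")
    if (strands[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, ""))
  names(lociSeqGenomic) <- locusIds

  # host genes: one contig per gene, exon spans the whole gene
  hc <- config@hostCategories
  geneIds <- unlist(lapply(names(hc), function(cat)
    if (hc[[cat]] > 0) sprintf("%s_%02d", cat, seq_len(hc[[cat]])) else character()))
  geneCats <- rep(names(hc), hc)
  geneSeqs <- Biostrings::DNAStringSet(vapply(seq_along(geneIds), function(i)
    paste(randomBases(config@geneLength), collapse = ""), ""))
  names(geneSeqs) <- geneIds

  genome <- c(lociSeqGenomic, geneSeqs)

  loci <- if (n > 0) GenomicRanges::GRanges(
    seqnames = locusIds,
    ranges = IRanges::IRanges(rep(1L, n), rep(config@l1Length, n)),
    strand = strands,
    locus_id = locusIds,
    class_true = classes) else GenomicRanges::GRanges()

  if (length(geneIds)) {
    genes <- GenomicRanges::GRanges(
      seqnames = geneIds,
      ranges = IRanges::IRanges(1L, config@geneLength),
      strand = "+",
      gene_id = geneIds,
      category = geneCats,
      polyA = !(geneCats %in% c("histone", "rRNA", "MT")),
      circ_junction = geneCats == "circRNA_host")
  } else {
    genes <- GenomicRanges::GRanges()
  }

  truth <- S4Vectors::DataFrame(
    locus_id = locusIds,
    class_true = classes,
    strand = strands,
    stop_codon = stopCodonIdx)

  new("L1Simulation",
      genome = genome, loci = loci, genes = genes,
      consensus = consSeq, consensusProteins = consensusProteins,
      orfRanges = IRanges::IRanges(
        start = c(lay$orf1[1], lay$orf2[1]),
        end = c(lay$orf1[2], lay$orf2[2]),
        names = c("ORF1", "ORF2")),
      truth = truth, config = config)
}

# Transcript-orientation sequence of every feature (loci then genes).
.featureSeqs <- function(sim) {
  loci <- sim@loci
  seqs <- sim@genome[sim@truth$locus_id]
  minus <- sim@truth$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  genes <- sim@genes
  if (length(genes)) seqs <- c(seqs, sim@genome[genes$gene_id])
  seqs
}

#' Write a simulation to standard-format files
#'
#' Serialises an [L1Simulation-class]: genome FASTA, LINE-1 loci BED
#' (half-open 0-based, handled by rtracklayer), gene/exon GTF (1-based
#' inclusive), ORF1p/ORF2p consensus protein FASTA, and the engineered-truth
#' TSV.
#'
#' @param sim an [L1Simulation-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    loci = file.path(dir, "loci.bed"),
    genes = file.path(dir, "genes.gtf"),
    orf1 = file.path(dir, "consensus_orf1.fa"),
    orf2 = file.path(dir, "consensus_orf2.fa"),
    truth = file.path(dir, "truth_loci.tsv"))
  Biostrings::writeXStringSet(sim@genome, paths["genome"])
  bed <- sim@loci
  names(bed) <- bed$locus_id
  rtracklayer::export(bed, paths["loci"], format = "BED")
  if (length(sim@genes)) {
    g <- sim@genes
    gtf <- c(g, g)
    gtf$type <- rep(c("gene", "exon"), each = length(g))
    gtf$gene_biotype <- rep(g$category, 2)
    rtracklayer::export(gtf, paths["genes"], format = "GTF")
  } else {
    file.create(paths["genes"])
  }
  Biostrings::writeXStringSet(sim@consensusProteins["ORF1"], paths["orf1"])
  Biostrings::writeXStringSet(sim@consensusProteins["ORF2"], paths["orf2"])
  writeTsv(sim@truth, paths["truth"])
  invisible(paths)
}
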