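#' Emulate exhaustive multi-hit alignment of simulated reads
#'
#' Stands in for a spliced aligner run: every simulated fragment is placed at
#' every genomic position where it aligns with at most `maxMismatches`
#' mismatches (summed over both mates). Because the simulated LINE-1 loci are
#' equal-length, substitution-only copies of one consensus, the only
#' alignable offset of a LINE-1 read in any locus is its true consensus
#' offset, so mismatch counts are computed exactly from the precomputed
#' inter-locus difference positions plus the fragment's recorded sequencing
#' errors; multi-mapping then arises naturally from inter-locus similarity.
#' Host-gene reads (unrelated random sequences) map uniquely to their own
#' gene. Back-splice junction-spanning mates of circRNA-host fragments do not
#' align contiguously to the linear genome and are excluded from the hit
#' table (they are what a linear aligner drops and a circRNA caller picks
#' up).
#'
#' @param rs an [L1ReadSet-class].
#' @param sim the matching [L1Simulation-class].
#' @param maxMismatches maximum mismatches per fragment (both mates);
#'   default `ceiling(0.1 * 2 * readLength)`.
#' @return A list with `hits` (a [S4Vectors::DataFrame]: read_id, library,
#'   feature_id, transcript-space mate windows, per-mate mismatch counts,
#'   primary flag) and `unmapped` (read ids with no retained hit).
#' @export
emulateAlignment <- function(rs, sim, maxMismatches = NULL) {
  L <- rs@readLength
  if (is.null(maxMismatches)) maxMismatches <- as.integer(ceiling(0.1 * 2 * L))
  nL1 <- length(sim@loci)
  Lc <- sim@config@l1Length
  frag <- rs@fragments

  hitList <- list()

  ## --- LINE-1 fragments: compare against every locus -------------------
  if (nL1 > 0) {
    lociT <- .featureSeqs(sim)[seq_len(nL1)]
    charMat <- do.call(rbind, strsplit(as.character(lociT), ""))  # K x Lc
    locusIdx <- stats::setNames(seq_len(nL1), sim@truth$locus_id)
    isL1 <- frag$feature_type == "locus"
    if (any(isL1)) {
      # cumulative difference counts of every locus vs each origin locus
      origins <- sort(unique(locusIdx[frag$feature_id[isL1]]))
      cumD <- vector("list", nL1)
      for (o in origins) {
        d <- charMat != matrix(charMat[o, ], nrow = nL1, ncol = Lc, byrow = TRUE)
        cumD[[o]] <- cbind(0L, t(apply(d, 1, cumsum)))  # K x (Lc+1)
      }
      fi <- which(isL1)
      nf <- length(fi)
      keepL <- vector("list", nf)
      m1L <- vector("list", nf)
      m2L <- vector("list", nf)
      err1 <- as.list(frag$err1[fi]); err2 <- as.list(frag$err2[fi])
      err1b <- as.list(frag$err1_base[fi]); err2b <- as.list(frag$err2_base[fi])
      starts <- frag$start[fi]; flens <- frag$frag_len[fi]
      oIdx <- unname(locusIdx[frag$feature_id[fi]])
      for (q in seq_len(nf)) {
        o <- oIdx[q]
        w1s <- starts[q]; w1e <- w1s + L - 1L
        w2s <- starts[q] + flens[q] - L; w2e <- w2s + L - 1L
        cm <- cumD[[o]]
        m1 <- cm[, w1e + 1L] - cm[, w1s]
        m2 <- cm[, w2e + 1L] - cm[, w2s]
        adj <- function(m, pos, bases) {
          for (t in seq_along(pos)) {
            e <- pos[t]
            m <- m - (charMat[, e] != charMat[o, e]) + (charMat[, e] != bases[t])
          }
          m
        }
        if (length(err1[[q]])) m1 <- adj(m1, err1[[q]], err1b[[q]])
        if (length(err2[[q]])) m2 <- adj(m2, err2[[q]], err2b[[q]])
        keep <- which(m1 + m2 <= maxMismatches)
        keepL[[q]] <- keep
        m1L[[q]] <- m1[keep]
        m2L[[q]] <- m2[keep]
      }
      nk <- lengths(keepL)
      keepV <- unlist(keepL, use.names = FALSE)
      if (length(keepV))
        hitList <- c(hitList, list(data.frame(
          read_id = rep(frag$read_id[fi], nk),
          library = rep(frag$library[fi], nk),
          feature_id = sim@truth$locus_id[keepV],
          w1s = rep(starts, nk),
          w2s = rep(starts + flens - L, nk),
          frag_len = rep(flens, nk),
          m1 = as.integer(unlist(m1L, use.names = FALSE)),
          m2 = as.integer(unlist(m2L, use.names = FALSE)),
          stringsAsFactors = FALSE)))
    }
  }

  ## --- host-gene fragments: unique hit on the source gene --------------
  isGene <- frag$feature_type == "gene"
  if (any(isGene)) {
    gi <- which(isGene & !frag$junction)
    if (length(gi)) {
      m1 <- lengths(frag$err1[gi])
      m2 <- lengths(frag$err2[gi])
      ok <- m1 + m2 <= maxMismatches
      gi <- gi[ok]
      hitList <- c(hitList, list(data.frame(
        read_id = frag$read_id[gi], library = frag$library[gi],
        feature_id = frag$feature_id[gi],
        w1s = frag$start[gi],
        w2s = frag$start[gi] + frag$frag_len[gi] - L,
        frag_len = frag$frag_len[gi],
        m1 = as.integer(m1[ok]), m2 = as.integer(m2[ok]))))
    }
  }

  hits <- if (length(hitList)) do.call(rbind, hitList) else
    data.frame(read_id = character(), library = character(),
               feature_id = character(), w1s = integer(), w2s = integer(),
               frag_len = integer(), m1 = integer(), m2 = integer())

  # primary hit = lowest total mismatch per read (ties: first feature)
  if (nrow(hits)) {
    tot <- hits$m1 + hits$m2
    ord <- order(hits$read_id, tot, hits$feature_id)
    hits <- hits[ord, , drop = FALSE]
    hits$primary <- !duplicated(hits$read_id)
    rownames(hits) <- NULL
  } else hits$primary <- logical()

  unmapped <- setdiff(frag$read_id, hits$read_id)
  list(hits = S4Vectors::DataFrame(hits), unmapped = unmapped)
}

# FLAG bits: paired 1, proper 2, mate-unmapped 8, self-rev 16, mate-rev 32,
# first 64, last 128, secondary 256
.samFlag <- function(first, selfRev, mateRev, secondary) {
  1L + 2L +
    ifelse(selfRev, 16L, 0L) + ifelse(mateRev, 32L, 0L) +
    ifelse(first, 64L, 128L) + ifelse(secondary, 256L, 0L)
}

#' Serialise emulated alignments as a multi-hit SAM file
#'
#' Writes one record per mate per hit: proper paired-end flags, secondary
#' (0x100) for non-primary hits, `NM` mismatch tags, simple `<L>M` CIGARs
#' (the simulator is substitution-only), flat Phred-40 qualities, and
#' genome-strand coordinates (transcript windows of minus-strand loci are
#' converted).
#'
#' @param hits hit table from [emulateAlignment()].
#' @param rs the [L1ReadSet-class] (sequences).
#' @param sim the [L1Simulation-class] (contig names/lengths, strands).
#' @param path output SAM path.
#' @return Invisibly, `path`.
#' @export
writeSAM <- function(hits, rs, sim, path) {
  L <- rs@readLength
  contigs <- names(sim@genome)
  lens <- Biostrings::width(sim@genome)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs, lens))
  hits <- as.data.frame(hits)
  if (!nrow(hits)) {
    writeLines(header, path)
    return(invisible(path))
  }
  strandOf <- stats::setNames(rep("+", length(contigs)), contigs)
  strandOf[sim@truth$locus_id] <- sim@truth$strand
  minus <- strandOf[hits$feature_id] == "-"
  Lc <- stats::setNames(lens, contigs)[hits$feature_id]

  # genome-forward leftmost positions per mate
  pos1 <- ifelse(minus, Lc - (hits$w1s + L - 1L) + 1L, hits$w1s)
  pos2 <- ifelse(minus, Lc - (hits$w2s + L - 1L) + 1L, hits$w2s)
  # on + loci mate1 is genome-forward, mate2 reverse; flipped on - loci
  rev1 <- minus
  rev2 <- !minus

  seq1 <- as.character(rs@mate1[hits$read_id])
  seq2 <- as.character(rs@mate2[hits$read_id])
  # SEQ is the genome-forward-strand sequence of the aligned read
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  seq1[rev1] <- rc(seq1[rev1])
  seq2[rev2] <- rc(seq2[rev2])
  qual <- strrep("I", L)
  tlen <- abs(hits$frag_len)
  sec <- !hits$primary
  rec1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                  hits$read_id, .samFlag(TRUE, rev1, rev2, sec),
                  hits$feature_id, pos1, ifelse(sec, 0L, 255L), L, pos2,
                  ifelse(pos1 <= pos2, tlen, -tlen), seq1, qual, hits$m1)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d",
                  hits$read_id, .samFlag(FALSE, rev2, rev1, sec),
                  hits$feature_id, pos2, ifelse(sec, 0L, 255L), L, pos1,
                  ifelse(pos2 <= pos1, tlen, -tlen), seq2, qual, hits$m2)
  writeLines(c(header, rec1, rec2), path)
  invisible(path)
}

# Read a multi-hit SAM back into fragment-level (read, contig, mismatch)
# tuples: converts to BAM via Rsamtools, groups mate records by
# (qname, rname) and sums NM.
readSamHits <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos"),
                               tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(x$qname))
    return(data.frame(read_id = character(), feature_id = character(),
                      m = integer()))
  df <- data.frame(read_id = x$qname, feature_id = as.character(x$rname),
                   m = x$tag$NM, stringsAsFactors = FALSE)
  agg <- stats::aggregate(m ~ read_id + feature_id, df, sum)
  agg[order(agg$read_id, agg$feature_id), , drop = FALSE]
}
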