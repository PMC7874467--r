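#' Find candidate ORFs in a LINE-1 locus sequence
#'
#' Scans the three sense-strand frames for maximal ATG-to-stop open reading
#' frames longer than `minOrfAa` amino acids (strictly greater; LINE-1 ORFs
#' are sense-encoded, so the antisense strand is not searched). Within each
#' stop-delimited segment the first ATG defines the maximal ORF. Ambiguous
#' bases translate to `X` and never yield a start or stop.
#'
#' @param sequence a [Biostrings::DNAString], DNAStringSet element or
#'   character string over A/C/G/T/N.
#' @param minOrfAa minimum protein length (aa, excluding the stop codon);
#'   candidates must exceed it.
#' @param requireStop drop open-ended frames that run off the sequence end
#'   without a stop codon (default TRUE).
#' @return data.frame, one row per candidate sorted by start: `frame` (0-2),
#'   `start`/`end` (1-based inclusive nucleotide span including the stop
#'   codon), `length_aa`, `protein`.
#' @examples
#' findOrfCandidates(paste0("ATG", strrep("GCT", 310), "TAA"), minOrfAa = 300)
#' @export
findOrfCandidates <- function(sequence, minOrfAa = 300L, requireStop = TRUE) {
  seqChar <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", seqChar))
    stop("sequence must contain only A/C/G/T/N")
  sequence <- Biostrings::DNAString(seqChar)
  n <- length(sequence)
  out <- list()
  for (frame in 0:2) {
    m <- n - frame
    if (m < 3) next
    aaLen <- m %/% 3
    sub <- Biostrings::subseq(sequence, frame + 1L, frame + 3L * aaLen)
    aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    ch <- strsplit(aa, "")[[1]]
    stops <- c(which(ch == "*"), if (!requireStop) length(ch) + 1L)
    segStart <- 1L
    for (sp in stops) {
      if (sp > segStart) {
        seg <- ch[segStart:(sp - 1L)]
        mpos <- which(seg == "M")
        if (length(mpos)) {
          aaStart <- segStart + mpos[1] - 1L
          lenAa <- sp - aaStart
          if (lenAa > minOrfAa) {
            ntStart <- frame + 3L * (aaStart - 1L) + 1L
            hasStop <- sp <= length(ch)
            ntEnd <- frame + 3L * (sp - 1L) + if (hasStop) 3L else 0L
            out[[length(out) + 1L]] <- data.frame(
              frame = frame, start = ntStart, end = ntEnd,
              length_aa = lenAa,
              protein = paste(ch[aaStart:(sp - 1L)], collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
      segStart <- sp + 1L
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Local alignment of a candidate protein to an ORF consensus
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, BLASTP-style
#' defaults: open 11, extend 1) of a translated ORF candidate against the
#' ORF1p or ORF2p consensus. Coverage is span coverage: the fraction of the
#' consensus between the first and last aligned consensus positions
#' (internal gaps included).
#'
#' @param protein,consensus amino-acid strings or [Biostrings::AAString]s.
#' @param gapOpening,gapExtension affine gap penalties.
#' @param substitutionMatrix scoring matrix name or matrix.
#' @return list: `coverage` (consensus span / consensus length, in \[0,1\]),
#'   `score`, `consensusStart`, `consensusEnd`.
#' @examples
#' alignToConsensus("MKLVPEWFR", "MKLVPEWFR")$coverage  # 1
#' @export
alignToConsensus <- function(protein, consensus, gapOpening = 11,
                             gapExtension = 1,
                             substitutionMatrix = "BLOSUM62") {
  protein <- as.character(protein)
  consensus <- as.character(consensus)
  if (!nzchar(protein) || !nzchar(consensus))
    stop("protein and consensus must be non-empty")
  aaOk <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", x)
  if (!aaOk(protein) || !aaOk(consensus))
    stop("non-amino-acid characters in input")
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(protein),
    subject = Biostrings::AAString(consensus),
    type = "local", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  sub <- Biostrings::subject(al)
  s <- Biostrings::start(sub)
  e <- Biostrings::end(sub)
  list(coverage = (e - s + 1) / nchar(consensus),
       score = Biostrings::score(al),
       consensusStart = s, consensusEnd = e)
}

#' Classify LINE-1 locus intactness from ORF consensus coverage
#'
#' An ORF is intact when some candidate's local-alignment span covers at
#' least `threshold` of the corresponding consensus protein. Class is
#' `FULLY_INTACT` iff both ORFs are intact, `ORF1_INTACT_ORF2_TRUNC` iff
#' only ORF1 is, `ORF1_TRUNC` otherwise (including loci with no candidate
#' ORF at all).
#'
#' @param sequence locus DNA sequence.
#' @param orf1Consensus,orf2Consensus consensus proteins.
#' @param threshold minimum consensus span coverage (default 0.95).
#' @param minOrfAa candidate ORF length floor passed to
#'   [findOrfCandidates()].
#' @return one-row data.frame: orf1_intact, orf2_intact, class, best
#'   coverages against each consensus.
#' @export
classifyLocus <- function(sequence, orf1Consensus, orf2Consensus,
                          threshold = 0.95, minOrfAa = 300L) {
  cand <- findOrfCandidates(sequence, minOrfAa = minOrfAa)
  cov1 <- cov2 <- 0
  if (nrow(cand)) {
    cov1 <- max(vapply(cand$protein, function(p)
      alignToConsensus(p, orf1Consensus)$coverage, 0))
    cov2 <- max(vapply(cand$protein, function(p)
      alignToConsensus(p, orf2Consensus)$coverage, 0))
  }
  orf1 <- cov1 >= threshold
  orf2 <- cov2 >= threshold
  cls <- if (orf1 && orf2) "FULLY_INTACT" else
    if (orf1) "ORF1_INTACT_ORF2_TRUNC" else "ORF1_TRUNC"
  data.frame(orf1_intact = orf1, orf2_intact = orf2, class = cls,
             orf1_coverage = cov1, orf2_coverage = cov2,
             n_candidates = nrow(cand), stringsAsFactors = FALSE)
}

#' Classify every locus of a panel
#'
#' Applies [classifyLocus()] to each locus sequence (transcript orientation)
#' of a simulation or any named [Biostrings::DNAStringSet].
#'
#' @param x an [L1Simulation-class] or named DNAStringSet of locus sequences.
#' @param orf1Consensus,orf2Consensus consensus proteins; defaulted from the
#'   simulation when `x` is an [L1Simulation-class].
#' @param threshold,minOrfAa see [classifyLocus()].
#' @return data.frame with `locus_id` plus the [classifyLocus()] columns.
#' @export
classifyLoci <- function(x, orf1Consensus = NULL, orf2Consensus = NULL,
                         threshold = 0.95, minOrfAa = 300L) {
  if (methods::is(x, "L1Simulation")) {
    seqs <- .featureSeqs(x)[seq_along(x@loci)]
    if (is.null(orf1Consensus)) orf1Consensus <- x@consensusProteins[["ORF1"]]
    if (is.null(orf2Consensus)) orf2Consensus <- x@consensusProteins[["ORF2"]]
  } else {
    seqs <- x
  }
  stopifnot(!is.null(names(seqs)), !is.null(orf1Consensus), !is.null(orf2Consensus))
  res <- do.call(rbind, lapply(seq_along(seqs), function(i)
    classifyLocus(seqs[[i]], orf1Consensus, orf2Consensus,
                  threshold = threshold, minOrfAa = minOrfAa)))
  cbind(data.frame(locus_id = names(seqs), stringsAsFactors = FALSE), res)
}
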