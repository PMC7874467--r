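# Input-expression multipliers per host category: rRNA carries the bulk of a
# non-depleted total-RNA library; MT-like genes are moderately elevated.
.EXPR_MULT <- c(mRNA = 1, histone = 1, MT = 5, rRNA = 500, lncRNA = 1,
                circRNA_host = 1)

#' Simulate paired input/IP RIP-seq libraries with known truth
#'
#' Draws per-feature true expression (Dirichlet over LINE-1 loci within the
#' LINE-1 compartment; log-normal with category multipliers for host genes,
#' rRNA dominating the input as in real total-RNA libraries) and per-feature
#' true IP enrichment factors from the config's per-category log-normal
#' models. Input fragments are drawn feature-proportionally to expression;
#' IP fragment probabilities are expression times enrichment, renormalised.
#' Fragment lengths are normal, truncated below at the read length;
#' per-base sequencing errors are applied at `errorRate` (always to a
#' different base). circRNA-host transcripts are circular: fragments that
#' cross the origin produce back-splice junction-spanning reads.
#'
#' @param sim an [L1Simulation-class].
#' @param config an [L1SimConfig-class]; defaults to the one inside `sim`.
#' @return An [L1ReadSet-class]; its `fragments` table is the per-read origin
#'   truth (library, source feature, transcript coordinates, error positions,
#'   junction flag) and `featureTruth` the feature-level truth (abundances
#'   and enrichment factors).
#' @examples
#' cfg <- simConfig(seed = 3, nL1Loci = 4, nReadsInput = 500, nReadsIP = 500)
#' rs <- simulateReads(simulateGenome(cfg))
#' rs
#' @export
simulateReads <- function(sim, config = sim@config) {
  set.seed(deriveSeed(config@seed, 2L))
  featSeqs <- .featureSeqs(sim)
  nL1 <- length(sim@loci)
  geneIds <- if (length(sim@genes)) sim@genes$gene_id else character()
  ids <- c(sim@truth$locus_id, geneIds)
  type <- c(rep("locus", nL1), rep("gene", length(geneIds)))
  category <- c(paste0("L1_", sim@truth$class_true, recycle0 = TRUE),
                if (length(sim@genes)) sim@genes$category else character())
  featLen <- Biostrings::width(featSeqs)
  circular <- c(rep(FALSE, nL1),
                if (length(sim@genes)) sim@genes$circ_junction else logical())
  if (length(ids) == 0)
    stop("zero total expression: simulation contains no features")

  # true expression
  l1Frac <- if (length(geneIds)) config@l1Fraction else 1
  expr <- numeric(length(ids))
  if (nL1 > 0) {
    a <- stats::rgamma(nL1, 1)
    expr[seq_len(nL1)] <- a / sum(a) * l1Frac
  } else l1Frac <- 0
  if (length(geneIds)) {
    # rRNA dominates the input (no depletion step), anchoring library-size
    # normalization at the unenriched compartment
    g <- rlnorm(length(geneIds), 0, 1) *
      .EXPR_MULT[category[(nL1 + 1):length(ids)]]
    expr[(nL1 + 1):length(ids)] <- g / sum(g) * (1 - l1Frac)
  }
  if (sum(expr) <= 0) stop("zero total expression")
  expr <- expr / sum(expr)

  # true IP enrichment factors per feature
  enr <- vapply(category, function(cat) {
    m <- sim@config@enrichmentModel[[cat]]
    if (is.null(m)) m <- list(meanlog = 0, sdlog = 0)
    rlnorm(1, m$meanlog, m$sdlog)
  }, 0)
  pIn <- expr
  pIp <- expr * enr
  pIp <- pIp / sum(pIp)

  L <- config@readLength
  drawLibrary <- function(lib, nFrag, p) {
    if (nFrag == 0)
      return(list(frag = S4Vectors::DataFrame(
        read_id = character(), library = character(), feature_id = character(),
        feature_type = character(), category = character(),
        start = integer(), frag_len = integer(), junction = logical(),
        err1 = IRanges::IntegerList(), err2 = IRanges::IntegerList(),
        err1_base = IRanges::CharacterList(), err2_base = IRanges::CharacterList()),
        m1 = Biostrings::DNAStringSet(), m2 = Biostrings::DNAStringSet()))
    cnt <- as.integer(rmultinom(1, nFrag, p))
    fi <- rep(seq_along(ids), cnt)
    len <- featLen[fi]
    fl <- sampleFragmentLengths(nFrag, config@fragmentMean, config@fragmentSd,
                                minLen = L, maxLen = max(featLen))
    fl <- pmin(fl, len)
    isCirc <- circular[fi]
    start <- integer(nFrag)
    start[!isCirc] <- 1L + floor(runif(sum(!isCirc)) * (len[!isCirc] - fl[!isCirc] + 1))
    start[isCirc] <- 1L + floor(runif(sum(isCirc)) * len[isCirc])
    junction <- isCirc & (start + fl - 1L > len)

    w1s <- start; w1e <- start + L - 1L
    w2s <- start + fl - L; w2e <- start + fl - 1L
    seqChr <- as.character(featSeqs)
    doubled <- ifelse(circular, paste0(seqChr, seqChr), seqChr)[fi]
    s1 <- substring(doubled, w1s, w1e)
    s2 <- substring(doubled, w2s, w2e)

    applyErrors <- function(s, ws) {
      ne <- rbinom(length(s), L, config@errorRate)
      posList <- vector("list", length(s))
      baseList <- vector("list", length(s))
      hit <- which(ne > 0)
      for (k in hit) {
        off <- sort(sample.int(L, ne[k]))
        ch <- strsplit(s[k], "")[[1]]
        ch <- substituteBases(ch, off)
        s[k] <- paste(ch, collapse = "")
        posList[[k]] <- ws[k] + off - 1L
        baseList[[k]] <- ch[off]
      }
      posList[ne == 0] <- list(integer())
      baseList[ne == 0] <- list(character())
      list(s = s, pos = IRanges::IntegerList(posList),
           base = IRanges::CharacterList(baseList))
    }
    e1 <- applyErrors(s1, w1s)
    e2 <- applyErrors(s2, w2s)
    m1 <- Biostrings::DNAStringSet(e1$s)
    m2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(e2$s))
    readId <- sprintf("%s_%06d", lib, seq_len(nFrag))
    names(m1) <- names(m2) <- readId
    frag <- S4Vectors::DataFrame(
      read_id = readId, library = lib, feature_id = ids[fi],
      feature_type = type[fi], category = category[fi],
      start = start, frag_len = fl, junction = junction,
      err1 = e1$pos, err2 = e2$pos,
      err1_base = e1$base, err2_base = e2$base)
    list(frag = frag, m1 = m1, m2 = m2)
  }

  inp <- drawLibrary("input", config@nReadsInput, pIn)
  ip <- drawLibrary("IP", config@nReadsIP, pIp)
  thetaTrue <- rep(NA_real_, length(ids))
  if (nL1 > 0 && l1Frac > 0)
    thetaTrue[seq_len(nL1)] <- expr[seq_len(nL1)] / sum(expr[seq_len(nL1)])
  featureTruth <- S4Vectors::DataFrame(
    feature_id = ids, feature_type = type, category = category,
    length = featLen, circular = circular,
    abundance_input = pIn, abundance_ip = pIp,
    theta_true = thetaTrue, enrichment = enr)

  new("L1ReadSet",
      fragments = rbind(inp$frag, ip$frag),
      mate1 = c(inp$m1, ip$m1), mate2 = c(inp$m2, ip$m2),
      featureTruth = featureTruth,
      readLength = L, errorRate = config@errorRate)
}

#' Write simulated libraries as paired FASTQ plus truth TSVs
#'
#' @param rs an [L1ReadSet-class].
#' @param dir output directory.
#' @param gzip compress the FASTQ files.
#' @return Invisibly, named vector of written paths.
#' @export
writeReads <- function(rs, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- c(
    input_R1 = file.path(dir, paste0("input_R1", ext)),
    input_R2 = file.path(dir, paste0("input_R2", ext)),
    ip_R1 = file.path(dir, paste0("ip_R1", ext)),
    ip_R2 = file.path(dir, paste0("ip_R2", ext)),
    reads = file.path(dir, "truth_reads.tsv"),
    features = file.path(dir, "truth_features.tsv"))
  writeFq <- function(x, path) {
    # flat Phred 40 qualities
    q <- Biostrings::PhredQuality(
      vapply(Biostrings::width(x), function(w) strrep("I", w), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = gzip)
  }
  isIn <- rs@fragments$library == "input"
  writeFq(rs@mate1[isIn], paths["input_R1"])
  writeFq(rs@mate2[isIn], paths["input_R2"])
  writeFq(rs@mate1[!isIn], paths["ip_R1"])
  writeFq(rs@mate2[!isIn], paths["ip_R2"])
  fr <- as.data.frame(rs@fragments[, c("read_id", "library", "feature_id",
                                       "feature_type", "category", "start",
                                       "frag_len", "junction")])
  fr$n_errors <- lengths(rs@fragments$err1) + lengths(rs@fragments$err2)
  writeTsv(fr, paths["reads"])
  writeTsv(rs@featureTruth, paths["features"])
  invisible(paths)
}

#' Feature-level count marginal of the read simulator
#'
#' Draws the same feature-level truth process as [simulateReads()]
#' (expression, per-category log-normal enrichment) and returns multinomial
#' input/IP counts per feature directly, without materialising read
#' sequences. This is exactly the count distribution that uniquely-mapping
#' reads produce, and is the fast path for large-library enrichment
#' studies.
#'
#' @param config an [L1SimConfig-class]; `hostCategories`, `enrichmentModel`,
#'   `nReadsInput`, `nReadsIP` and `seed` are used.
#' @param nRep replicate libraries per group (columns `input_1..`, `IP_1..`).
#' @return A list: `counts` (features x samples integer matrix), `meta`
#'   ([S4Vectors::DataFrame] with category, polyA flag, true abundance and
#'   true enrichment), `groups` (named list of column indices).
#' @export
simulateCountTable <- function(config, nRep = 1L) {
  set.seed(deriveSeed(config@seed, 5L))
  hc <- config@hostCategories
  ids <- unlist(lapply(names(hc), function(cat)
    if (hc[[cat]] > 0) sprintf("%s_%02d", cat, seq_len(hc[[cat]])) else character()))
  category <- rep(names(hc), hc)
  if (!length(ids)) stop("zero total expression: no host genes configured")
  expr <- rlnorm(length(ids), 0, 1) * .EXPR_MULT[category]
  expr <- expr / sum(expr)
  enr <- vapply(category, function(cat) {
    m <- config@enrichmentModel[[cat]]
    rlnorm(1, m$meanlog, m$sdlog)
  }, 0)
  pIp <- expr * enr
  pIp <- pIp / sum(pIp)
  counts <- cbind(
    matrix(unlist(lapply(seq_len(nRep), function(r)
      rmultinom(1, config@nReadsInput, expr))), ncol = nRep),
    matrix(unlist(lapply(seq_len(nRep), function(r)
      rmultinom(1, config@nReadsIP, pIp))), ncol = nRep))
  dimnames(counts) <- list(ids, c(sprintf("input_%d", seq_len(nRep)),
                                  sprintf("IP_%d", seq_len(nRep))))
  meta <- S4Vectors::DataFrame(
    feature_id = ids, category = category,
    polyA = !(category %in% c("histone", "rRNA", "MT")),
    abundance_input = expr, enrichment = enr)
  list(counts = counts, meta = meta,
       groups = list(input = seq_len(nRep), IP = nRep + seq_len(nRep)))
}

#' Fabricate external granule-enrichment tables with declared latent structure
#'
#' Builds synthetic per-gene "p-body" and "stress-granule" log-enrichment
#' vectors tied to a signal vector (typically the log true IP enrichment) by
#' a latent-factor construction: the p-body vector loads on the standardised
#' signal with loading `loadingPbody`; the SG vector loads on the *p-body*
#' vector with loading `sgFromPbody` and carries no direct signal loading, so
#' any SG-signal correlation is mediated entirely by p-bodies (the
#' construction that partial correlation should cancel).
#'
#' @param geneIds character gene identifiers.
#' @param signal numeric vector, same length (e.g. log true enrichment).
#' @param loadingPbody correlation loading of p-body values on the signal.
#' @param sgFromPbody loading of SG values on the p-body vector.
#' @param seed integer seed.
#' @return A list of two [S4Vectors::DataFrame]s, `pbody` and `sg`, each with
#'   columns gene_id, value (log scale), source.
#' @export
simulateGranuleTables <- function(geneIds, signal, loadingPbody = 0.6,
                                  sgFromPbody = 0.8, seed = 1L) {
  stopifnot(length(geneIds) == length(signal),
            abs(loadingPbody) <= 1, abs(sgFromPbody) <= 1)
  set.seed(deriveSeed(seed, 6L))
  z <- as.numeric(scale(signal))
  pb <- loadingPbody * z + sqrt(1 - loadingPbody^2) * rnorm(length(z))
  zpb <- as.numeric(scale(pb))
  sg <- sgFromPbody * zpb + sqrt(1 - sgFromPbody^2) * rnorm(length(z))
  list(
    pbody = S4Vectors::DataFrame(gene_id = geneIds, value = pb, source = "p_body"),
    sg = S4Vectors::DataFrame(gene_id = geneIds, value = sg, source = "SG"))
}
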