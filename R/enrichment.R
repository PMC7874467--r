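#' Hierarchical read-category fractions (rRNA, exon, LINE-1, other)
#'
#' Assigns each read (primary alignment position) to exactly one category in
#' the fixed order rRNA then exon then LINE-1 then other: reads overlapping
#' rRNA intervals are counted and filtered out first, remaining reads
#' overlapping annotated exons next, then LINE-1 loci; everything else is
#' "other". Fractions sum to exactly 1.
#'
#' @param reads [GenomicRanges::GRanges] of primary alignment positions.
#' @param rRNA,exons,l1 [GenomicRanges::GRanges] of the category intervals
#'   (same coordinate system as `reads`).
#' @return named numeric: fractions for rRNA, exon, L1, other (and attribute
#'   `counts` with the raw counts).
#' @export
countReadCategories <- function(reads, rRNA, exons, l1) {
  n <- length(reads)
  if (n == 0) stop("no reads")
  lvl <- unique(c(GenomeInfoDb::seqlevels(reads), GenomeInfoDb::seqlevels(rRNA),
                  GenomeInfoDb::seqlevels(exons), GenomeInfoDb::seqlevels(l1)))
  GenomeInfoDb::seqlevels(reads) <- lvl
  GenomeInfoDb::seqlevels(rRNA) <- lvl
  GenomeInfoDb::seqlevels(exons) <- lvl
  GenomeInfoDb::seqlevels(l1) <- lvl
  remaining <- rep(TRUE, n)
  counts <- c(rRNA = 0L, exon = 0L, L1 = 0L, other = 0L)
  for (cat in c("rRNA", "exon", "L1")) {
    iv <- switch(cat, rRNA = rRNA, exon = exons, L1 = l1)
    hit <- remaining & IRanges::overlapsAny(reads, iv, ignore.strand = TRUE)
    counts[cat] <- sum(hit)
    remaining <- remaining & !hit
  }
  counts["other"] <- sum(remaining)
  out <- counts / n
  attr(out, "counts") <- counts
  out
}

#' Pool back-splice junction reads into a single circRNA feature
#'
#' No individual back-splice junction carries many reads, so all junction
#' reads are summed into one `circRNA_pooled` quantification per sample.
#'
#' @param junctionCounts numeric vector (one sample) or matrix/data.frame
#'   (junctions x samples) of back-splice junction read counts.
#' @return named numeric of pooled counts per sample.
#' @export
poolCircReads <- function(junctionCounts) {
  if (is.null(dim(junctionCounts)))
    return(c(circRNA_pooled = sum(junctionCounts)))
  out <- colSums(as.matrix(junctionCounts))
  if (is.null(names(out))) names(out) <- paste0("sample_", seq_along(out))
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: each sample's factor is the median, over
#' features with all-positive counts, of the ratio of its count to the
#' featurewise geometric mean. Factors are rescaled to geometric mean 1, so
#' they are comparable across runs while preserving all between-sample
#' ratios.
#'
#' @param counts features x samples numeric matrix (non-negative).
#' @param pseudocount optional value added to every count before computing
#'   the factors (escape hatch when no feature is positive in all samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature with positive counts in all samples; ",
         "consider pseudocount > 0")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  s <- apply(sub / geo, 2, median)
  s <- s / exp(mean(log(s)))
  if (is.null(names(s))) names(s) <- colnames(counts)
  s
}

#' Library-total size factors
#'
#' Per-sample scaling by total aligned reads (column sums, rescaled to
#' geometric mean 1). In a non-depleted total-RNA RIP experiment the library
#' total is dominated by rRNA, which is not enriched by the pulldown, so
#' this normalization anchors fold enrichments at the unenriched
#' compartment: unbound features read out near 1x and bound features near
#' their true pulldown factor. Restricting `features` (e.g. to exon-aligned
#' features) reproduces the alternative exon-anchored scale.
#'
#' @param counts features x samples matrix.
#' @param features optional row subset (names, indices or logical) over
#'   which the totals are computed.
#' @return named positive numeric vector of size factors, geometric mean 1.
#' @export
librarySizeFactors <- function(counts, features = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  s <- colSums(counts)
  if (any(s <= 0)) stop("every sample needs a positive total count")
  s <- s / exp(mean(log(s)))
  if (is.null(names(s))) names(s) <- colnames(counts)
  s
}

#' Per-feature IP/input fold enrichment with test and FDR
#'
#' Normalises counts by size factors, computes the fold enrichment
#' \eqn{E = \mathrm{mean}_{IP}(c/s + p_0) / \mathrm{mean}_{input}(c/s + p_0)}
#' with pseudocount \eqn{p_0}, and attaches a two-sided per-feature p-value:
#' with a single sample per group, an exact binomial test of the IP count
#' against the IP share of the feature's total expected under equal
#' normalised abundance; with replicates in both groups, a rank-sum test of
#' the normalised counts. BH-adjusted FDR is appended.
#'
#' Normalization: `"library"` (default, [librarySizeFactors()] over all
#' rows, or over `normFeatures` for an exon-anchored scale) or
#' `"median_ratio"` ([medianRatioSizeFactors()]); alternatively pass
#' `sizeFactors` explicitly.
#'
#' @param counts features x samples matrix.
#' @param ipCols,inputCols column names or indices of the two groups.
#' @param sizeFactors optional named size factors; computed from `counts`
#'   when NULL.
#' @param normalization size-factor method when `sizeFactors` is NULL.
#' @param normFeatures optional row subset for `"library"` normalization.
#' @param pseudocount continuity pseudocount (default 0.5).
#' @param meta optional data.frame/DataFrame of feature metadata (e.g.
#'   `category`), cbound to the result.
#' @return data.frame: feature_id, normalized means, `E`, `log2E`, `p`,
#'   `fdr` (+ metadata columns).
#' @export
foldEnrichment <- function(counts, ipCols, inputCols, sizeFactors = NULL,
                           normalization = c("library", "median_ratio"),
                           normFeatures = NULL,
                           pseudocount = 0.5, meta = NULL) {
  counts <- as.matrix(counts)
  normalization <- match.arg(normalization)
  if (length(ipCols) == 0 || length(inputCols) == 0)
    stop("both IP and input sample groups must be declared")
  if (is.null(sizeFactors))
    sizeFactors <- switch(normalization,
      library = librarySizeFactors(counts, normFeatures),
      median_ratio = medianRatioSizeFactors(counts))
  # anchor at the input group: a c-fold rescaling of any one sample is then
  # absorbed exactly by its own factor, pseudocount included
  sf <- sizeFactors / mean(sizeFactors[inputCols])
  norm <- sweep(counts, 2, sf, "/")
  ipMean <- rowMeans(norm[, ipCols, drop = FALSE]) + pseudocount
  inMean <- rowMeans(norm[, inputCols, drop = FALSE]) + pseudocount
  E <- ipMean / inMean

  nIp <- length(ipCols)
  nIn <- length(inputCols)
  if (nIp >= 2 && nIn >= 2) {
    p <- apply(norm, 1, function(r)
      stats::wilcox.test(r[ipCols], r[inputCols], exact = FALSE,
                         correct = TRUE)$p.value)
  } else {
    xIp <- rowSums(counts[, ipCols, drop = FALSE])
    xIn <- rowSums(counts[, inputCols, drop = FALSE])
    p0 <- sum(sf[ipCols]) / (sum(sf[ipCols]) + sum(sf[inputCols]))
    tot <- xIp + xIn
    p <- vapply(seq_along(xIp), function(i) {
      if (tot[i] == 0) return(1)
      stats::binom.test(xIp[i], tot[i], p0)$p.value
    }, 0)
  }
  p[is.na(p)] <- 1
  out <- data.frame(
    feature_id = rownames(counts) %||% paste0("feature_", seq_len(nrow(counts))),
    ip_mean = ipMean - pseudocount, input_mean = inMean - pseudocount,
    E = E, log2E = log2(E), p = p, fdr = bhFDR(p),
    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(out, as.data.frame(meta))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enrichment summary of one feature category
#'
#' Median and quartiles of fold enrichment within the category, with a
#' two-sample two-sided rank-sum (Mann-Whitney) comparison against all other
#' features (exact for small samples without ties, normal approximation with
#' tie correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param records output of [foldEnrichment()] with a `category` column.
#' @param category the category to summarise.
#' @return list: n, median, q25, q75, W statistic, p.
#' @export
categorySummary <- function(records, category) {
  stopifnot("category" %in% names(records))
  inCat <- records$category == category
  if (!any(inCat)) stop("empty category: ", category)
  e <- records$E[inCat]
  rest <- records$E[!inCat]
  wt <- if (length(rest)) stats::wilcox.test(e, rest) else
    list(statistic = NA_real_, p.value = NA_real_)
  list(category = category, n = sum(inCat),
       median = median(e), q25 = unname(quantile(e, 0.25)),
       q75 = unname(quantile(e, 0.75)),
       W = unname(wt$statistic), p = wt$p.value)
}

#' Expressed-locus overlap between samples, within vs between families
#'
#' A locus is "expressed" in a sample when its EM expected count reaches
#' `floor`. Pairwise overlap is the Jaccard index as a percentage,
#' \eqn{100 |A \cap B| / |A \cup B|}; within-family overlaps are compared to
#' between-family overlaps with a one-sided Welch t-test (within greater).
#'
#' @param sets named list; either character vectors of expressed locus ids,
#'   or numeric vectors of per-locus expected counts (thresholded at
#'   `floor`).
#' @param withinPairs,betweenPairs two-column matrices (or lists of length-2
#'   vectors) of set names defining the two pair groups.
#' @param floor expression floor applied to numeric sets (default 1).
#' @return list: `overlap` (named percentage per requested pair), `within`,
#'   `between` (the two groups of values), `t`, `p` (Welch one-sided;
#'   NA with an explanatory `note` when a group has fewer than 2 values).
#' @export
locusSetOverlap <- function(sets, withinPairs, betweenPairs, floor = 1) {
  toSet <- function(x) {
    if (is.numeric(x)) names(x)[x >= floor] else as.character(x)
  }
  sets <- lapply(sets, toSet)
  if (any(lengths(sets) == 0)) stop("each expressed-locus set must be nonempty")
  jac <- function(a, b) 100 * length(intersect(a, b)) / length(union(a, b))
  pairMat <- function(p) if (is.list(p)) do.call(rbind, p) else as.matrix(p)
  wp <- pairMat(withinPairs)
  bp <- pairMat(betweenPairs)
  ov <- function(pm) apply(pm, 1, function(r) jac(sets[[r[1]]], sets[[r[2]]]))
  within <- stats::setNames(ov(wp), paste(wp[, 1], wp[, 2], sep = ":"))
  between <- stats::setNames(ov(bp), paste(bp[, 1], bp[, 2], sep = ":"))
  if (length(within) < 2 || length(between) < 2) {
    return(list(overlap = c(within, between), within = within,
                between = between, t = NA_real_, p = NA_real_,
                note = "t-test undefined: fewer than 2 overlap values in a group"))
  }
  tt <- tryCatch(stats::t.test(within, between, alternative = "greater",
                               var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(overlap = c(within, between), within = within,
                between = between, t = NA_real_, p = NA_real_,
                note = "t-test undefined: overlap values essentially constant"))
  list(overlap = c(within, between), within = within, between = between,
       t = unname(tt$statistic), p = tt$p.value, note = NULL)
}
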