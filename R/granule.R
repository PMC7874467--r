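#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j},
#' capped at 1, returned in input order. Input is validated to lie in
#' \[0, 1\].
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bhFDR <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(p, method = "BH")
}

#' FDR-gated 2x2 set overlap with odds ratio and exact test
#'
#' Cross-tabulates membership of two gene sets within a declared universe:
#' a = |A intersect B|, b = |A \\ B|, c = |B \\ A|, d = the rest. The odds
#' ratio is ad/bc, with the Haldane-Anscombe 0.5 correction (flagged) when
#' any cell is zero. The one-sided p-value (enrichment direction) is the
#' exact hypergeometric tail P(X >= a), computed in log space so it never
#' underflows to a printed zero; a two-sided alternative delegates to
#' [stats::fisher.test()].
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all considered genes.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return list: `table` (2x2 matrix), `oddsRatio`, `corrected` (Haldane
#'   flag), `p`, `logP` (natural log of `p`).
#' @export
overlapTest <- function(setA, setB, universe,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  cc <- length(setdiff(setB, setA))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(A = c("inA", "notA"), B = c("inB", "notB")))
  corrected <- any(tab == 0)
  orTab <- if (corrected) tab + 0.5 else tab
  oddsRatio <- (orTab[1, 1] * orTab[2, 2]) / (orTab[1, 2] * orTab[2, 1])
  if (alternative == "greater") {
    # hypergeometric upper tail P(X >= a): draws |A| from |B| successes
    logP <- stats::phyper(a - 1, length(setB), length(universe) - length(setB),
                          length(setA), lower.tail = FALSE, log.p = TRUE)
    p <- exp(logP)
  } else {
    p <- stats::fisher.test(tab)$p.value
    logP <- log(p)
  }
  list(table = tab, oddsRatio = unname(oddsRatio), corrected = corrected,
       p = p, logP = logP)
}

# n! permutations of 1..n as a matrix (n! x n); n <= 8 kept tractable.
.allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Tie-aware Spearman correlation with exact small-sample p
#'
#' rho is the Pearson correlation of midranks. The two-sided p-value uses
#' full permutation enumeration for n <= 8 (exact even under ties) and the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 df
#' otherwise.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `rho`, `p`, `n`, `method`; `rho` is NA with a `note` when
#'   either vector is constant.
#' @export
spearmanCor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined", note = "constant input vector"))
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .allPerms(n)
    rhoPerm <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Partial Spearman correlation controlling for a third variable
#'
#' First-order partial correlation on midranks,
#' \eqn{\rho_{xy\cdot z} = (\rho_{xy} - \rho_{xz}\rho_{yz}) /
#' \sqrt{(1-\rho_{xz}^2)(1-\rho_{yz}^2)}}, with a t-test on n-3 degrees of
#' freedom. Used to ask whether an x-y association survives once a shared
#' correlate z (e.g. p-body enrichment when comparing IP with stress-granule
#' enrichment) is accounted for.
#'
#' @param x,y,z paired numeric vectors, n >= 4.
#' @return list: `rho`, `p`, `n`; NA with a `note` when either marginal
#'   correlation with z is +-1 (the partial correlation is undefined).
#' @export
partialSpearmanCor <- function(x, y, z) {
  keep <- complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4) stop("need n >= 4 paired observations")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                note = "partial correlation undefined: |cor with z| = 1"))
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  rho <- max(min(rho, 1), -1)
  tstat <- rho * sqrt((n - 3) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 3)
  list(rho = rho, p = p, n = n)
}

#' Join IP enrichments with an external per-gene table and compare
#'
#' Inner-joins the [foldEnrichment()] table with an external enrichment
#' vector on gene id, then computes the Spearman correlation between the IP
#' log2 enrichment and the external values, the partial Spearman given a
#' second external vector, and the FDR-gated 2x2 overlap (IP-enriched =
#' `fdr < fdrGate` and `E > 1`; externally enriched = value above
#' `externalCut`, 0 for log-scale tables, 1 for fold-scale). The 2x2
#' universe is the joined gene set.
#'
#' @param enrichment [foldEnrichment()] output (`feature_id`, `E`, `log2E`,
#'   `fdr`).
#' @param external data.frame/DataFrame with `gene_id` and `value`.
#' @param external2 optional second external table (for the partial
#'   correlation and to mirror its confounding).
#' @param fdrGate BH FDR cutoff for "IP-enriched" (default 0.05).
#' @param externalScale "log" (enriched when value > 0, default) or "fold"
#'   (enriched when value > 1).
#' @param minJoin minimum join size (default 10).
#' @return A [GranuleComparison-class].
#' @export
joinAndCompare <- function(enrichment, external, external2 = NULL,
                           fdrGate = 0.05,
                           externalScale = c("log", "fold"),
                           minJoin = 10L) {
  externalScale <- match.arg(externalScale)
  enrichment <- as.data.frame(enrichment)
  external <- as.data.frame(external)
  ids <- intersect(enrichment$feature_id, external$gene_id)
  if (length(ids) < minJoin)
    stop(sprintf(paste0(
      "join too small (%d genes, need >= %d); enrichment ids look like [%s], ",
      "external ids look like [%s]"),
      length(ids), minJoin,
      paste(utils::head(enrichment$feature_id, 3), collapse = ", "),
      paste(utils::head(external$gene_id, 3), collapse = ", ")))
  discarded <- (nrow(enrichment) - length(ids)) + (nrow(external) - length(ids))
  e <- enrichment[match(ids, enrichment$feature_id), , drop = FALSE]
  x <- external$value[match(ids, external$gene_id)]
  joined <- S4Vectors::DataFrame(gene_id = ids, log2E = e$log2E, fdr = e$fdr,
                                 external = x)
  sp <- spearmanCor(e$log2E, x)
  pr <- list(rho = NA_real_, p = NA_real_)
  if (!is.null(external2)) {
    external2 <- as.data.frame(external2)
    x2 <- external2$value[match(ids, external2$gene_id)]
    joined$external2 <- x2
    ok <- complete.cases(e$log2E, x, x2)
    if (sum(ok) >= minJoin) pr <- partialSpearmanCor(e$log2E[ok], x[ok], x2[ok])
  }
  cut <- if (externalScale == "log") 0 else 1
  setA <- ids[e$fdr < fdrGate & e$E > 1]
  setB <- ids[!is.na(x) & x > cut]
  ot <- overlapTest(setA, setB, ids)
  new("GranuleComparison",
      n = length(ids), discarded = as.integer(discarded),
      rho = sp$rho, rhoP = sp$p,
      partialRho = pr$rho, partialP = pr$p,
      table = ot$table, oddsRatio = ot$oddsRatio,
      orCorrected = ot$corrected, exactP = ot$p, exactLogP = ot$logP,
      joined = joined)
}
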