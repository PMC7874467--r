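#' Construct a CompatibilityMatrix from a weight matrix
#'
#' Low-level constructor: coerces any matrix-like object to the sparse
#' general column-compressed form and attaches identifiers.
#'
#' @param weights reads x loci matrix of non-negative alignment weights.
#' @param readIds,locusIds identifiers; defaulted from dimnames.
#' @param dropped count of reads excluded upstream.
#' @param errorRate per-base error rate the weights were computed with.
#' @return A [CompatibilityMatrix-class].
#' @export
compatibilityMatrix <- function(weights, readIds = rownames(weights),
                                locusIds = colnames(weights), dropped = 0L,
                                errorRate = NA_real_) {
  w <- methods::as(methods::as(methods::as(
    Matrix::Matrix(weights, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  if (is.null(readIds)) readIds <- sprintf("read_%d", seq_len(nrow(w)))
  if (is.null(locusIds)) locusIds <- sprintf("locus_%d", seq_len(ncol(w)))
  dimnames(w) <- list(if (nrow(w)) readIds else NULL,
                      if (ncol(w)) locusIds else NULL)
  new("CompatibilityMatrix", weights = w, readIds = readIds,
      locusIds = locusIds, dropped = as.integer(dropped),
      errorRate = errorRate)
}

#' Build the read-by-locus compatibility matrix
#'
#' Converts reported multi-hit alignments into the sparse weight matrix the
#' EM consumes: for fragment i with \eqn{m_{ij}} mismatches over \eqn{L}
#' aligned bases on locus j, \eqn{w_{ij} = \epsilon^{m_{ij}}
#' (1-\epsilon)^{L - m_{ij}}} with \eqn{\epsilon} the per-base error rate.
#' Accepts either the hit table produced by [emulateAlignment()] or a path
#' to a multi-hit SAM file (read back through Rsamtools; mismatches from the
#' `NM` tag, mates summed per fragment). Hits on contigs outside `locusIds`
#' are ignored; fragments left with no locus hit are dropped and counted.
#'
#' @param x hit table ([S4Vectors::DataFrame] / data.frame with columns
#'   read_id, feature_id, and either `m` or `m1`+`m2`) or a SAM file path.
#' @param locusIds character vector of LINE-1 locus identifiers (columns).
#' @param errorRate per-base error rate \eqn{\epsilon}.
#' @param readLength mate length in bp; aligned length is `2 * readLength`.
#' @param library optional filter on the `library` column (`"input"`/`"IP"`).
#' @return A [CompatibilityMatrix-class].
#' @export
buildCompatibility <- function(x, locusIds, errorRate, readLength,
                               library = NULL) {
  if (is.character(x) && length(x) == 1) {
    x <- readSamHits(x)
  } else {
    x <- as.data.frame(x)
  }
  if (!is.null(library) && "library" %in% names(x))
    x <- x[x$library == library, , drop = FALSE]
  if (!"m" %in% names(x)) {
    if (!all(c("m1", "m2") %in% names(x)))
      stop("hit table lacks mismatch information (need 'm' or 'm1'+'m2')")
    x$m <- x$m1 + x$m2
  }
  if (anyNA(x$m))
    stop("missing mismatch count for read(s): ",
         paste(utils::head(x$read_id[is.na(x$m)], 3), collapse = ", "))
  allReads <- unique(x$read_id)
  x <- x[x$feature_id %in% locusIds, , drop = FALSE]
  dropped <- length(allReads) - length(unique(x$read_id))
  if (!nrow(x)) {
    return(new("CompatibilityMatrix",
               weights = methods::as(Matrix::Matrix(0, 0, length(locusIds),
                                                    sparse = TRUE), "CsparseMatrix"),
               readIds = character(), locusIds = locusIds,
               dropped = as.integer(dropped), errorRate = errorRate))
  }
  rid <- sort(unique(x$read_id))
  i <- match(x$read_id, rid)
  j <- match(x$feature_id, locusIds)
  Ltot <- 2L * readLength
  w <- if (errorRate == 0) as.numeric(x$m == 0) else
    errorRate^x$m * (1 - errorRate)^(Ltot - x$m)
  keep <- w > 0
  W <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                            dims = c(length(rid), length(locusIds)),
                            dimnames = list(rid, locusIds))
  # rows that lost all entries (all weights zero) are dropped too
  rs <- Matrix::rowSums(W > 0)
  if (any(rs == 0)) {
    dropped <- dropped + sum(rs == 0)
    W <- W[rs > 0, , drop = FALSE]
    rid <- rid[rs > 0]
  }
  new("CompatibilityMatrix",
      weights = methods::as(W, "CsparseMatrix"), readIds = rid,
      locusIds = locusIds, dropped = as.integer(dropped),
      errorRate = errorRate)
}

#' Maximum-likelihood locus abundances by expectation-maximization
#'
#' Fits the multinomial mixture \eqn{P(\mathrm{read}\ i) = \sum_j \theta_j
#' w_{ij}} over LINE-1 loci by EM from a uniform start: E-step
#' responsibilities \eqn{r_{ij} = \theta_j w_{ij} / \sum_k \theta_k w_{ik}},
#' M-step \eqn{\theta_j = \sum_i r_{ij} / n}. The likelihood is concave in
#' \eqn{\theta} for fixed weights, so the uniform start affects only ties
#' (indistinguishable loci split evenly by symmetry). Iteration stops when
#' the relative log-likelihood change drops below `tol` or at `maxIter`
#' (flagged unconverged).
#'
#' @param C a [CompatibilityMatrix-class].
#' @param tol relative log-likelihood change for convergence.
#' @param maxIter iteration cap.
#' @return An [AbundanceEstimate-class] (theta, expected counts,
#'   log-likelihood trace, iterations, convergence flag).
#' @examples
#' W <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 4), j = c(1, 1, 2, 1, 2),
#'                           x = 1, dims = c(4, 2))
#' C <- new("CompatibilityMatrix", weights = methods::as(W, "CsparseMatrix"),
#'          readIds = paste0("r", 1:4), locusIds = c("A", "B"),
#'          dropped = 0L, errorRate = 0.01)
#' theta(emQuantify(C))  # MLE: 2/3, 1/3
#' @export
emQuantify <- function(C, tol = 1e-8, maxIter = 1000L) {
  W <- C@weights
  n <- nrow(W)
  K <- ncol(W)
  if (n == 0 || K == 0) stop("empty compatibility matrix")
  th <- rep(1 / K, K)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  resp <- NULL
  emStep <- function(t0) {
    num <- W %*% Matrix::Diagonal(x = t0)
    s <- Matrix::rowSums(num)
    Matrix::colSums(Matrix::Diagonal(x = 1 / s) %*% num) / n
  }
  logLik <- function(t0) sum(log(as.numeric(W %*% t0)))
  while (it < maxIter) {
    it <- it + 1L
    num <- W %*% Matrix::Diagonal(x = th)      # theta_j * w_ij
    s <- Matrix::rowSums(num)                  # sum_k theta_k w_ik
    ll <- sum(log(s))
    trace <- c(trace, ll)
    resp <- Matrix::Diagonal(x = 1 / s) %*% num
    th <- Matrix::colSums(resp) / n
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  # Aitken delta-squared polish: components decaying geometrically toward a
  # simplex boundary converge slowly under plain EM; the extrapolated limit
  # is exact for geometric sequences and is accepted only if it does not
  # decrease the likelihood.
  a <- as.numeric(th); b <- as.numeric(emStep(a)); cc <- as.numeric(emStep(b))
  d1 <- b - a; d2 <- cc - b
  den <- d2 - d1
  acc <- ifelse(abs(den) > .Machine$double.eps, cc - d2^2 / den, cc)
  acc[!is.finite(acc) | acc < 0] <- 0
  if (sum(acc) > 0) {
    acc <- acc / sum(acc)
    if (logLik(acc) >= logLik(cc) - 1e-12) th <- acc else th <- cc
  } else th <- cc
  llFinal <- logLik(as.numeric(th))
  if (llFinal >= trace[length(trace)]) trace <- c(trace, llFinal)
  # expected counts re-evaluated at the reported theta
  num <- W %*% Matrix::Diagonal(x = as.numeric(th))
  s <- Matrix::rowSums(num)
  counts <- Matrix::colSums(Matrix::Diagonal(x = 1 / s) %*% num)
  th <- as.numeric(th)
  names(th) <- names(counts) <- C@locusIds
  new("AbundanceEstimate",
      theta = as.numeric(th) |> stats::setNames(C@locusIds),
      counts = as.numeric(counts) |> stats::setNames(C@locusIds),
      logLik = trace, iterations = it, converged = converged,
      nReads = as.integer(n))
}

#' Dense simplex grid search for the mixture MLE (small instances)
#'
#' Independent oracle for [emQuantify()]: enumerates \eqn{\theta} on the
#' probability simplex with the given step (K at most 3) and returns the
#' grid point maximising the observed-data log-likelihood
#' \eqn{\sum_i \log \sum_j \theta_j w_{ij}}. With `refine = TRUE` (default)
#' the search then re-grids locally around the coarse maximum at
#' successively finer steps: a step-0.001 simplex grid alone can misplace
#' the dependent component of a 3-locus instance by up to two steps, so the
#' refinement is what makes the oracle itself accurate to ~1e-5.
#'
#' @param W dense or sparse weight matrix, at most 3 columns.
#' @param step coarse grid step on each component.
#' @param refine local refinement rounds (each shrinks the step tenfold).
#' @return list with `theta` (the maximising grid point) and `logLik`.
#' @export
gridSearchMLE <- function(W, step = 0.001, refine = 2L) {
  W <- as.matrix(W)
  K <- ncol(W)
  stopifnot(K >= 1, K <= 3)
  if (K == 1) return(list(theta = 1, logLik = sum(log(W[, 1]))))
  evalGrid <- function(ga, gb = NULL) {
    if (K == 2) {
      TH <- cbind(ga, 1 - ga)
    } else {
      TH <- as.matrix(expand.grid(a = ga, b = gb))
      TH <- TH[rowSums(TH) <= 1 + 1e-12, , drop = FALSE]
      TH <- cbind(TH, 1 - rowSums(TH))
    }
    TH <- TH[apply(TH, 1, min) >= -1e-12, , drop = FALSE]
    S <- TH %*% t(W)     # (grid x reads)
    ll <- rowSums(log(S))
    best <- which.max(ll)
    list(theta = as.numeric(TH[best, ]), logLik = ll[best])
  }
  clampSeq <- function(center, halfwidth, by) {
    s <- seq(max(0, center - halfwidth), min(1, center + halfwidth), by = by)
    unique(pmin(pmax(s, 0), 1))
  }
  res <- evalGrid(seq(0, 1, by = step),
                  if (K == 3) seq(0, 1, by = step))
  h <- step
  for (r in seq_len(refine)) {
    fine <- h / 10
    res2 <- evalGrid(clampSeq(res$theta[1], 2 * h, fine),
                     if (K == 3) clampSeq(res$theta[2], 2 * h, fine))
    if (res2$logLik >= res$logLik) res <- res2
    h <- fine
  }
  res
}

#' Aggregate EM abundances by intactness class
#'
#' Sums the estimated per-locus relative abundances and expected counts over
#' the loci of each intactness class; "intact LINE-1" expression is then the
#' FULLY_INTACT total and "intact ORF1" expression the FULLY_INTACT +
#' ORF1_INTACT_ORF2_TRUNC total. Totals over the three classes conserve the
#' grand total by construction.
#'
#' @param estimate an [AbundanceEstimate-class].
#' @param calls data.frame / DataFrame with columns `locus_id` and `class`
#'   (or `class_true`), covering every locus in the estimate.
#' @return data.frame with one row per class: summed theta and counts, plus
#'   the two cumulative intact totals as attributes `intact_l1`
#'   (FULLY_INTACT) and `intact_orf1` (FULLY_INTACT + ORF1-intact).
#' @export
aggregateByClass <- function(estimate, calls) {
  calls <- as.data.frame(calls)
  cl <- if ("class" %in% names(calls)) calls$class else calls$class_true
  idx <- match(names(estimate@theta), calls$locus_id)
  if (anyNA(idx))
    stop("no intactness call for locus: ",
         paste(utils::head(names(estimate@theta)[is.na(idx)], 3), collapse = ", "))
  cl <- factor(cl[idx], levels = .INTACT_CLASSES)
  out <- data.frame(
    class = .INTACT_CLASSES,
    theta = as.numeric(tapply(estimate@theta, cl, sum, default = 0)),
    counts = as.numeric(tapply(estimate@counts, cl, sum, default = 0)))
  attr(out, "intact_l1") <- out$theta[out$class == "FULLY_INTACT"]
  attr(out, "intact_orf1") <- sum(out$theta[out$class != "ORF1_TRUNC"])
  out
}
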