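#' @importFrom stats rlnorm rnorm runif rbinom rmultinom median quantile
#'   complete.cases setNames
NULL

.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Derive a per-stage seed from the master seed; keeps every value < 2^31.
deriveSeed <- function(seed, stage) {
  (as.numeric(seed) * 10007 + stage * 7919) %% 2147483629
}

# Random DNA as a character vector of single bases.
randomBases <- function(n) sample(.BASES, n, replace = TRUE)

# Random coding sequence for `naa` amino acids: ATG start, no internal stop,
# terminal stop codon. Returns character vector of bases, length 3*(naa+1).
randomCds <- function(naa) {
  codons <- character(naa)
  codons[1] <- "ATG"
  i <- 2L
  while (i <= naa) {
    cod <- paste(sample(.BASES, 3, replace = TRUE), collapse = "")
    if (!cod %in% .STOP_CODONS) {
      codons[i] <- cod
      i <- i + 1L
    }
  }
  unlist(strsplit(c(codons, sample(.STOP_CODONS, 1)), ""))
}

# 0-based half-open (BED) <-> 1-based inclusive (GTF/SAM) conversions.
# All internal coordinates are 1-based inclusive (GRanges convention);
# rtracklayer performs the BED shift on import/export, these helpers cover
# hand-built records (SAM POS and the simulator truth tables).
zeroBasedStart <- function(start1) start1 - 1L
oneBasedStart <- function(start0) start0 + 1L

# Substitute bases at `pos` in a base vector with a different random base.
substituteBases <- function(bases, pos) {
  if (!length(pos)) return(bases)
  cur <- bases[pos]
  repl <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1), "")
  bases[pos] <- repl
  bases
}

# Truncated-normal fragment lengths (lower bound = read length).
sampleFragmentLengths <- function(n, mean, sd, minLen, maxLen) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < minLen | out > maxLen)
  guard <- 0L
  while (length(bad) && guard < 50L) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- which(out < minLen | out > maxLen)
    guard <- guard + 1L
  }
  out[out < minLen] <- minLen
  out[out > maxLen] <- maxLen
  as.integer(out)
}

# Write a data.frame / DataFrame as TSV (deterministic, no quoting).
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Computes the fold change \eqn{2^{-\Delta\Delta C_t}} with
#' \eqn{\Delta\Delta C_t = (C_t^{target} - C_t^{ref})_{treated} -
#' (C_t^{target} - C_t^{ref})_{control}}, the standard relative
#' quantification against an internal reference gene (e.g. RPL19).
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl cycle
#'   threshold values (positive reals; vectorised).
#' @return Numeric fold change(s); 1 means no change, values below 1 indicate
#'   reduced expression in the treated condition.
#' @examples
#' ddct(22, 20, 24, 20)  # 4-fold up
#' ddct(24, 20, 22, 20)  # 4-fold down (0.25)
#' @export
ddct <- function(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl) {
  stopifnot(all(ctTargetTreated > 0), all(ctRefTreated > 0),
            all(ctTargetControl > 0), all(ctRefControl > 0))
  ddc <- (ctTargetTreated - ctRefTreated) - (ctTargetControl - ctRefControl)
  2^(-ddc)
}
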