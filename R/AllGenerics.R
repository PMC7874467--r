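#' Accessors for l1ripseq objects
#'
#' Small accessor layer over the S4 classes: `theta()` and `expectedCounts()`
#' read an [AbundanceEstimate-class]; `logLikTrace()` its likelihood trace;
#' `isConverged()` its convergence flag; `compatWeights()`, `readIds()` and
#' `locusIds()` read a [CompatibilityMatrix-class]; `simGenome()`, `simLoci()`
#' and `simGenes()` read an [L1Simulation-class].
#'
#' @param object an l1ripseq S4 object.
#' @return The slot value (copies, never references into the object).
#' @name accessors
#' @aliases theta expectedCounts logLikTrace isConverged compatWeights
#'   readIds locusIds simGenome simLoci simGenes
NULL

#' @rdname accessors
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("expectedCounts", function(object) standardGeneric("expectedCounts"))
#' @rdname accessors
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("compatWeights", function(object) standardGeneric("compatWeights"))
#' @rdname accessors
#' @export
setGeneric("readIds", function(object) standardGeneric("readIds"))
#' @rdname accessors
#' @export
setGeneric("locusIds", function(object) standardGeneric("locusIds"))
#' @rdname accessors
#' @export
setGeneric("simGenome", function(object) standardGeneric("simGenome"))
#' @rdname accessors
#' @export
setGeneric("simLoci", function(object) standardGeneric("simLoci"))
#' @rdname accessors
#' @export
setGeneric("simGenes", function(object) standardGeneric("simGenes"))

#' @rdname accessors
setMethod("theta", "AbundanceEstimate", function(object) object@theta)
#' @rdname accessors
setMethod("expectedCounts", "AbundanceEstimate", function(object) object@counts)
#' @rdname accessors
setMethod("logLikTrace", "AbundanceEstimate", function(object) object@logLik)
#' @rdname accessors
setMethod("isConverged", "AbundanceEstimate", function(object) object@converged)
#' @rdname accessors
setMethod("compatWeights", "CompatibilityMatrix", function(object) object@weights)
#' @rdname accessors
setMethod("readIds", "CompatibilityMatrix", function(object) object@readIds)
#' @rdname accessors
setMethod("locusIds", "CompatibilityMatrix", function(object) object@locusIds)
#' @rdname accessors
setMethod("simGenome", "L1Simulation", function(object) object@genome)
#' @rdname accessors
setMethod("simLoci", "L1Simulation", function(object) object@loci)
#' @rdname accessors
setMethod("simGenes", "L1Simulation", function(object) object@genes)

setMethod("show", "L1SimConfig", function(object) {
  cat("L1SimConfig:", object@nL1Loci, "LINE-1 loci of", object@l1Length, "bp,",
      "divergence", object@divergenceRate, "\n")
  cat("  class mix:", paste(sprintf("%s=%.2f", names(object@classProportions),
                                    object@classProportions), collapse = " "), "\n")
  cat("  host genes:", paste(sprintf("%s=%d", names(object@hostCategories),
                                     object@hostCategories), collapse = " "), "\n")
  cat("  libraries:", object@nReadsInput, "input /", object@nReadsIP, "IP fragments,",
      "2 x", object@readLength, "bp, error", object@errorRate, "\n")
})

setMethod("show", "L1Simulation", function(object) {
  cat("L1Simulation:", length(object@genome), "contigs;",
      length(object@loci), "LINE-1 loci;", length(object@genes), "host genes\n")
  cat("  engineered classes:",
      paste(names(table(object@truth$class_true)),
            table(object@truth$class_true), collapse = " ", sep = "="), "\n")
})

setMethod("show", "L1ReadSet", function(object) {
  tab <- table(object@fragments$library)
  cat("L1ReadSet:", nrow(object@fragments), "fragments (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), 2 x",
      object@readLength, "bp\n")
})

setMethod("show", "CompatibilityMatrix", function(object) {
  cat("CompatibilityMatrix:", nrow(object@weights), "fragments x",
      ncol(object@weights), "loci;",
      length(object@weights@x), "nonzero weights;",
      object@dropped, "fragments dropped\n")
})

setMethod("show", "AbundanceEstimate", function(object) {
  cat("AbundanceEstimate over", length(object@theta), "loci from",
      object@nReads, "fragments\n")
  cat("  EM:", object@iterations, "iterations,",
      if (object@converged) "converged," else "NOT converged,",
      "logL =", format(utils::tail(object@logLik, 1), digits = 10), "\n")
})

setMethod("show", "GranuleComparison", function(object) {
  cat("GranuleComparison over", object@n, "joined genes (", object@discarded,
      "discarded )\n")
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", object@rho, object@rhoP))
  if (!is.na(object@partialRho))
    cat(sprintf("  partial Spearman rho = %.3f (p = %.3g)\n",
                object@partialRho, object@partialP))
  cat(sprintf("  overlap OR = %.3g%s, exact p = %.3g (log p = %.2f)\n",
              object@oddsRatio,
              if (object@orCorrected) " (Haldane-corrected)" else "",
              object@exactP, object@exactLogP))
})
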