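#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom Biostrings DNAStringSet DNAString AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Simulation configuration for the toy RIP-seq experiment
#'
#' Holds every tunable of the synthetic-data generator: the LINE-1 panel
#' (number of loci, element length, inter-locus divergence, intactness-class
#' mix), the host-gene panel (counts per RNA category), the sequencing model
#' (read/fragment lengths, library sizes, per-base error rate) and the
#' pulldown model (per-category log-normal IP enrichment parameters).
#'
#' Construct with [simConfig()], which supplies defaults; the validity method
#' enforces the invariants (class proportions sum to 1, non-negative counts,
#' divergence in \[0, 0.25\], element long enough to hold both ORFs).
#'
#' @slot seed integer master seed.
#' @slot nL1Loci number of LINE-1 loci.
#' @slot l1Length element length in bp.
#' @slot orf1Aa,orf2Aa lengths (amino acids, excluding the stop) of the two
#'   consensus ORFs embedded in the element.
#' @slot divergenceRate substitutions per site applied independently to each
#'   locus relative to the shared consensus.
#' @slot classProportions named numeric of length 3: fractions of loci that
#'   are \code{FULLY_INTACT}, \code{ORF1_INTACT_ORF2_TRUNC}, \code{ORF1_TRUNC}.
#' @slot hostCategories named integer: gene counts per category
#'   (\code{mRNA}, \code{histone}, \code{MT}, \code{rRNA}, \code{lncRNA},
#'   \code{circRNA_host}).
#' @slot geneLength host gene length in bp.
#' @slot l1Fraction fraction of input-library expression allotted to the
#'   LINE-1 compartment (1 when there are no host genes).
#' @slot readLength,fragmentMean,fragmentSd sequencing geometry in bp.
#' @slot nReadsInput,nReadsIP fragments per library.
#' @slot enrichmentModel named list; per category a list with \code{meanlog}
#'   and \code{sdlog} of the log-normal true IP enrichment (sdlog 0 fixes the
#'   enrichment at exp(meanlog)).
#' @slot errorRate per-base sequencing error probability.
#' @slot minusStrand logical; allow loci on the minus strand.
#' @slot stranded logical; record library strandedness (unstranded default).
#'
#' @aliases L1SimConfig-class
#' @exportClass L1SimConfig
setClass("L1SimConfig",
  representation(
    seed = "integer",
    nL1Loci = "integer",
    l1Length = "integer",
    orf1Aa = "integer",
    orf2Aa = "integer",
    divergenceRate = "numeric",
    classProportions = "numeric",
    hostCategories = "integer",
    geneLength = "integer",
    l1Fraction = "numeric",
    readLength = "integer",
    fragmentMean = "numeric",
    fragmentSd = "numeric",
    nReadsInput = "integer",
    nReadsIP = "integer",
    enrichmentModel = "list",
    errorRate = "numeric",
    minusStrand = "logical",
    stranded = "logical"
  )
)

.INTACT_CLASSES <- c("FULLY_INTACT", "ORF1_INTACT_ORF2_TRUNC", "ORF1_TRUNC")
.HOST_CATEGORIES <- c("mRNA", "histone", "MT", "rRNA", "lncRNA", "circRNA_host")

setValidity("L1SimConfig", function(object) {
  msg <- character()
  if (abs(sum(object@classProportions) - 1) > 1e-8)
    msg <- c(msg, "classProportions must sum to 1")
  if (!identical(names(object@classProportions), .INTACT_CLASSES))
    msg <- c(msg, sprintf("classProportions must be named %s",
                          paste(.INTACT_CLASSES, collapse = ", ")))
  if (any(object@classProportions < 0)) msg <- c(msg, "classProportions must be >= 0")
  if (object@divergenceRate < 0 || object@divergenceRate > 0.25)
    msg <- c(msg, "divergenceRate must lie in [0, 0.25]")
  if (!identical(names(object@hostCategories), .HOST_CATEGORIES))
    msg <- c(msg, sprintf("hostCategories must be named %s",
                          paste(.HOST_CATEGORIES, collapse = ", ")))
  if (any(object@hostCategories < 0) || object@nL1Loci < 0 ||
      object@nReadsInput < 0 || object@nReadsIP < 0)
    msg <- c(msg, "all counts must be >= 0")
  # 5'UTR + ORF1 + inter-ORF spacer + ORF2 + minimal 3'UTR must fit
  needed <- 60L + 3L * (object@orf1Aa + 1L) + 30L + 3L * (object@orf2Aa + 1L) + 30L
  if (object@l1Length < needed)
    msg <- c(msg, sprintf("l1Length (%d) too short to contain both ORFs (need >= %d)",
                          object@l1Length, needed))
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0, 1)")
  if (object@l1Fraction < 0 || object@l1Fraction > 1)
    msg <- c(msg, "l1Fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A simulated toy genome with LINE-1 loci and host genes
#'
#' Returned by [simulateGenome()]. One contig per LINE-1 locus and per host
#' gene; LINE-1 loci are substitution-mutated copies of a shared consensus
#' element, with engineered premature stop codons defining the intactness
#' classes. The engineered truth (class and stop position per locus) is kept
#' alongside the annotations.
#'
#' @slot genome [Biostrings::DNAStringSet] of contigs.
#' @slot loci [GenomicRanges::GRanges] of LINE-1 loci (mcols: \code{locus_id},
#'   \code{class_true}).
#' @slot genes [GenomicRanges::GRanges] of host genes (mcols: \code{gene_id},
#'   \code{category}, \code{polyA}, \code{circ_junction}).
#' @slot consensus [Biostrings::DNAString]-like consensus element sequence.
#' @slot consensusProteins [Biostrings::AAStringSet] with entries ORF1, ORF2.
#' @slot orfRanges [IRanges::IRanges] of ORF1/ORF2 within the element.
#' @slot truth [S4Vectors::DataFrame]: per-locus engineered class and stop
#'   codon index (NA when none).
#' @slot config the [L1SimConfig-class] used.
#'
#' @aliases L1Simulation-class
#' @exportClass L1Simulation
setClass("L1Simulation",
  representation(
    genome = "DNAStringSet",
    loci = "GRanges",
    genes = "GRanges",
    consensus = "DNAString",
    consensusProteins = "AAStringSet",
    orfRanges = "IRanges",
    truth = "DataFrame",
    config = "L1SimConfig"
  )
)

#' Simulated paired input/IP read libraries with per-read truth
#'
#' Returned by [simulateReads()]. Fragments are paired-end; the per-read
#' origin table records, for every fragment, its library, true source
#' feature, fragment coordinates within that feature, sequencing-error
#' positions, and whether it spans a circRNA back-splice junction. The
#' feature-level truth (input relative abundance and true IP enrichment
#' factor per feature) is stored in \code{featureTruth}.
#'
#' @slot fragments [S4Vectors::DataFrame], one row per fragment.
#' @slot mate1,mate2 [Biostrings::DNAStringSet] read sequences.
#' @slot featureTruth [S4Vectors::DataFrame]: feature_id, type, true input
#'   abundance, true IP enrichment factor.
#' @slot readLength integer.
#' @slot errorRate numeric.
#'
#' @aliases L1ReadSet-class
#' @exportClass L1ReadSet
setClass("L1ReadSet",
  representation(
    fragments = "DataFrame",
    mate1 = "DNAStringSet",
    mate2 = "DNAStringSet",
    featureTruth = "DataFrame",
    readLength = "integer",
    errorRate = "numeric"
  )
)

#' Sparse read-by-locus alignment-compatibility weights
#'
#' Rows are retained fragments, columns LINE-1 loci; entry \eqn{w_{ij} =
#' \epsilon^{m}(1-\epsilon)^{L-m}} is the alignment likelihood of fragment i
#' under locus j with m mismatches over L aligned bases. Fragments with no
#' locus hit are excluded and counted in \code{dropped}. This is the sole
#' input of [emQuantify()].
#'
#' @slot weights sparse \code{dgCMatrix} (fragments x loci).
#' @slot readIds,locusIds character identifiers for rows/columns.
#' @slot dropped integer: fragments with no compatible locus.
#' @slot errorRate the \eqn{\epsilon} used for the weights.
#'
#' @aliases CompatibilityMatrix-class
#' @exportClass CompatibilityMatrix
setClass("CompatibilityMatrix",
  representation(
    weights = "dgCMatrix",
    readIds = "character",
    locusIds = "character",
    dropped = "integer",
    errorRate = "numeric"
  )
)

setValidity("CompatibilityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != length(object@readIds)) msg <- c(msg, "readIds length != nrow(weights)")
  if (ncol(w) != length(object@locusIds)) msg <- c(msg, "locusIds length != ncol(weights)")
  if (any(!is.finite(w@x)) || any(w@x < 0)) msg <- c(msg, "weights must be finite and >= 0")
  if (nrow(w) > 0 && any(Matrix::rowSums(w > 0) == 0))
    msg <- c(msg, "every retained read must have at least one positive weight")
  if (length(msg)) msg else TRUE
})

#' Per-locus abundance estimate from the EM
#'
#' Returned by [emQuantify()]. \code{theta} is the maximum-likelihood
#' relative abundance over loci (sums to 1); \code{counts} the expected
#' fragment counts \eqn{n_j = \sum_i r_{ij}} (sums to the number of retained
#' fragments); the log-likelihood trace is non-decreasing by construction of
#' the EM.
#'
#' @slot theta named numeric, per-locus relative abundance.
#' @slot counts named numeric, per-locus expected fragment counts.
#' @slot logLik numeric log-likelihood trace (one value per iteration).
#' @slot iterations integer.
#' @slot converged logical.
#' @slot nReads integer, retained fragments.
#'
#' @aliases AbundanceEstimate-class
#' @exportClass AbundanceEstimate
setClass("AbundanceEstimate",
  representation(
    theta = "numeric",
    counts = "numeric",
    logLik = "numeric",
    iterations = "integer",
    converged = "logical",
    nReads = "integer"
  )
)

setValidity("AbundanceEstimate", function(object) {
  msg <- character()
  if (abs(sum(object@theta) - 1) > 1e-6) msg <- c(msg, "theta must sum to 1")
  if (any(object@theta < -1e-12)) msg <- c(msg, "theta must be >= 0")
  if (object@nReads > 0 && abs(sum(object@counts) - object@nReads) > 1e-6 * max(1, object@nReads))
    msg <- c(msg, "expected counts must sum to the number of retained reads")
  if (length(object@logLik) > 1 &&
      any(diff(object@logLik) < -1e-8 * pmax(1, abs(object@logLik[-1]))))
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Comparison of IP enrichments with an external per-gene dataset
#'
#' Returned by [joinAndCompare()]. Holds the join size, Spearman (and, when a
#' second external vector is supplied, partial Spearman) correlation between
#' the IP log-enrichments and the external values, and the FDR-gated 2x2
#' overlap table with its odds ratio and one-sided exact hypergeometric p.
#'
#' @slot n integer, genes in the inner join.
#' @slot discarded integer, genes dropped by the join.
#' @slot rho,rhoP Spearman correlation and p-value.
#' @slot partialRho,partialP partial Spearman given the second external
#'   vector (NA when not requested).
#' @slot table 2x2 integer matrix (IP-enriched x external-enriched).
#' @slot oddsRatio numeric; Haldane-corrected when a cell is zero.
#' @slot orCorrected logical flag for the Haldane correction.
#' @slot exactP,exactLogP one-sided exact test p and its natural log.
#' @slot joined [S4Vectors::DataFrame] scatter-ready joined table.
#'
#' @aliases GranuleComparison-class
#' @exportClass GranuleComparison
setClass("GranuleComparison",
  representation(
    n = "integer",
    discarded = "integer",
    rho = "numeric",
    rhoP = "numeric",
    partialRho = "numeric",
    partialP = "numeric",
    table = "matrix",
    oddsRatio = "numeric",
    orCorrected = "logical",
    exactP = "numeric",
    exactLogP = "numeric",
    joined = "DataFrame"
  )
)
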