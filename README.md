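# l1ripseq

Locus-resolved analysis of LINE-1 ORF1p RIP-seq experiments in R.

LINE-1 (L1) is the only autonomous human retrotransposon; its ORF1p protein
coats LINE-1 mRNA as homotrimers and is the bait in RNA
immunoprecipitation sequencing (RIP-seq) experiments that ask *which* of the
genome's near-identical LINE-1 copies are transcribed, and which host RNAs
ORF1p binds besides its own. Two obstacles dominate this analysis, and this
package implements tested solutions to both plus everything around them:

- **Multi-mapping reads.** Reads from one LINE-1 locus align almost equally
  well to many near-identical copies. `emQuantify()` resolves fragments to
  individual loci by maximum likelihood under the multinomial mixture
  $P(i) = \sum_j \theta_j w_{ij}$, where
  $w_{ij} = \varepsilon^{m_{ij}}(1-\varepsilon)^{L-m_{ij}}$ is the alignment
  likelihood of fragment $i$ under locus $j$ ($m_{ij}$ mismatches over $L$
  aligned bases at per-base error rate $\varepsilon$), via EM:
  $r_{ij} = \theta_j w_{ij}/\sum_k \theta_k w_{ik}$, then
  $\theta_j = \sum_i r_{ij}/n$. The likelihood is concave, so the uniform
  start reaches the global maximum; `gridSearchMLE()` is the independent
  grid-search oracle used to verify it.
- **ORF intactness.** `classifyLoci()` finds maximal ATG-to-stop ORFs
  > 300 aa in three sense frames, aligns them locally (BLOSUM62, affine
  gaps) to ORF1p/ORF2p consensus proteins, and calls an ORF intact when the
  alignment spans ≥ 95% of the consensus; loci are classed fully intact /
  ORF1-intact-ORF2-truncated / ORF1-truncated.

Around this core: IP-vs-input fold enrichment with library-anchored or
median-of-ratios size factors, exact binomial / rank-sum tests and BH FDR
(`foldEnrichment()`, `librarySizeFactors()`, `medianRatioSizeFactors()`,
`bhFDR()`); hierarchical read-category fractions and pooled circRNA
counting (`countReadCategories()`, `poolCircReads()`); expressed-locus
Jaccard overlaps with a Welch one-sided test (`locusSetOverlap()`); ΔΔCt
qPCR quantification (`ddct()`); and the RNA-granule comparison layer —
tie-aware Spearman and partial Spearman correlation, FDR-gated 2×2 overlaps
with exact hypergeometric p in log space (`spearmanCor()`,
`partialSpearmanCor()`, `overlapTest()`, `joinAndCompare()`). A
ground-truthed synthetic-data generator (`simulateGenome()`,
`simulateReads()`, `emulateAlignment()`) builds a toy genome whose LINE-1
loci genuinely multi-map and whose per-feature pulldown enrichments are
known, so the whole pipeline is testable without downloads.

## Worked example

Simulate a six-locus panel, classify intactness, and resolve multi-mapping
fragments per library:

```r
library(l1ripseq)
cfg <- simConfig(seed = 7, nL1Loci = 6, nReadsInput = 20000, nReadsIP = 20000)
sim <- simulateGenome(cfg)

calls <- classifyLoci(sim)
calls[, c("locus_id", "class", "orf1_coverage", "orf2_coverage")]
#>     locus_id                  class orf1_coverage orf2_coverage
#> 1 L1locus_01           FULLY_INTACT    1.00000000    0.99777778
#> 2 L1locus_02 ORF1_INTACT_ORF2_TRUNC    1.00000000    0.04444444
#> 3 L1locus_03             ORF1_TRUNC    0.05882353    1.00000000
#> 4 L1locus_04 ORF1_INTACT_ORF2_TRUNC    1.00000000    0.04444444
#> 5 L1locus_05             ORF1_TRUNC    0.13823529    1.00000000
#> 6 L1locus_06           FULLY_INTACT    1.00000000    1.00000000

rs <- simulateReads(sim)
aln <- emulateAlignment(rs, sim)
C <- buildCompatibility(aln$hits, sim@truth$locus_id, rs@errorRate,
                        rs@readLength, library = "input")
C
#> CompatibilityMatrix: 926 fragments x 6 loci; 5555 nonzero weights; 19055 fragments dropped
emQuantify(C)
#> AbundanceEstimate over 6 loci from 926 fragments
#>   EM: 4 iterations, converged, logL = -4334.567392
```

("Dropped" fragments are the host-gene reads, which hit no LINE-1 locus
and carry no information about locus abundances.)

A truncated ORF leaves the other ORF's coverage at 1.0 but its own near
zero (the premature stop shatters the candidate below the 300 aa floor), so
the coverage gate recovers every engineered class. The input-library EM
estimate tracks the simulated truth, while the IP library shifts mass onto
intact elements — ORF1p's cis-preference, here encoded in the generator's
per-class enrichment factors:

```r
#               L1locus_01 L1locus_02 L1locus_03 L1locus_04 L1locus_05 L1locus_06
# theta (input)      0.252      0.082      0.102      0.051      0.387      0.127
# theta (IP)         0.526      0.065      0.015      0.048      0.080      0.265
# theta (truth)      0.244      0.088      0.111      0.055      0.375      0.128
```

`aggregateByClass()` turns the IP estimate into class totals — with both
fully intact loci pulled down hardest, 79% of IP LINE-1 mass is fully
intact versus 37% in the input truth.

The whole chain, including enrichment and the granule comparison, runs as
one call with a manifest and per-stage logs:

```r
res <- runPipeline(demoConfig(seed = 1), outDir = "demo_out")
res$comparison
#> GranuleComparison over 50 joined genes ...
#>   Spearman rho = 0.41 (p = ...)
```

A thin command-line wrapper with per-stage subcommands lives at
`inst/cli/l1ripseq.R`
(`Rscript l1ripseq.R run-all --config cfg.yaml --seed 1 --out dir/`).

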