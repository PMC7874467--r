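---
title: "Locus-resolved ORF1p RIP-seq analysis: models and methods"
author: "l1ripseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-resolved ORF1p RIP-seq analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1ripseq)
```

## The scientific problem

LINE-1 (L1) is the only autonomous human retrotransposon. A full-length
element carries a 5'UTR promoter, two open reading frames — ORF1, an RNA
chaperone that coats the LINE-1 mRNA as homotrimers, and ORF2, an
endonuclease/reverse transcriptase — and a 3'UTR. Most of the hundreds of
thousands of genomic copies are mutated or truncated; only loci whose ORFs
remain intact can drive retrotransposition. Two analysis problems make
locus-level study of LINE-1 hard:

1. **Multi-mapping.** Reads from one locus align nearly as well to many
   near-identical copies, so per-locus read counts are not directly
   observable.
2. **Intactness.** Whether a locus can still encode functional ORF1p/ORF2p
   must be decided from its sequence, not from the alignment.

This package implements, as reusable and tested components, the analysis
pipeline of an ORF1p RNA-immunoprecipitation (RIP-seq) experiment: an
expectation–maximization (EM) assignment of multi-mapping fragments to
individual loci; an ORF-intactness classifier based on consensus-protein
alignment coverage; IP-versus-input enrichment estimation for LINE-1
classes and host-RNA categories; and the statistics used to compare
per-gene IP enrichments with external RNA-granule (p-body, stress-granule)
datasets. A ground-truthed synthetic-data generator provides the inputs, so
every stage is verifiable end to end without any external download.

## The EM model for multi-mapping fragments

Let $w_{ij}$ be the alignment likelihood of fragment $i$ under locus $j$:
for $m_{ij}$ mismatches over $L$ aligned bases (both mates of a pair,
treated as one fragment) and per-base error rate $\varepsilon$,

$$w_{ij} = \varepsilon^{m_{ij}} (1-\varepsilon)^{L - m_{ij}}.$$

Fragments are modelled as draws from the multinomial mixture
$P(i) = \sum_j \theta_j w_{ij}$ with $\theta$ the per-locus relative
abundance. `emQuantify()` maximises the likelihood by EM: the E-step
computes responsibilities $r_{ij} = \theta_j w_{ij} / \sum_k \theta_k
w_{ik}$, the M-step sets $\theta_j = \sum_i r_{ij}/n$. Because the
log-likelihood is concave in $\theta$ for fixed weights, the EM converges
to the global maximum from the uniform start; initialisation only decides
ties, so indistinguishable loci receive exactly equal shares. Expected
counts $n_j = \sum_i r_{ij}$ conserve the number of retained fragments, and
the log-likelihood trace is non-decreasing by construction — both are
asserted in the test suite, and `gridSearchMLE()` provides an independent
dense simplex grid-search oracle against which the EM is checked
exhaustively on small instances.

Numerical choices: convergence is declared on the *relative*
log-likelihood change (default $10^{-8}$, scale-free) with an iteration
cap; oracle comparisons run with a tightened tolerance ($10^{-12}$, 50k
iterations). Components whose maximum sits on the simplex boundary
approach it geometrically and arbitrarily slowly when two loci are
near-indistinguishable, so the implementation finishes with a guarded
Aitken $\Delta^2$ polish: the extrapolated limit of each component's
geometric decay is adopted only if it does not decrease the likelihood, so
the monotone-likelihood guarantee is preserved while boundary estimates
become exact. The grid-search oracle itself refines locally around its
coarse maximum (the dependent component of a 3-locus simplex grid point
otherwise carries up to two grid steps of quantization error). Fragments
with no reported locus alignment carry no information about $\theta$ and
are excluded and counted. This module implements the core multinomial-mixture
EM over reported alignments; refinements such as modelling passive
(intronic) transcription or 5' truncation are deliberately out of scope,
and the class-aggregation and enrichment layers are agnostic to them.

## ORF intactness classification

`findOrfCandidates()` translates the three sense-strand frames (LINE-1
ORFs are sense-encoded) and reports every maximal ATG-to-stop reading
frame strictly longer than 300 amino acids — within a stop-delimited
segment the first ATG defines the maximal ORF. Candidates are locally
aligned to the ORF1p and ORF2p consensus proteins
(`alignToConsensus()`: Smith–Waterman, BLOSUM62, affine gaps with open 11
/ extend 1, mirroring BLASTP conventions; all parameters configurable).
Coverage is *span* coverage — the fraction of the consensus between the
first and last aligned consensus positions, internal gaps included — and
an ORF is intact when some candidate covers at least 95% of its consensus.
Classes follow: both ORFs intact → `FULLY_INTACT`; only ORF1 →
`ORF1_INTACT_ORF2_TRUNC`; otherwise `ORF1_TRUNC` (a locus with no
candidates at all is `ORF1_TRUNC`). Raising the threshold can only move a
locus toward a less-intact class (a tested monotonicity property).
`aggregateByClass()` then sums EM abundances over classes, giving the
"intact LINE-1" and "intact ORF1" expression totals.

## Enrichment estimation and normalization

`foldEnrichment()` reports $E = (\bar c_{IP} + p_0) / (\bar c_{input} +
p_0)$ on size-factor-normalised counts, with pseudocount $p_0 = 0.5$ as a
continuity correction for zero-input features. Two size-factor methods are
provided:

* `librarySizeFactors()` — totals over all (or a declared subset of)
  features. In a total-RNA RIP experiment without rRNA depletion the
  library is dominated by rRNA, which the pulldown does not enrich, so
  total-count scaling anchors $E$ at the unenriched compartment: unbound
  features read out near 1× and bound features near their true pulldown
  factor. Passing `normFeatures` restricts the anchor explicitly (e.g. to
  rRNA features, or to exon-aligned features for the exon-anchored scale
  that shifts all values by a constant factor).
* `medianRatioSizeFactors()` — the median-of-ratios estimator (median over
  all-positive features of count over featurewise geometric mean, on the
  natural scale, rescaled to geometric mean 1). This is the right choice
  when most features are unchanged between samples; in an IP where *most*
  genes are genuinely enriched it would normalise the global enrichment
  away, which is why the library anchor is the default here.

Inside `foldEnrichment()` the factors are re-anchored to the input group
mean so that rescaling any one library by a constant is absorbed exactly by
its own factor, pseudocount included (a tested equivariance). Per-feature
p-values use an exact binomial test of the IP count against the IP share of
the feature total expected under equal normalised abundance (one sample per
group), or a rank-sum test across replicates; BH FDR is attached via
`bhFDR()`. `categorySummary()` compares a category's enrichment
distribution against all other features with a two-sided Mann–Whitney test,
`countReadCategories()` assigns reads hierarchically (rRNA first, then
exon, then LINE-1, then other — first match wins, so a read overlapping
rRNA and an exon counts as rRNA), `poolCircReads()` sums all back-splice
junction reads into one pooled circRNA feature, and `ddct()` implements
$2^{-\Delta\Delta C_t}$ relative qPCR quantification.

`locusSetOverlap()` quantifies how similar the expressed-locus repertoires
of two samples are: a locus is "expressed" when its expected count reaches
a configurable floor (default 1; there is no canonical threshold), overlap
is the Jaccard index as a percentage (the symmetric choice; an asymmetric
denominator would change the printed numbers), and within-family versus
between-family overlaps are compared with a one-sided Welch t-test
(unequal variances — the safer default when only "one-sided t-test" is
specified). Degenerate (constant) overlap groups report `NA` with a note
rather than failing.

## Granule comparison statistics

`joinAndCompare()` inner-joins the enrichment table with an external
per-gene vector, then computes: tie-aware Spearman correlation
(`spearmanCor()`: Pearson on midranks; exact full-permutation p for
$n \le 8$, $t$ approximation on $n-2$ df otherwise — full enumeration
beyond $n = 8$ is combinatorially out of reach and the approximation error
is already negligible there); partial Spearman correlation
(`partialSpearmanCor()`, the first-order recursion on midranks with a
$t$-test on $n-3$ df; the rank-residual regression method serves as an
independent oracle in the tests) given a second external vector; and an
FDR-gated 2×2 overlap with odds ratio and one-sided exact hypergeometric p
computed in log space (`overlapTest()`), Haldane-corrected and flagged when
a cell is zero. The 2×2 universe is the joined gene set, not all annotated
genes — using all genes would inflate the both-absent cell with genes never
measurable in one assay. The partial correlation answers the confounding
question this design exists for: when two external compartments (p-bodies
and stress granules) share most of their RNA content, a marginal
correlation with the second compartment can be entirely mediated by the
first; the synthetic construction in `simulateGranuleTables()` builds
exactly this structure (the SG vector loads only on the p-body vector), and
the tests verify the partial correlation collapses it to ≈0. Log-p values
are always reported alongside p so extreme significance never prints as 0.

## What the synthetic data emulates

`simulateGenome()` builds one consensus element (5'UTR, ORF1 of 340 aa,
spacer, ORF2 of 450 aa, 3'UTR; 3.6 kb total — a scaled-down full-length
element that keeps both ORFs above the 300 aa candidate floor while staying
fast), then derives each locus by substitution mutation at the configured
divergence (default 0.02, typical of the young L1 subfamilies whose copies
are recent enough to cross-map). Mutations that would create an accidental
in-frame stop, or destroy a start/stop, in an ORF meant to stay intact are
reverted, so the engineered truth is exact: truncated-class loci carry
exactly one premature stop placed in the middle half of the ORF.
Host genes are random-sequence contigs in six categories — polyA mRNA,
histone-like (non-polyA), mitochondrial-like, rRNA, lncRNA-like, and
circRNA hosts whose transcripts are circular so fragments crossing the
origin produce genuine back-splice junction reads.

`simulateReads()` draws input fragments proportionally to expression and IP
fragments proportionally to expression times a per-feature enrichment
factor sampled from per-category log-normal models. Defaults encode the
experiment's observed structure: gene categories centre near 10× (the
observed per-cell-line medians span roughly 5–22×), mitochondrial RNA
higher (~25×), pooled circRNA ~34×, LINE-1 loci strongest for fully intact
elements (60×) with ORF1-only (25×) and truncated (5×) below — the
cis-preference of ORF1p — and histone-like genes fixed at exactly 1× (the
non-polyadenylated control that the pulldown should not capture). rRNA is
fixed at 1× and carries the bulk of input expression (multiplier 500, about
85–90% of reads — no rRNA depletion step), which is what anchors
library-total normalization. The LINE-1 compartment defaults to 5% of input
expression: far above the ~0.1% of a real library, chosen so that
locus-level quantification is exercised at desk scale; the EM itself is
insensitive to this share. Fragment lengths are normal (250 ± 40 bp,
truncated at the read length), errors are uniform per-base substitutions
(0.002) to a different base, and qualities are flat — quality-score realism,
splicing, UMIs and duplicates are deliberately not modelled. Loci sit on
the plus strand by default; a flag enables minus-strand loci with
reverse-complemented reads. Coordinates are BED half-open 0-based on disk,
GTF/SAM 1-based, GRanges 1-based in memory, with conversions confined to
the serialization layer.

`emulateAlignment()` stands in for a read aligner. Because simulated loci
are equal-length substitution-only copies of one consensus, a LINE-1 read's
only alignable offset in any locus is its true consensus offset; mismatch
counts against every locus are therefore computed exactly from precomputed
inter-locus difference positions plus the fragment's recorded error
positions, and a hit is reported wherever the fragment total is at most
`maxMismatches` (default 10% of aligned bases). This is exact for this
genome by construction — it is an emulation of the *reporting*, not a
heuristic mapper — and multi-mapping then arises naturally from inter-locus
similarity. Host reads map uniquely to their own gene; junction-spanning
circRNA mates do not align contiguously and are excluded from the SAM, as
a linear aligner would drop them (the pooled circRNA count instead comes
from the junction-read truth, standing in for an upstream circRNA caller).

Because the generator's host genes are random sequences with unique
mapping, passing tests demonstrates correct inference *given* the model's
assumptions — they do not show robustness to real-genome features such as
paralogy among host genes, splicing, coverage bias, or LINE-1 5'
truncation gradients.

## Pipeline, determinism and problem sizes

`runPipeline()` chains simulate → classify-orfs → quantify-l1 → enrich →
compare-granules, stops at the first failing stage naming it, and writes a
manifest (config hash, per-stage wall time, md5 of every output file).
Stage seeds derive from the master seed by fixed offsets, so any stage can
be reproduced independently and a rerun is byte-identical — asserted by
checksum comparison in the tests. The demo configuration uses 12 loci,
68 host genes and 50k fragments per library and runs in well under a
minute; the heavier study conditions exercised by the test-suite and the
acceptance script are 50 loci with 100k LINE-1 fragments for EM recovery,
a 60-locus panel at divergence 0.03 for the classifier, 1M fragments per
library for enrichment recovery, and 200 replicate null simulations for
FDR calibration — sizes chosen to make the statistical checks sharp while
keeping a full run on one CPU in a few minutes.

## Known limitations

* The EM models fragments as independent draws from reported alignments;
  it does not model positional bias, passive transcription, or truncation.
* The intactness classifier requires an ATG-initiated ORF (a flag enables
  stop-to-stop frames) and decides on span coverage; heavily diverged
  elements whose best local alignment fragments into pieces may be called
  truncated even when a full protein is plausible.
* Enrichment p-values with one library per condition test sampling noise
  only; they cannot capture biological replicate variance (with
  replicates, the rank-sum path is used instead).
* The library-anchored enrichment scale assumes the anchor compartment is
  genuinely unenriched; if the pulldown bound rRNA, all fold enrichments
  would be deflated by that factor.
* External granule tables are synthetic here; with real tables, gene-id
  namespace mismatches surface as a hard join error rather than a silent
  empty result.
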