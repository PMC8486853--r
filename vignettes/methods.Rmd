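---
title: "Methods: quantifying enhancer decommissioning and germline competence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying enhancer decommissioning and germline competence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`germcomp` implements the quantitative backbone of a chromatin-level
germline-competence analysis: given histone-mark coverage tracks across
pluripotent stages (EpiLC, EpiSC), peak calls, chromatin-interaction
anchor pairs, single-cell UMI counts and single-cell CpG methylation
calls, it (i) defines the gene sets and cell populations of interest,
(ii) builds a distal enhancer catalog linked to those genes, (iii)
classifies enhancers by how consistently they retain H3K4me1 across
replicates, and (iv) quantifies epigenetic heterogeneity at single-cell
resolution. Everything upstream of these quantities — alignment, peak
calling, embedding computation, interaction calling — is treated as
input, not reimplemented.

# Gene sets and cell populations

**Differential expression.** Marker sets are defined target-vs-background
on per-cell normalized expression (counts scaled to 10,000 per cell). The
two-sample test is pluggable; the default is a two-sided Wilcoxon
rank-sum with Benjamini–Hochberg adjustment. We use a rank test rather
than a negative-binomial likelihood-ratio test because it is
assumption-light and exactly reproducible, and because the package's
validation criterion is recovery of planted markers, not numerical
agreement with any particular toolkit's p-values. Membership requires,
strictly, adjusted *p* < 0.005, expressing fraction in the target
pct.1 > 0.2, expressing fraction in the background pct.2 < 0.4, and a
positive log2 fold change. All three inequalities are strict; the
boundary tests pin this down.

**Transcriptional noise.** Within a stage, genes are ranked by dispersion
(variance/mean of normalized counts) and the top 500 are kept. The
selection criterion behind "most variable genes" is a genuinely open
choice; dispersion is used because it discounts the mean-variance
coupling of count data. All cell pairs are compared by Spearman ρ over
those genes and mapped to d = √((1 − ρ)/2), which lies in [0, 1] with
d = 0 for identical rankings, √0.5 at independence, and 1 for reversed
rankings. Ties get average ranks. A cell that is constant across the
selected genes has no defined ρ; its pairs are excluded with a warning
rather than silently assigned ρ = 0.

**Gating.** PGCLC-like cells are gated as
(*Dppa3* > 0.1 OR *Prdm1* > 1) AND *Klf4* < 1. The bare rule is
ambiguous about precedence; we bind the disjunction first, consistent
with the population label "*Prdm1* or *Dppa3*⁺/*Klf4*⁻": a cell at or
above the Klf4 threshold is never gated in. The expression scale for the
thresholds is also not fixed by the rule itself, so it is exposed as an
argument; the default is log1p counts-per-10k.

**Clustering and annotation.** Clustering is k-means on a supplied 2-D
embedding (10 restarts, best within-cluster sum of squares, seeded).
Clusters are annotated by a one-sided hypergeometric enrichment of each
candidate tissue's markers among the cluster's upregulated genes
(markers are expected to be pre-filtered to log2 fold change > 2.5 by
the caller); the label is the most significant tissue, and clusters with
no BH-adjusted enrichment below 0.05 are "undefined".

# Enhancer catalog

All intervals cross the package surface in BED convention (0-based,
half-open); GenomicRanges performs the arithmetic internally.

- **Merging**: peaks from all replicates are fused when they overlap or
  are separated by ≤ 1000 bp. The boundary is inclusive, matching the
  `-d` semantics of standard interval-merge tools; merging a merged set
  is a no-op.
- **Promoter/blacklist subtraction**: every base inside TSS ± 2 kb (or a
  blacklist region) is removed; empty remnants are dropped. TSS is the
  strand-aware 5′ end of the gene model.
- **Interaction linking**: a (peak, gene) link requires one anchor
  within 1 kb of the peak and the partner anchor within 3 kb of the
  gene's TSS; both anchor orders are tested, so the operation is
  symmetric under anchor swapping. Distances are nearest-edge gaps (0
  when overlapping), with a TSS treated as a 1-bp feature; whether the
  original analysis measured from anchor edges or midpoints is not
  recoverable, and edges are used throughout. One record per peak
  aggregates all linked genes, which is what makes ratios like "415
  enhancers over 216 genes = 1.9 enhancers/gene" well defined.
- **Proximal assignment**: peaks within 500 kb of a gene-set TSS are
  kept, unless any TSS lies within 3.5 kb; the nearest gene-set gene is
  assigned, ties broken lexicographically for determinism.

# Chromatin signal

**RPGC normalization.** A raw track is scaled by a single factor so the
base-weighted genome-wide mean coverage is 1 ("1× depth"). The operation
is idempotent and invariant to global rescaling; the unit tests hold the
mean to 1 ± 1e−6.

**Windowed quantification.** Signal is averaged over
[anchor − 1 kb, anchor + 1 kb), partial bins weighted by base overlap,
windows clipped at chromosome ends. "Within 1 kb of the enhancer" can be
read as midpoint-anchored or edge-extended; the midpoint reading is the
default and the anchor is exposed as an argument.

**Group classification.** Per enhancer and replicate, the ratio
(EpiLC + ε)/(EpiSC + ε) is computed with ε = 0.01 RPGC — small enough to
be negligible against typical signal of order 1, large enough to keep
empty windows finite. Group I requires, strictly, ratio > 1.2 in at
least 2 of 3 replicates; everything else is Group II, so the labels
partition the catalog and raising the threshold can only shrink Group I.

**Paired effect size.** The effect size of a paired two-sided Wilcoxon
signed-rank comparison is r = z/√n: zero differences are dropped, |d|
ranks use average ties, the variance is tie-corrected, and no continuity
correction is applied, so that z agrees exactly with the mean and SD of
the exhaustively enumerated sign-flip null (verified at n = 12 in the
tests). r is clamped to [−1, 1]; with all differences tied and
same-signed the statistic attains exactly 1. The all-zero-difference
case returns r = 0 with a degenerate [0, 0] interval and a warning
rather than an exception, so pipelines do not die on a pathological
contrast. Confidence intervals are percentile bootstrap over resampled
pairs (1000 resamples, seeded).

**Flanking-bin correlation.** For the mCpG-vs-H3K4me1 comparison, each
signal is averaged over one 500 bp bin immediately upstream and one
immediately downstream of the enhancer ("two 500 bp bins up- and
downstream" read as one bin per side, two bins total; the alternative
reading is a parameter), the two bins are pooled per enhancer, and
Spearman ρ is computed across enhancers. Rank correlation makes the
result unit-free, so percent methylation against RPGC is fine.

# Single-cell methylation heterogeneity

CpG sites are retained at 3–100 reads inclusive. Cells must cover
strictly more than 100 distinct CpG sites within the enhancer set;
"coverage > 10²" could in principle mean read depth, but the site-count
reading matches the ~150-shared-CpGs-per-pair scale the dissimilarity
operates at, and is what we implement. For each cell pair, dissimilarity
is the mean absolute difference of per-site methylation rates over CpGs
covered in both cells, ×100. On binary single-cell calls this is exactly
the fraction of discordant sites (the 0-similar/1-dissimilar scheme);
on fractional calls it generalizes smoothly, which is why rates rather
than binarized states are the primitive. Pairs sharing no site are NA —
flagged, never coerced to 0 — and excluded from stage means. Stage
heterogeneity is the mean over defined within-stage pairs.

# The synthetic-data generator

The generator exists so every downstream operation can be validated
against *known* ground truth. One master integer seed drives everything;
each generator draws from an independent substream (seed + fixed offset)
so regenerating one data type never perturbs another.

Defaults (the package's study conditions, used by the tests and the
acceptance script): a 2 × 1 Mb genome with 100 bp bins; 50 genes with
TSSs ≥ 12 kb apart; 40 class-I, 40 class-II and 20 decoy enhancers of
2 kb, ≥ 4 kb from every TSS and from each other; H3K4me1 EpiLC/EpiSC
fold 2.0 (class I) vs 1.0 (class II) with multiplicative lognormal
replicate noise of sd 0.1 on an enhancer mean of 8 against a 0.5
baseline; one true anchor pair per linked enhancer plus 40 decoy pairs
violating a distance rule by ≥ 5 kb; 80 cells per pluripotent stage and
a 200-cell embryoid body with a 40-cell PGCLC-like cluster, NB counts
with marker off-state mean 0.3 and 4× on-state, EpiLC dispersion 0.2 vs
0.8 elsewhere; and 12 cells per methylome stage with beta-distributed
enhancer methylation (mean 0.5; variances 0.01/0.09/0.04 planting a
known heterogeneity ordering), ~20 CpGs per enhancer, 30% site dropout,
3–30 reads per site. The 2 kb enhancer width is deliberate: the default
1 kb quantification window then sits wholly inside the enhancer, so the
zero-noise limit gives window ratios exactly equal to the configured
fold, an analytically exact oracle. The sizes keep the full test suite
under half a minute and the end-to-end demo in seconds on one CPU.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: read-level artefacts (GC bias,
duplicates, mappability), realistic peak-width and signal-shape
distributions, polymer-physics Hi-C contact structure, doublets and
ambient RNA in the UMI counts, or bisulfite conversion errors. Recovery
rates on planted truth certify the correctness of the computations, not
the biological error rates one would see on sequencing data.

# Degenerate inputs and numerical conventions

Zero-length subtraction remnants are dropped; empty windows are NA;
all-zero tracks refuse RPGC normalization; constant genes get p = 1
rather than a test error; k-means ties across restarts resolve to the
first-best restart via the seeded restart order; the dissimilarity and
noise matrices are symmetric with zero diagonals by construction. All
randomized package operations (bootstrap, k-means restarts, generators)
take explicit seeds and restore the caller's RNG state.

# Known limitations

The published catalog itself (415 enhancers, the 71%/29% group split,
~30% in vivo heterogeneity) depends on external accessions and is out of
scope at desk scale; this package validates the *operations* on planted
synthetic data and reproduces the in-text arithmetic those counts imply.
The Wilcoxon default for marker definition will not numerically match
negative-binomial toolkits on real data (the test is pluggable if that
matters), and the proximal-assignment tie-break, merge inclusivity at
exactly 1 kb, and edge-based anchor distances are documented choices
where the source pipelines leave the convention unstated.
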