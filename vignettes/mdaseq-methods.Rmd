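---
title: "Methods: lineage and maturation analysis of midbrain dopamine neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage and maturation analysis of midbrain dopamine neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdaseq)
```

# Scope

mdaseq re-implements, as a tested pipeline, the computational procedures
used to dissect the developmental heterogeneity of *Pitx3*-positive
midbrain dopamine (mDA) neurons: per-library quality control,
spike-in-calibrated variable-gene selection, principal-component
pseudotime with temporal curve clustering, a consensus-graph clustering
with marker-rule lineage annotation, an in situ sequencing barcode
decoder, and rank-based random-forest label transfer between the
dissociated and spatial modalities. Everything runs on synthetic data
with planted structure, so each stage can be scored against a known
truth without any external download.

# Quality control

Each library carries six alignment metrics: uniquely mapping fraction,
mismatch fraction, exon-mapping fraction, 3'-mapping fraction, fraction
of genes detected, and normalization reads. A cell passes iff all six
comparisons hold for its stage group; the defaults are the published
values (embryonic/perinatal: > 17.1 % unique, < 66 % mismatch, > 62 %
exon, < 7.8 % 3', >= 15 % genes detected, > 100,000 reads; adult: > 21,
< 80, > 61, < 8.8, >= 3.4, > 100,000). Bounds printed with ">"/"<" are
treated as strict — a metric exactly at such a threshold fails — while
the genes-detected bound ("at least") is inclusive. The filter is by
construction monotone: improving any single metric can never turn a pass
into a fail.

Oligodendrocyte-like contaminants are removed at the cluster level: a
community is flagged when its median reporter (eGFP) expression falls
below a detection floor (default 1 RPKM) while its median *Olig1*
exceeds a high-expression threshold (default 150 RPKM, re-using the
annotation threshold). The source protocol states this rule only
qualitatively; both cut-offs are exposed as arguments.

# Variable genes against the spike-in noise fit

Technical noise is modelled from the spike-in rows as
CV²(m) = a1/m + α0, fitted by a gamma GLM with identity link on 1/mean
(`statmod::glmgam.fit`, the standard approach for this regression).
A gene is called biologically variable when its observed CV²
significantly exceeds the fitted technical expectation at its mean,
using the one-sided chi-square test
(n−1)·CV²obs/CV²tech ~ χ²(n−1) with Benjamini–Hochberg adjustment.
The exact test behind the original selection is not restated in the
protocol; the chi-square formulation is this package's documented
choice, with the adjusted level defaulting to 0.1. Selection requires at
least 10 spike-ins above a mean floor (default 1 RPKM) and refuses
subsets without spike-ins, mirroring the design in which only E18.5, P1
and P90 libraries carry them; gene sets are therefore computed per stage
subset (E18.5, P1, P90) and on their union.

# Pseudotime and temporal classes

Pseudotime is the first principal component of log2(RPKM + 1) over the
merged variable genes, affinely mapped to [0, 100]. The log transform is
not stated in the protocol; it is the standard variance stabilization
for RPKM-scale data, and it means pseudotime is only *nearly* invariant
to a global rescaling of the matrix (the package's tests check rank
agreement ≥ 0.99 rather than exact equality). A principal component has
no intrinsic sign, so the axis is oriented by requiring the earliest
stage's mean pseudotime to lie below the latest stage's.

Genes changing with age are found by Wilcoxon rank-sum statistics for
each pairwise contrast of the Embryonic/Perinatal/Adult groups, with a
permutation null and BH q-values (threshold 0.01). This is a stand-in of
the same rank/resampling family as the SAMseq procedure used originally.
The null is pooled across genes — for fixed group sizes all genes share
the rank-sum null up to tie corrections — which gives p-value resolution
1/(genes × permutations) and makes q < 0.01 attainable at moderate
permutation counts (default 1000; 300–500 in the shipped tests and
scripts, a problem-size choice).

Temporal curves are natural cubic splines (df = 3) of log2(RPKM + 1) on
pseudotime, evaluated on a 100-point grid and clamped at zero. Fits are
per-gene independent, so curve fitting commutes with gene subsetting.
The cv² filter removes genes whose squared coefficient of variation
exceeds the mean cv² of their expression bin; "across different
expression levels" is read as 20 equal-count mean-expression bins, with
a single global-mean comparison available via `method = "global"`.
Whether the original filter used raw expression or fitted curves is
ambiguous; the default computes it on raw expression per gene. Retained
curves are standardized per gene and clustered with k-means (k = 3,
50 restarts, fixed seed).

# Consensus clustering and lineage annotation

Four t-SNE embeddings are computed, one per variable-gene set, each
seeing a different slice of the variation. From each embedding every
cell contributes its 5 nearest Euclidean neighbours; an unordered pair
counts at most once per embedding, and the fused graph's edge weight is
the number of embeddings (1–4) supporting the pair. Neighbour counting
(not rank weighting) is the default reading of the construction; the
published description does not weight by rank. Communities come from
weighted infomap (10 trials, fixed seed). t-SNE perplexity (30) and the
infomap trial count are not stated in the protocol and are exposed as
configuration.

Annotation follows the marker rule: a marker is "majority high" in a
community when more than half its cells exceed 150 RPKM. Precedence
when several markers are majority-high is Gad2 > Nxph4 > (Dat branch:
Vip > Aldh1a1 > Th-only), reproducing the two-branch, seven-lineage
structure in which branch identity dominates within-branch markers. The
Th-low/Th-high split within the *Nxph4* and *Gad2* branches — performed
manually in the original analysis — uses the same majority/threshold
rule on *Th*. Communities matching no marker are ND. Age groups are
majority votes per community over Embryonic (E13.5, E15.5), Perinatal
(E18.5, P1, P7) and Adult (P90), ties going to the earlier group.

# In situ decoding

Each amplicon spot carries a 4-round × 4-channel intensity tensor. Per
round, the called base is the channel-map letter (A=Cy5, C=Texas Red,
G=Cy3, T=AF488) of the argmax channel, and the quality score is the
maximum signal divided by the sum of all signals. Ties are broken to
the lowest channel index and flagged; real fluorescence ties are
measure-zero but synthetic integer intensities can tie. A spot is kept
iff its minimum per-round quality score reaches the threshold (default
0.5 — the published account thresholds without giving a value or an
aggregation; the minimum is the conservative choice) and its barcode is
an exact member of the codebook. The codebook guarantees pairwise
Hamming distance ≥ 2, which detects any single-round miscall but cannot
uniquely correct it, so near-miss barcodes are rejected, never remapped.

Spots are assigned to the nearest nucleus centroid within a radius
(watershed segmentation and image handling are out of scope; the
generator provides centroids), with equidistant ties going to the lower
cell id. The four published cell/gene filters are then applied in their
printed order: gate on Th/Pitx3/eGFP, drop genes seen in fewer than 10
cells, drop Pitx3/eGFP/Nxph4, drop cells with fewer than 3 genes. The
rules are a single ordered pass, exactly as printed; a second pass could
in principle remove more (a rule-4 cell removal can push a gene below
the 10-cell floor), and the idempotence checks use tables where one
pass is a fixpoint.

# Label transfer

Both modalities are reduced to within-cell ranks over the shared gene
panel (average ranks for ties; genes absent from a matrix score zero
before ranking). Ten random forests (ntree = 1000, mtry = 15, capped at
the panel size) are trained on the reference ranks with distinct seeds.
Per forest, a cell's prediction is kept only when the top class wins
strictly more than 45 % of the tree votes; the consensus label requires
strictly more than half of the forests to agree, otherwise "none". Both
strictness choices follow the printed wording ("more than"). "Votes"
are tree-vote fractions, not calibrated probabilities. Cross-dataset
cluster similarity is all-pairs Spearman correlation between
cluster-average expression profiles over a shared gene set; constant
profiles have no rank ordering and are reported as missing.

# The synthetic-data generator

The generator emulates the study's design: six stages (E13.5–P90,
default 100 cells each), seven lineages in two *Dat* branches at equal
proportions, marker genes at 300 RPKM in their own lineage (above the
150 RPKM rule) and 5 RPKM elsewhere, 92 spike-ins, Bernoulli dropout
(default 0.1), and technical noise CV²(m) = a1/m + α0 (defaults a1 = 3,
α0 = 0.05, a typical Smart-seq2-scale regime). Spike-in counts per cell
and dropout magnitude are not stated in the source protocol; these
defaults are configurable, documented choices. Expression is a
log-normal biological layer (geometric sd 0.35) times a gamma technical
layer, so the mean–CV² relation assumed by the selector holds by
construction; spike-ins carry the technical layer only. Temporal genes
(default 150, split early/intermediate/late) follow a 1.6-fold-per-stage
gradient; true maturation time is the stage index plus uniform jitter,
giving a continuous target for pseudotime recovery. Beyond the marker
panel, each lineage up-regulates a 20-gene signature 4-fold: real
lineages differ across broad expression programs, and the consensus
clustering (like any clustering of real data) relies on that breadth
rather than on six marker genes alone.

Barcodes come from the parity code (fourth base = sum of the first three
mod 4), which attains the maximum 64 codewords at Hamming distance 2;
requested codebooks are random subsets. Spot tensors place the signal
(default 100) on the barcode channel, optional crosstalk on the others,
and truncated Gaussian noise on top. Cells sit on a centroid grid and
emit 40 spots each (typical of padlock panels with abundant targets)
within a third of the grid spacing, so nearest-centroid assignment at
half the spacing recovers the true cell. Spot gene frequencies are
best derived from reference expression profiles
(`gene_frequencies_from_profiles()`), reflecting that amplicon counts
scale with expression; the marker-weighted fallback is cruder.

What the generator does *not* emulate: batch and plate effects,
ambient contamination, UMI-less amplification bias beyond the gamma
layer, doublets, spatially varying optical background, segmentation
errors, and real midbrain anatomy. Passing tests therefore demonstrate
the correctness and calibration of the procedures under the assumed
noise model, not robustness to every artefact of real data.

# Numerical choices and problem sizes

Fixed seeds flow to every stochastic step (simulation, t-SNE, infomap,
k-means, permutations, forests), making discrete outputs bit-identical
across reruns. Degenerate inputs error early: zero-variance matrices for
pseudotime, empty graphs, empty codebooks, all-"none" predictions.
The shipped tests and the acceptance script use 600-cell simulations
for the scRNA-seq arm, 100–500 nuclei for the spatial arm, 300-gene DE
matrices with 300–400 permutations, and 3–5 simulation seeds per
recovery estimate — sizes chosen so the full suite exercises every
stage at meaningful statistical resolution.

# Known limitations

* The published data-dependent numbers (1,106 retained cells, 48
  infomap communities, 2,167 curve-filtered genes, the 89 %/11 % branch
  split in tissue) depend on the deposited full-depth data set and are
  not reproduced here; the pipeline reproduces the *procedures* and
  their printed parameters.
* Permutation DE with a pooled null assumes exchangeable gene-wise rank
  statistics; strong tie structure (heavily zero-inflated genes) would
  weaken the pooling approximation.
* t-SNE coordinates are deterministic only for a fixed seed, BLAS and
  Rtsne version; discrete downstream outputs (communities, labels) are
  the reproducibility contract.
* The number of infomap communities is data- and resolution-dependent;
  the annotation step is designed to be robust to over-partitioning
  (several communities may map to one lineage).
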