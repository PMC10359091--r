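---
title: "Predicting base-pair single-cell methylation from single-cell Hi-C: methods and design"
author: "hicmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting base-pair single-cell methylation from single-cell Hi-C: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Assays that capture chromosome conformation and DNA methylation simultaneously
in the same single cell (methyl-3C / Methyl-HiC) are still rare, while
single-cell Hi-C data are comparatively plentiful. `hicmeth` predicts
base-pair-specific CpG methylation levels in promoter regions of an individual
cell from two inputs that are available without a methylation assay: the
cell's Hi-C contact list and the reference DNA sequence. The premise is that
the 3D organisation of a single genome carries cell-type-specific information
that co-varies with the methylation state of regulatory regions, so a model
that reads both the contact graph and the sequence can reconstruct
methylation profiles that preserve cell-to-cell variability.

# Pipeline

## Coordinates and windows

All internal coordinates are 0-based and half-open; each input format keeps
its native convention at the boundary (GTF 1-based, BED 0-based, contact and
methylation files 1-based by default and configurable). Every promoter is
anchored on its TSS (the 5' end of the gene respecting strand) and carries
two windows:

* a **contact window** of 10,001 bp, `[tss - 5000, tss + 5001)` — 5 kb on
  either side of the TSS plus the TSS base itself — used to assign Hi-C
  contacts to promoters and hence to define graph connectivity;
* a **sequence/target window** of 1,000 bp, `[tss - 500, tss + 500)`, used
  for the node sequence encoding and the per-base prediction targets.

The 1-kb window is TSS-centred by choice: nothing anchors it elsewhere, a
symmetric window treats upstream and downstream context identically, and the
anchor is configurable. Regions near chromosome edges are clipped and
flagged rather than dropped; positions outside the chromosome are invalid in
the target mask.

## Meta-cells

A single cell's contact list and methylation calls are far too sparse to
define a dense graph or reliable per-base targets, so both are pooled over a
**meta-cell**: the target cell plus its `k = 20` most similar cells.

* Hi-C similarity is the cosine between genome-wide binned contact-pair
  count vectors (1 Mb bins by default; the synthetic benchmark uses 10 kb
  bins because its chromosomes are only 250 kb). Ties are broken by
  lexicographic cell id so selection is deterministic.
* Methylation similarity is the cosine between methylation-level vectors on
  the sites covered in both cells; candidates sharing no site score 0.

For training and validation cells the neighbour pool is restricted to the
target's labelled cell type; blind-test cells draw from the full pool, since
their labels are treated as unknown. Pooled methylation sums methylated and
total read counts per site over members and takes the ratio of the sums, so
deeply covered sites weigh more than shallow ones — the natural estimator if
one imagines physically merging the members' reads. `k = 20` is the default
because the edge feature carries one count per meta-cell member, fixing the
feature length at `k + 3 = 23`; `k` is configurable and the feature length
tracks it.

## The promoter graph

Per (cell, chromosome): nodes are the chromosome's promoters in TSS order; an
undirected edge joins promoters *i* and *j* exactly when the aggregated
meta-cell contact count between their contact windows is at least 1. A
contact whose ends fall inside the windows of several promoters (windows may
overlap) increments every qualifying pair once.

* **Node features** encode the 1-kb window sequence as L1-normalised
  overlapping k-mer frequencies (`k = 6` by default, 4096 values; k-mers
  containing `N` are skipped). Minus-strand promoters are encoded from the
  complementary bases of the stored positive-strand window in positive-strand
  5'→3' order, i.e. complemented but *not* reversed. The encoder is a
  pluggable function of fixed output dimension, so a learned sequence
  embedding can replace the k-mer profile without touching the rest of the
  pipeline.
* **Edge features** are 23 values: the 21 per-member contact counts for the
  pair (target cell first, then neighbours in selection order), one
  occurrence value, and the genomic TSS distance in bp. The occurrence value
  summarises in how many of the 21 members the pair has a nonzero count; we
  read it as that integer count (range 1–21), with the alternative reading
  (the count divided by 21) available as a configuration switch, since the
  phrase "average number of occurrences" admits both.
* **Targets** are 1000-length vectors with a boolean mask: a position is
  masked-in iff it is the C or G of a CpG in the reference window *and* the
  pooled meta-cell calls cover it. A plus-strand call sits on the C; a
  minus-strand call (a cytosine on the negative strand) is reported at the G
  position. Values are pooled levels in `[0, 1]`.

## The edge-aware graph transformer

Each block computes, per head, query/key/value projections of the node
states and a projection of the edge state; the edge encoding is added to the
key, and attention over a node's neighbours is the exponential
scaled-dot-product, normalised over the neighbourhood:

$$\alpha_{h,ij} = \frac{\exp(q_i^\top (k_j + e_{h,ij}) / \sqrt{d})}
  {\sum_{u \in N(i)} \exp(q_i^\top (k_u + e_{h,iu}) / \sqrt{d})}.$$

Messages are $\alpha_{h,ij}(v_j + e_{h,ij})$, summed over neighbours and
concatenated across heads, then passed through LayerNorm followed by ReLU
(normalisation applied directly to the multi-head attention output). Edge
states are updated in parallel: per head, the scalar $\alpha_{h,ij}$ is
concatenated with the block-input edge state, heads are concatenated, then
LayerNorm + ReLU. In the final block the head concatenation is replaced by
the head average, and — following the displayed equation, which defines the
final node state directly as that average — no LayerNorm/ReLU is applied
there; with one head the final block therefore outputs the plain
attention-weighted aggregation. The default architecture is 5 blocks with 1
head and hidden size 64 per head, the configuration selected on validation
data.

Choices the method description leaves open, resolved here as the package's
own design:

* **Edge-state recurrence.** The attention equations index edge features by
  block, so each block consumes the previous block's updated edge states
  (dimension grows by `H × (1 + ...)` per block); a `raw` mode that
  re-projects the original 23 values in every block is available as a
  configuration switch.
* **Output head.** An affine map from the final node state to 1000 values
  followed by a sigmoid, giving predictions in (0, 1) for every base of the
  target window.
* **Loss and optimiser.** Masked mean squared error over mask-true positions
  (the targets are real-valued levels, not binary labels), minimised by Adam
  with learning rate 1e-3 by default, one gradient step per graph (each graph
  is one training example), early stopping on validation loss with patience
  10, and the best-validation parameters returned. All of this is seeded and
  reproducible bit-for-bit.
* **Isolated nodes.** A node with no edges receives a zero aggregation
  vector, so it still flows through the block stack and the output head;
  every promoter gets a prediction.
* **Numerical details.** Attention exponents are max-stabilised per
  neighbourhood (value-identical in exact arithmetic); LayerNorm uses
  population variance with eps 1e-5; raw edge features pass through `log1p`
  before the first block so member counts (order 1–10) and TSS distances
  (order 1e4–1e5) share a scale — this transform is part of the model
  configuration, not of the stored features.

Gradients come from a small reverse-mode tape written for this model; the
test suite checks them against central finite differences, and the full
forward pass against an independent straight-line scalar implementation of
the block equations.

## Evaluation

Metrics are computed only on positions with true levels available: Pearson
correlation and mean absolute error on the continuous levels; Matthews
correlation, average precision and ROC AUC on the truth binarised at 0.5
(predictions serve as scores; MCC thresholds them at the same 0.5). The 0.5
split is symmetric and, because observed single-cell levels concentrate at
exactly 0 and 1, the metrics are insensitive to its exact value; it is
configurable. Stratified views reproduce the standard analyses: absolute
error by true-level bin (exact 0 and exact 1 are their own bins) and the
metric set by promoter degree.

Two naive baselines predict a promoter's bases directly from its graph
neighbours' true levels at the same window offsets: variant 1 copies the
single most-connected neighbour (highest aggregated contact count, ties to
the lowest node index); variant 2 takes the contact-count-weighted mean over
all neighbours. Both are this package's documented constructions — they
stand in for baselines whose exact published definitions are not public —
and isolated nodes are excluded from their evaluation.

Cell-type structure is scored by clustering the cells × CpG-position matrix
of predicted levels: K-means with 4 centers (10 restarts, seeded) gives
`ARI-all-data` against the known types; t-SNE to two components (perplexity
30, reduced automatically for small cell counts, seeded) followed by K-means
on the two coordinates gives `ARI-two-components`. Promoters can also be
ranked by their single-promoter clustering ARI, with a cumulative top-k
curve.

# The synthetic benchmark

## What the generator emulates

The generator plants exactly the dependency structure the predictor assumes:
cell types differ in their Hi-C contact patterns, and methylation depends on
the contact structure. Each type owns a disjoint clique of promoters per
chromosome; a cell's contacts sample promoter pairs with weight
`1 + contact_boost` inside its type's clique and 1 elsewhere, with end
positions uniform in the contact windows and a Poisson number of contacts
per cell. Methylation probability per CpG is
`sigmoid(baseline + beta_seq * motif + beta_topo * in_clique + noise)`, where
`motif` is the GC content of the 7-bp context scaled to [-1, 1] (a
type-independent sequence effect, mirroring the shared reference genome),
`in_clique` indicates the cell type's own clique, and the Gaussian noise is
per-CpG, shared across types. Reads per CpG per strand are Poisson with
zero-read sites absent, and methylated counts are Binomial — so observed
single-cell levels concentrate at 0 and 1, as real single-cell data do.

Defaults are the benchmark study conditions: 2 chromosomes of 250 kb with 20
promoters each (40 genome-wide, TSSs every 12 kb), 4 types × 40 cells, 60
contacts and ~20 planted CpGs per promoter window per cell, `contact_boost
= 10`, `baseline = -4`, `beta_seq = 2`, `beta_topo = 8`, noise sd 0.5, one
read per CpG per strand in expectation. With these values a clique CpG of
the matching type sits near logit +4 (p ≈ 0.98) and background near -4
(p ≈ 0.02), so the planted signal is strong and recoverable — the intended
regime for an end-to-end correctness check.

What the generator does **not** emulate: distance-dependent contact decay,
TADs or compartments, polymer constraints, inter-chromosomal contacts,
read-level bisulfite chemistry, or promoters whose methylation depends on
cell type through anything other than contact-clique membership. Passing the
benchmark therefore demonstrates that the pipeline learns a planted
topology+sequence signal end to end, not that it attains any particular
accuracy on real methyl-3C data.

## Benchmark protocol and problem sizes

`run_benchmark()` simulates the default conditions, splits cells **within
each type** (24/8/8 per type for train/validation/test), builds meta-cells
(type-restricted neighbours for train/validation, full pool for test, 10-kb
similarity bins), trains the transformer (5 blocks, 1 head, hidden size 32,
4-mer node encoder, learning rate 2e-3, up to 20 epochs, patience 5), and
evaluates held-out metrics, both baselines, and clustering. The within-type
split departs from the type-disjoint train/test split used with real data
for a structural reason: clustering held-out cells into 4 types requires all
4 types in the held-out set, and the simulation has exactly 4 types. The
type-disjoint scheme remains available through the command-line layer, which
enforces split disjointness by cell id. The reduced hidden size, 4-mer
encoder and 20-epoch cap are the benchmark's problem sizes, chosen so a full
run completes in a few minutes on one CPU while leaving the planted signal
comfortably learnable; the model defaults (64, 6-mer, 100 epochs) remain the
package defaults for real use.

The **zero-signal control** re-simulates with `beta_topo = 0` and
`contact_boost = 0` and applies the *trained* model to the new held-out
cells: when Hi-C carries no type information, predictions derive from the
(shared) reference sequence plus typeless contact noise, so clustering them
against the planted types must collapse to chance (ARI ≈ 0). This is the
converse check that the clustering success in the signal condition really
flows through the Hi-C input.

# Known limitations

* The meta-cell neighbour metrics (binned-cosine for Hi-C, shared-site
  cosine for methylation) and the two naive baselines are this package's
  documented constructions; published supplementary definitions they stand
  in for were not available, so exact numeric parity with published tables
  is out of scope.
* DNABERT-style learned sequence embeddings are not reproduced; the k-mer
  encoder is the default and the encoder interface is the extension point.
* Graphs are per-chromosome; inter-chromosomal contacts contribute nothing
  to connectivity.
* Training is plain R; it is comfortable at benchmark scale (hundreds of
  graphs, tens of nodes) but not at genome scale (thousands of promoters per
  chromosome, tens of thousands of graphs).
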