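---
title: "Protein function annotation from feature-map images: models and methods"
author: "ProFunMap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein function annotation from feature-map images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProFunMap)
```

## The problem

Protein function prediction assigns Gene Ontology (GO) terms to amino-acid
sequences. The GO label space is hierarchical (a DAG with one root per
namespace: biological process, molecular function, cellular component) and
severely long-tailed: a handful of shallow families collect thousands of
annotated proteins while the many deep, specific families have few. Models
trained naively on such data learn the head families and ignore the tail.
ProFunMap implements a pipeline built around three ideas:

1. **Multi-scale representation.** Each sequence is summarized by a
   1,484-dimensional, seven-class descriptor vector, which is then viewed at
   two scales: a *feature-similarity* scale, where correlated descriptors
   are laid out next to each other on a square grid so the vector becomes a
   multi-channel image (one channel per descriptor class), and a
   *protein-similarity* scale, where the protein is represented by its
   vector of cosine distances to every protein of a fixed reference cohort.
2. **Dual-path encoding with pre-training.** A multi-channel CNN consumes
   the image, a five-layer fully-connected network consumes the similarity
   vector; the two path embeddings are concatenated and refined by a
   fully-connected head that is pre-trained against the GO labels under a
   focal loss.
3. **Level-wise recurrent decoding.** A three-layer LSTM consumes the
   frozen embedding and emits, at each of its time steps, sigmoid scores
   for the GO terms of one hierarchy level, shallow to deep, so the
   decoder can model dependencies between a family and its ancestors. The
   final score ensembles the decoder with a sequence-similarity transfer
   baseline.

## The descriptor stack

The default specification (`defaultDescriptorSpec()`) concatenates, in this
order: amino-acid composition (20), type-I pseudo amino-acid composition
with $\lambda = 30$ and weight $w = 0.05$ (50), amphiphilic pseudo
amino-acid composition with $\lambda = 30$ (80), normalized Moreau–Broto,
Moran and Geary autocorrelations over 8 AAindex property scales at lags
1–30 (720), quasi-sequence-order descriptors at max lag 21 (124), the
7-group composition/transition/distribution descriptors (147) and
conjoint-triad frequencies (343) — 1,484 features in total. The class
order fixes the channel order of the rendered images. The per-class sizes
are a documented parameterization of the standard published definitions,
chosen so the seven classes sum exactly to 1,484; every length
and parameter is configurable.

All residue property values are taken from published AAindex entries
shipped with `seqinr` rather than hand-typed tables. For the
quasi-sequence-order class two residue-distance matrices are used: a
Grantham-style composition/polarity/volume distance (weights 1.833,
0.1018, 0.000399, mean-scaled to 100) computed from the AAindex Grantham
property scales, and a physicochemical distance over the standardized
hydrophobicity/hydrophilicity/mass triple that also drives the pseudo
amino-acid classes. The residue-distance matrix classically used with quasi-sequence-order
descriptors is not redistributable here; the package's two matrices are
its own documented choice and are normalized to a maximum of
1 so both contribute comparably to the coupling numbers. Property scales
are standardized over the alphabet with the sample standard deviation.

Sequences must use the 20 canonical letters. The default sanitization maps
B→D, Z→E, J→L, U→C, O→K and drops X; a stricter drop-all policy is
available. The default spec requires at least 31 residues (the largest
correlation lag plus one); shorter sequences are rejected with a clear
error rather than padded.

## From descriptors to images

The cohort descriptor matrix is min-max normalized per feature,
$x^{norm} = (x - \min f_i)/(\max f_i - \min f_i)$, with constant features
set to 0 (warned). The feature-distance matrix uses the cosine distance
$d(f_a, f_b) = 1 - \frac{f_a \cdot f_b}{\|f_a\|\,\|f_b\|}$ between feature
columns; the protein-distance matrix applies the same formula to rows.
Zero-norm vectors carry no directional information and receive distance 1
to everything (logged).

The template map embeds the feature-distance matrix in 2-D — PCA on the
distance rows by default, with a UMAP option that delegates to the python
`umap-learn` package (`metric = "precomputed"`, seeded) through a
subprocess because no R UMAP implementation is available to the package.
PCA is the default because it is deterministic, dependency-free and, at
this cohort scale, the two methods produce layouts of comparable quality.
The embedded points are min-max rescaled to the unit square and assigned
to distinct cells of the smallest square grid that holds them
($39 \times 39$ for 1,484 features) by solving the rectangular linear
assignment problem with a Jonker–Volgenant shortest-augmenting-path solver
(implemented in C++ in this package; its optimality is tested against
exhaustive search). The cost of placing feature $i$ in cell $j$ is the
squared Euclidean distance between the rescaled embedding point and the
cell center — the standard choice in grid-layout methods for tabular data
(the solver is fixed by the method, the cost function is this package's
choice). The PCA sign
is fixed by forcing the largest-magnitude loading of each component
positive, so identical inputs give identical maps across platforms.

A protein's image places its normalized intensities (queries are clipped
to [0,1] after normalization with the frozen reference statistics) at the
assigned cells of its class channel; everything else is zero. The
similarity vector of a reference protein is its column of the protein
distance matrix (the matrix is symmetric, so row and column retrieval
coincide); for an unseen protein the same cosine formula is evaluated
against every reference row. This extension to queries outside the
reference cohort is required for inference and uses the frozen
normalization statistics.

## Encoder, decoder and losses

The CNN path applies two $3{\times}3$ stride-1 convolutions, each followed
by overlapping max-pooling (pool length 2, stride 1 — kept overlapping
even though stride-2 pooling is more common), ReLU
activations, then a dense layer to the embedding width. The
similarity-vector path is a five-layer ReLU fully-connected network whose
widths taper geometrically from the input size to the embedding width.
The two embeddings are concatenated and a refinement head maps them onto
the label space for pre-training. Defaults: filter counts 32 and 64,
embedding width 512 per path; these are free parameters the method leaves
open, and the desk-scale analyses below use smaller values.

Training uses Adam (the method fixes the learning rate at 0.0002 but
not the optimizer; Adam is the standard choice at that magnitude),
mini-batches of 32, and a focal loss
$-\alpha y (1-p)^\gamma \log p - (1-\alpha)(1-y) p^\gamma \log(1-p)$
with the canonical $\gamma = 2$, $\alpha = 0.25$; at $\gamma = 0$,
$\alpha = 0.5$ it reduces to half the binary cross-entropy (unit-tested).
Early stopping monitors the validation loss of the 80/20 split with
patience 10 and restores the best parameters. Divergence (non-finite
loss) aborts with diagnostics. All gradients are hand-derived and checked
against numerical differentiation in the test suite.

The decoder is a three-layer LSTM with 256 units per layer and tanh
activations, unrolled over 11 time steps. The label space, ordered by
hierarchy level and term id, is partitioned into level chunks: chunk $t$
holds the terms of the $t$-th shallowest level present, with deeper levels
merged into the last chunk. The mapping of levels to time steps is this
package's design: the decoder is motivated by the label hierarchy and
unrolls over 11 steps, and one chunk per level is the natural reading
given roots at level 1 and the deepest families at level 11. The embedding enters at step 1 and zeros afterwards (state-carried
decoding); feeding the embedding at every step is a configuration switch
away but was not needed. Forget-gate biases initialize to 1, a standard
recurrent-training aid.

Final scores ensemble the decoder with similarity transfer:
$s = \alpha\,s_{DL} + (1-\alpha)\,s_{sim}$, where the similarity score of
a query for term $t$ is the similarity-weighted vote of its $k = 30$
nearest reference proteins ($sim = 1 - d$ clipped to [0,1]). The weight
$\alpha$ is chosen on the validation fold by scanning
$\{0, 0.1, \ldots, 1\}$ for the best protein-centric Fmax, ties towards
the deep-learning side. By default a hierarchical-consistency pass then
raises every term's score to the maximum over its descendants inside the
label space, enforcing the true-path rule on the output; the flag is on by
default and documented because a hierarchy-aware decoder can still emit
locally inconsistent scores.

## Ontology handling

The OBO parser retains `is_a` edges only; `part_of` and `regulates`
relations are dropped so each namespace is a single-rooted DAG;
`is_a`-only keeps the level definition unambiguous. Obsolete terms are excluded. Levels follow the
minimum-depth rule: roots at level 1, every term one below its shallowest
parent — the natural reading of "direct children of the roots are level
2" for multi-parent diamonds. Annotation propagation closes each
(protein, term) pair over all non-root ancestors and is idempotent; root
annotations are dropped as uninformative. Label families are selected by
a strict threshold (more than 50 proteins by default) and each level is
classified head or tail by whether its average protein count (ANP) is at
least 2,000, boundary inclusive.

## Evaluation

`computeFmax()` implements the CAFA protein-centric Fmax: precision at
threshold $t$ averages over proteins with at least one prediction
$\ge t$, recall over all benchmark proteins, scanning thresholds
0.01–1.00 in steps of 0.01 (the CAFA convention; the grid is
configurable). Proteins with empty truth sets are excluded with a
warning. `computeAUPRC()` micro-averages over all (protein, term) pairs
and integrates the right-continuous precision–recall staircase with tie
groups. `levelAUC()` computes term-centric ROC AUCs (equal to the
normalized Mann–Whitney statistic, which the tests exploit as an oracle)
and macro-averages them within each hierarchy level; the head/tail
summary averages level AUCs within the two groups. All metrics are tested
against brute-force reference implementations on random instances to
1e-10.

## The synthetic benchmark

Real benchmark cohorts (tens of thousands of proteins, version-pinned GO
releases) are outside desk scale, so the package ships a generator whose
fixtures exercise every stage. `generateToyOntology()` builds a random
`is_a` DAG over three namespaces with occasional multi-parent diamonds,
acyclic by construction. `generateCohort()` plants recoverable signals:
each leaf family gets a distinct 6-mer motif and two bias residues; a
protein samples 1–3 leaves, its background residue distribution is tilted
towards its leaves' bias residues (factor 3) and each leaf's motif is
written into the sequence at non-overlapping positions (one guaranteed
copy, up to two more best-effort). Leaf prevalence decays as
rank$^{-1.5}$ with quotas assigned by largest remainder, so family sizes
are long-tailed and non-increasing in rank by construction. Sequences are
60–200 residues, the default cohort has 500 proteins on a 40-term,
depth-6 ontology, split 64/16/20 into train/validation/test (an 80/20
modelling split plus a held-out fold). A single seed drives everything.

What the generator does *not* emulate: homology structure between related
sequences, domain architecture, realistic residue composition,
annotation noise, or the species composition of real benchmarks. Passing
the held-out checks shows the pipeline can extract planted compositional
and motif signals end to end — not that it matches published performance
on real cohorts, which would require the original training data at full
scale.

For the desk-scale benchmark the label-space threshold is 20 proteins
(yielding 17 families across levels 2–4) rather than the full-scale
default of 50, which at $n = 500$ would keep only 10 families; the strict
full-scale threshold remains the package default. The analyses in the
acceptance script use reduced free-parameter widths (conv filters 8/16,
embedding 64) — the method's fixed hyperparameters are never changed — with
20 training epochs (patience 5) for the generalization run and 120 epochs
without effective early stopping for the capacity (overfit) run; at these
sizes the capacity run reaches a training Fmax of 1.0 and the whole
script completes in minutes on one CPU.

## Numerical choices and degenerate inputs

* Constant features normalize to 0 (warned); zero-norm vectors get cosine
  distance 1; distances are clamped to [0,2] and symmetrized against
  floating-point drift; near-zero query distances below 1e-12 snap to 0 so
  an exact duplicate of a reference protein reports distance 0.
* Moran and Geary autocorrelations of a constant realized property track
  are undefined and return 0 by convention (logged in the docs).
* Focal-loss probabilities are clamped to [1e-7, 1-1e-7].
* Assignment ties (equal-cost cells) resolve towards unassigned columns;
  any optimal solution is accepted by the tests, which compare total cost.
* Template maps serialize to JSON with doubles written as %.17g strings,
  so a round trip is bit-exact.
* Prediction TSVs round scores to 3 decimals — diff-stable files and
  standard submission practice; namespace roots never appear in output.

## Known limitations

* No GPU path and no mini-batch parallelism; the implementation targets
  cohorts of hundreds to a few thousand proteins.
* The level-to-time-step mapping and the ensemble rule are documented
  design choices of this package; both are configurable at the API
  level.
* `part_of`-aware propagation, GO-slim mapping and term-centric semantic
  distance metrics are out of scope.
* The UMAP option requires the python package at run time; PCA is the
  self-contained default.
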