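# ProFunMap

Protein function annotation in R from a multi-scale sequence
representation: descriptor vectors become feature-similarity **images**
(correlated descriptors placed next to each other on a square grid) and
protein-similarity **vectors** (cosine distances to a reference cohort); a
dual-path encoder (multi-channel CNN + five-layer fully-connected network)
is pre-trained against Gene Ontology labels under a focal loss, and a
three-layer LSTM decodes GO terms level by level down the hierarchy,
ensembled with a sequence-similarity baseline. The package targets
method developers and bioinformaticians who want a fully inspectable,
CPU-scale implementation of this family of models, together with
CAFA-style evaluation (protein-centric Fmax, micro-averaged AUPRC,
level-stratified AUC) and long-tail (head/tail level) diagnostics.

## The model in brief

Every sequence is summarized by 1,484 descriptors in seven classes
(amino-acid composition, pseudo and amphiphilic pseudo amino-acid
composition, Moreau–Broto/Moran/Geary autocorrelations, quasi-sequence-
order, composition/transition/distribution, conjoint triads). After
per-feature min-max normalization over the cohort,

* the **feature-distance matrix** `d(f_a, f_b) = 1 − cos(f_a, f_b)` is
  embedded in 2-D (PCA by default) and the embedded features are assigned
  to distinct cells of a 39 × 39 grid by an exact Jonker–Volgenant linear
  assignment — the frozen *template map*. A protein's *ProMAP* image
  places its normalized intensities at those cells, one channel per
  descriptor class (7 × 39 × 39);
* the **protein-distance matrix** over the same formula yields each
  protein's *ProSIM* vector (its column of the matrix; queries outside
  the cohort are scored against every reference row).

The encoder (conv 3×3/stride 1, overlapping max-pool 2/stride 1, twice,
then dense; five FC layers on the ProSIM path; concatenation + refinement
head) is trained with Adam (batch 32, learning rate 2e-4), focal loss
(γ = 2, α = 0.25) and early stopping on an 80/20 split. The decoder LSTM
(3 × 256 units, tanh, 11 time steps) emits sigmoid scores for one
hierarchy level per step. Final scores blend the decoder with a k-nearest
similarity transfer, the blend weight chosen on validation Fmax, followed
by a hierarchical-consistency pass (a parent never scores below a child).

## Worked example

Everything below is self-contained: the synthetic benchmark plants motif
and composition signals on a toy GO DAG, so the labels are recoverable
from sequence alone.

```r
library(ProFunMap)

bench <- generateBenchmark(n = 500, seed = 7)   # cohort + toy GO + split
idx   <- split(seq_along(bench$records), unname(bench$split))

cfg <- runConfig(seed = 1, familyMinCount = 20,
                 model = modelConfig(convFilters = c(8L, 16L),
                                     embedDim = 64L,
                                     maxEpochs = 20L, patience = 5L))
model <- trainProFunModel(bench$records[c(idx$train, idx$validation)],
                          bench$annotations, bench$graph, cfg,
                          split = list(train = seq_along(idx$train),
                                       validation = length(idx$train) +
                                         seq_along(idx$validation)))
model
#> ProFunModel: 400 reference proteins, 17 GO families, alpha = 0.10
#>   grid 39 x 39, 7 channels, 11 decoder time steps

pred  <- predictFunctions(model, bench$records[idx$test])
truth <- lapply(idx$test, function(i) {
  p <- bench$records[[i]]$id
  intersect(bench$truth@pairs$term[bench$truth@pairs$protein == p],
            colnames(pred))
})
computeFmax(pred, truth)$fmax
#> [1] 0.8408688
```

The trained model reports the grid geometry (39 × 39 cells, 7 channels),
the selected label space (17 families with more than 20 training
proteins) and the ensemble weight chosen on validation (0.1 here: on this
small planted-signal cohort the k-nearest similarity transfer is already
strong, so the blend leans on it while the decoder contributes the rest).
A held-out Fmax of 0.84 means the pipeline recovers most true families at
its best threshold; the label-frequency prior reaches only 0.65 on the
same fold.

A thin command-line wrapper covers the same stages
(`inst/scripts/profunmap simulate|features|templatemap|encode|train|predict|evaluate`),
writing a JSON run manifest next to every artifact.

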