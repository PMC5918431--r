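---
title: "Methods: mutation embeddings from co-occurrence, literature and interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation embeddings from co-occurrence, literature and interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what the test
suite does and does not demonstrate.

## The model

A tumour sample is a set of mutated genes. The working assumption is that
genes recurrently co-mutated across samples are functionally related —
the analogue of the distributional hypothesis for words. `mutembed` embeds
genes with skip-gram and negative sampling (SGNS): for a (center, context)
pair $(e_i, e_j)$ and negatives $D_i$, the per-pair loss is

$$L = -\log\sigma(u_i^\top v_j) - \sum_{l\in D_i}\log\big(1-\sigma(u_i^\top v_l)\big),$$

minimised by SGD over all pairs. $U$ (rows $u_i$) is the embedding lookup
layer and is what the user gets; $V$ is the output layer. Negatives are
drawn i.i.d. from the unigram distribution raised to the $3/4$ power, with
the pair's own positive context excluded by rejection, since negatives
should be non-contextual entities.

### Context construction

Within a sample, mutations have no meaningful order, so a sliding text
window would be arbitrary. Instead each sample is subsampled **without
replacement 10 times with draw size 10** (`draws_per_sample`,
`draw_size`), and within a draw every gene is context for every other,
i.e. a draw of size $s$ emits all $s(s-1)$ ordered pairs. Two consequences
are intended:

* samples with very few mutations (but at least 2) are used in full on
  every draw, so their precious co-occurrence signal is weighted up;
* hypermutated samples — per-sample burden in real cohorts spans below 10
  to above 1000 — contribute each individual mutation to only
  $\approx$ `draw_size`/burden of draws, damping their noise.

Two details here were genuinely open. Whether pairs within a draw should
be formed center-versus-rest or as all ordered pairs is equivalent in
expectation up to multiplicity; all ordered pairs was chosen because it is
deterministic given the draw. And the 10 draws are independent
repetitions of the same procedure (a gene may recur across draws of one
sample); that is the natural reading of repeating a fixed-size sampling
procedure.

### The four variants

* **basic** — SGNS on cohort profiles only.
* **pretrained-init** — rows of $U$ whose gene has a vector in a
  pre-trained word-vector table (matched case-insensitively) are
  initialised from it before cohort training; $V$ and unmatched rows are
  untouched. This transfers literature context: in text, driver genes
  co-occur with a recognisable vocabulary and with each other.
* **retrofit** — post-processing on a protein-interaction network (below).
* both — initialisation and retrofitting combined.

Which variant is fitted follows from which optional inputs are passed to
`mutation_embedding()`; there is no separate switch to keep inconsistent
states unrepresentable.

## Retrofitting

Given trained vectors $\tilde Q$ and one-hop neighbour sets $S_i$ from the
interaction graph (intersected with the embedded vocabulary — degrees are
computed *after* that intersection), retrofitting considers

$$J(Q,\tilde Q)=\sum_i\Big(\alpha_i\lVert q_i-\tilde q_i\rVert^2+\sum_{j\in S_i}\beta_{ij}\lVert q_i-q_j\rVert^2\Big),
\qquad \alpha_i = 1,\; \beta_{ij}=|S_i|^{-1},$$

and applies the standard iterative update

$$q_i \leftarrow \frac{\alpha_i\tilde q_i+\sum_{j\in S_i}\beta_{ij}q_j}{\alpha_i+\sum_{j\in S_i}\beta_{ij}}$$

swept cyclically, 10 sweeps by default with early stopping at a maximum
per-sweep change of `tol = 1e-6`. Entities without neighbours keep
$q_i=\tilde q_i$ exactly.

One property of this procedure deserves a precise statement, because it is
easy to mis-assert. With the default weights, $\sum_j \beta_{ij} = 1$, so
the update is Gauss–Seidel on the linear system $(2D-A)\,Q = D\tilde Q$
($D$ = degree matrix, $A$ = adjacency), whose matrix is symmetric positive
definite. The iteration therefore converges monotonically — but in the
quadratic that system is the gradient of,

$$F(Q)=\sum_i |S_i|\,\lVert q_i-\tilde q_i\rVert^2+\sum_{\{i,j\}\in E}\lVert q_i-q_j\rVert^2,$$

a degree-reweighted relative of $J$, **not** in $J$ itself: because
$\beta_{ij}\ne\beta_{ji}$ whenever degrees differ, the update ignores the
reverse-direction terms of $J$ and $J$ can (and in practice does,
transiently) increase between sweeps while $F$ decreases. The package
deliberately keeps the published update — its fixed point (e.g.
$q_A=(2/3,1/3),\,q_B=(1/3,2/3)$ for two anchored unit vectors with
$\beta=1$) is the behaviour practitioners expect from this
post-processing step — and `retrofit_objective()` evaluates $J$ exactly
as defined, with the directed double sum. The unit tests assert the
guaranteed properties: monotone descent of $F$, stationarity of the limit
under the update map, convex-combination geometry, identity on empty
graphs, and continuity as $\beta\to 0$.

Only positive interactions are used; evidence of *absence* of interaction
has no representation in this quadratic and is out of scope.

## Evaluation

* **PCA** (`pca_project`) mean-centres, never scales, and fixes component
  signs by making the largest-magnitude loading positive, so projections
  are reproducible across platforms.
* **k-means** (`kmeans_cluster`) runs on the full-dimensional vectors
  (never on a projection), takes the best of `n_init = 10` restarts, and
  is deterministic given its seed. The degenerate case $k=n$ returns the
  exact optimum (singletons, zero inertia) directly.
* **NMI** uses natural logarithms (the measure is base-invariant),
  $0\log 0 \equiv 0$, and
  $\mathrm{NMI}=\mathrm{MI}/\big[(H(\Omega)+H(C))/2\big]$. If both
  partitions are single-block, both entropies vanish but the partitions
  are identical; 1 is returned with a warning rather than NaN.
* The driver/passenger evaluation clusters the known drivers together
  with an equal-sized random sample of passengers (`evaluate_embedding`);
  sampling as many passengers as there are drivers keeps the two-class
  problem balanced, and the sample size is exposed for users who want the
  unbalanced regime.
* The binary gene-by-sample matrix (`binary_matrix`) is provided as the
  sparse baseline representation that dense embeddings are compared
  against.

## Driver identification

All embedded genes are clustered (k = 200 by default at cohort scale;
desk-scale analyses here use k = 20 on 500 genes) and the cluster
containing the **most** known drivers is selected — maximum count, not
minimum p-value, with ties broken by smaller hypergeometric p-value and
then lower cluster id. The enrichment test is the hypergeometric upper
tail $P(X \ge k)$ with the population $N$ = all embedded genes (not all
human genes: genes that never entered the embedding could never have been
drawn into a cluster). Cluster members carrying no driver label, known or
predicted, are reported as candidates.

Gene-set over-representation uses the one-sided (greater) Fisher exact
test — the standard over-representation convention — with
Benjamini–Hochberg correction across sets, against a background that
defaults to the embedded vocabulary but is overridable, since hosted
enrichment platforms use their own backgrounds and produce numerically
different tables for the same cluster.

`hypergeom_sf()` delegates to `stats::phyper` (log-scale internals, so
tails of order $10^{-50}$ are stable); the tests cross-check it against
exhaustive enumeration of the probability mass function for every
parameter combination with $N \le 25$, and `fisher_exact_greater()`
against both the enumeration and `stats::fisher.test`.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `dim` | 300 | embedding dimension; the scale at which gene representations are usually trained |
| `draws_per_sample`, `draw_size` | 10, 10 | context subsampling (above) |
| `negatives` | 5 | negatives per pair; the standard small-corpus choice — the method only requires the count be fixed |
| `epochs` | 5 | passes over the pair stream, word2vec convention |
| `lr_initial`, `lr_final` | 0.025, 1e-4 | linear SGD decay over all updates, word2vec convention |
| `min_count` | 1 | cohort vocabularies are small relative to text; nothing is discarded by default |
| `alpha`, `beta` | 1, $|S_i|^{-1}$ | retrofitting weights as published |
| `retrofit_iterations`, `tol` | 10, 1e-6 | sweeps; convergence is geometric so 10 is ample |
| `eval_k`, `enrich_k` | 2, 200 | clusters for the two analyses |

## Numerical and engineering choices

* $U$ is initialised uniform in $(-0.5/d,\,0.5/d)$ and $V$ at zero — the
  word2vec convention; with all scores zero the per-pair loss is exactly
  $(1+|D_i|)\log 2$, which the tests pin down.
* The SGD loop is compiled (Rcpp), single-threaded, and uses its own
  splitmix64 RNG with Walker alias sampling for the noise distribution,
  so training is bit-reproducible from one integer seed, independent of —
  and without disturbing — R's RNG stream. A concurrency mode is
  deliberately not offered; it would forfeit that determinism.
* The sigmoid and $\log\sigma$ are computed overflow-safe; training aborts
  with a diagnostic if any parameter goes non-finite (symptom of a
  too-high learning rate).
* Vocabulary order is count-descending with lexicographic tie-break —
  fully deterministic, so vocabulary indices are stable across runs.
* Gene symbols are upper-cased at every ingestion point: cohort profiles,
  vector tables, networks, labels and gene sets are joined by gene name
  and need one canonical casing.
* All file formats are plain text (two-column TSVs, word2vec text
  vectors, GMT), and every reader raises typed conditions
  (`mutembed_format_error`, `mutembed_validation_error`, ...) that the
  command-line wrapper maps to exit codes.

## The synthetic cohort generator

`simulate_cohort()` plants two 20-gene driver modules in a 500-gene
universe and draws 400 samples by default: a sample expresses each module
independently with penetrance 0.5 (an expressed module contributes each
gene with probability 0.9), and adds uniform passengers with count
`round(passenger_rate × Pareto(α = 2))`, `passenger_rate = 5`. The Pareto
multiplier reproduces the qualitative burden distribution of real
cohorts — most samples carry a handful of passengers, occasional
hypermutated ones carry hundreds — while α = 2 keeps the mean finite.
Penetrance 0.5 makes module co-occurrence strong but not deterministic,
and roughly a quarter of samples express both modules, which is what lets
the model place the two modules in one driver region of the space.
`simulate_ppi()` is a stochastic block model on the modules
(`intra_p = 0.3`, `inter_p = 0.01`); `simulate_corpus()` writes sentences
where driver genes co-occur with a shared "driver-context" filler
vocabulary and passengers with neutral fillers, with 10% cross-class
mixing so the classes are not trivially separable.

What the generator does *not* emulate: mutational signatures and
trinucleotide context, cancer-type heterogeneity, realistic per-gene
background mutation rates, gene-length effects, partial driver overlap
between modules, or the ambiguity of gene-name recognition in real text.
Passing the end-to-end tests therefore demonstrates that the
implementation recovers planted co-occurrence/network/literature structure
at realistic noise levels — not that it reproduces any particular
cohort-scale result. Published cohort-scale scores (e.g. visualisation
NMIs near 0.65–0.87 on real pan-cancer data) require the original cohort,
literature and network inputs and are outside what simulation can certify.

## Problem sizes used in the checks

The end-to-end checks run the default generator (400 samples, 500 genes,
2 × 20 drivers) across 5 replicate seeds with the full default model
(dim 300, 5 epochs), plus one 20-cluster identification run; unit tests
use miniature cohorts (60–120 samples, dim 12–32) and analytic fixtures.
The heavy recovery check asks that the combined variant reach NMI ≥ 0.6
on a majority of replicates while random vectors of the same shape stay
≤ 0.1, and that pre-training plus retrofitting not hurt the basic model
on average — the desk-scale analogue of the qualitative claim that the
augmentations sharpen the driver/passenger distinction.

## Known limitations

* The MAF reader consumes only `Tumor_Sample_Barcode` and `Hugo_Symbol`;
  selecting protein-altering mutations (or any consequence filtering) is
  the caller's responsibility upstream.
* Retrofitting treats all network edges equally; edge weights, negative
  interactions and multi-hop structure are not modelled.
* Sample-level vectors from `predict()` are unweighted means of member
  gene vectors — a deliberately simple aggregate, not a learned one.
* With `min_count = 1`, genes seen in a single sample are embedded but
  their vectors are dominated by initialisation; pre-trained
  initialisation is the intended remedy.
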