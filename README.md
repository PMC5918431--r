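# mutembed

Dense, low-dimensional representations of gene-level cancer mutations,
learned from which genes are mutated together in the same tumour samples.

## The problem

Somatic mutation profiles are usually handed to downstream models as huge
sparse binary matrices (gene × sample indicators). That encoding carries no
biological context: it cannot express that two genes tend to be co-mutated,
or that a gene behaves like the known cancer drivers. `mutembed` treats a
tumour sample the way word-embedding methods treat a sentence — the
mutations that co-occur in one sample are each other's *context* — and
trains a skip-gram model with negative sampling (SGNS) over those contexts.
Because cohort data are scarce compared with text corpora, two optional
augmentations inject outside knowledge:

* **Pre-trained initialisation** — the embedding lookup layer is seeded
  with word vectors for gene names trained on a text corpus, so literature
  context (driver genes co-occurring with words like "critical" or "drug
  resistance") is inherited before cohort training begins.
* **Retrofitting** — after training, vectors are pulled toward their
  one-hop neighbours in a protein-interaction network, on the assumption
  that interacting proteins have similar alteration effects.

## The model

For a center gene $e_i$ with context gene $e_j$ and negatives
$D_i$ drawn from the unigram$^{3/4}$ noise distribution, SGNS minimises

$$L = -\log\sigma(u_i^\top v_j) \;-\; \sum_{l \in D_i}\log\left(1 - \sigma(u_i^\top v_l)\right)$$

where $u_i$ (rows of $U$, the lookup layer) are the embeddings kept at the
end. Mutation order within a sample is meaningless, so instead of a sliding
window each sample is randomly subsampled **10 times without replacement
with draw size 10**, and every gene in a draw is context for every other —
hypermutated samples therefore contribute each of their mutations rarely,
while small samples are used in full.

Retrofitting minimises
$J(Q,\tilde Q) = \sum_i \big( \alpha_i\lVert q_i-\tilde q_i\rVert^2 +
\sum_{j\in S_i}\beta_{ij}\lVert q_i-q_j\rVert^2 \big)$
with $\alpha_i = 1$, $\beta_{ij} = |S_i|^{-1}$, where $S_i$ are the one-hop
network neighbours, via the iterative update
$q_i \leftarrow (\alpha_i\tilde q_i + \sum_{j\in S_i}\beta_{ij} q_j) /
(\alpha_i + \sum_j \beta_{ij})$.

Embeddings are evaluated by PCA visualisation and by clustering
driver/passenger-labelled genes (k-means, scored with normalized mutual
information), and driver candidates are prioritised by finding the k-means
cluster most enriched in known drivers (hypergeometric upper-tail test),
with gene-set over-representation via one-sided Fisher tests and
Benjamini–Hochberg correction.

## Worked example

Everything runs on simulated data with planted structure — a cohort whose
samples carry co-occurring driver-module genes plus random passengers, and
a modular interaction network:

```r
library(mutembed)
cohort <- simulate_cohort(n_samples = 200, n_genes = 250, seed = 1)
graph  <- simulate_ppi(cohort$modules, cohort$genes, seed = 1)
fit <- mutation_embedding(cohort$profiles, graph = graph, dim = 64, seed = 1)
fit
#> Mutation embedding (sgns+retrofit)
#>   250 genes embedded in 64 dimensions
#>   trained on 161500 (center, context) pairs, 5 epochs, seed 1
```

Do drivers and passengers separate? Cluster the 40 planted drivers plus 40
sampled passengers with k-means (k = 2) and score against the truth:

```r
evaluate_embedding(fit$vectors, cohort$labels, seed = 1)$report
#>   n_drivers n_passengers k      nmi
#> 1        40           40 2 0.915425
```

An NMI of 0.92 means the 2-cluster split almost exactly reproduces the
driver/passenger labelling (1 = identical partitions, 0 = independent).
Candidate driver identification: cluster *all* genes, take the cluster with
the most known drivers, and test its enrichment:

```r
part <- kmeans_cluster(fit$vectors, k = 10, seed = 1)
most_enriched_cluster(part, cohort$labels)$result
#>     N  K  n  k      p_value
#> 1 250 40 23 20 1.098601e-15
```

20 of the 23 genes in the selected cluster are planted drivers (of 40 among
250 genes) — enrichment far beyond chance. The three unlabelled members
would be reported by `extract_candidates()` as driver candidates. Vector
neighbourhoods tell the same story:

```r
nearest_genes(fit, "DRV1_01", n = 5)
#>   PSG0027   DRV1_02   DRV1_11   DRV1_12   DRV1_19
#> 0.9770781 0.9766190 0.9736071 0.9620134 0.9618868
```

Four of the five nearest neighbours of a module-1 driver are module-1
drivers (by cosine similarity).

File-based workflows (profile TSV/MAF in, word2vec-format vectors and TSV
reports out) go through `pipeline_config()` / `run_pipeline()`, or the thin
command-line wrapper in `inst/cli/mutembed.R`.

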