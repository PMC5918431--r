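# Embedding evaluation: the binary gene-by-sample baseline, principal
# component projection for visualisation, k-means clustering, and normalized
# mutual information between a clustering and a class labelling.

#' Binary gene-by-sample mutation matrix
#'
#' The sparse baseline representation: entry (g, s) is 1 iff gene g is
#' mutated in sample s.  Row order follows `vocab` (default: the cohort
#' vocabulary in count-descending order), column order follows the samples.
#'
#' @param profiles a [mutation_profiles] object.
#' @param vocab optional character vector fixing the row order.
#' @return 0/1 integer matrix, genes in rows, samples in columns.
#' @export
binary_matrix <- function(profiles, vocab = NULL) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  if (is.null(vocab)) vocab <- build_vocab(profiles)$vocab
  out <- matrix(0L, nrow = length(vocab), ncol = length(profiles),
                dimnames = list(vocab, names(profiles)))
  for (s in seq_along(profiles)) {
    i <- match(profiles[[s]], vocab)
    out[i[!is.na(i)], s] <- 1L
  }
  out
}

#' Project vectors onto their leading principal components
#'
#' Mean-centred PCA with a deterministic sign convention: within each
#' component, the loading with the largest absolute value is made positive.
#'
#' @param vectors numeric n x d matrix, n > `n_components`.
#' @param n_components number of components to keep (default 2).
#' @return list with `coordinates` (n x n_components scores),
#'   `explained_variance_ratio`, and `rotation` (loadings).
#' @export
pca_project <- function(vectors, n_components = 2L) {
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) <= n_components) {
    abort_config("need more rows than components")
  }
  if (all(apply(vectors, 2L, stats::var) < .Machine$double.eps)) {
    abort_degenerate("input has zero variance; nothing to project")
  }
  p <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    lead <- which.max(abs(rot[, c]))
    if (rot[lead, c] < 0) {
      rot[, c] <- -rot[, c]
      scores[, c] <- -scores[, c]
    }
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = scores,
       explained_variance_ratio = evr[seq_len(k)],
       rotation = rot)
}

#' k-means clustering of embedding vectors
#'
#' Lloyd-style k-means (via [stats::kmeans]) with `n_init` random restarts,
#' keeping the best-inertia solution.  Clustering operates on the
#' full-dimensional vectors, not on a PCA projection.  Deterministic under
#' `seed`.
#'
#' @param vectors numeric matrix, one item per row (row names kept).
#' @param k number of clusters, `k <= nrow(vectors)`.
#' @param seed integer seed.
#' @param n_init random restarts (default 10).
#' @return named integer vector of cluster assignments in 1..k, with the
#'   achieved total within-cluster sum of squares in attribute `"inertia"`.
#' @export
kmeans_cluster <- function(vectors, k, seed = 1L, n_init = 10L) {
  stopifnot(is.matrix(vectors))
  if (k > nrow(vectors)) abort_config("k must not exceed the number of items")
  if (k == nrow(vectors)) {
    # every point its own cluster: the unique optimum, inertia 0
    out <- seq_len(k)
    names(out) <- rownames(vectors)
    attr(out, "inertia") <- 0
    return(out)
  }
  fit <- with_seed(seed,
    suppressWarnings(stats::kmeans(vectors, centers = k, nstart = n_init, iter.max = 100L))
  )
  out <- fit$cluster
  names(out) <- rownames(vectors)
  attr(out, "inertia") <- fit$tot.withinss
  out
}

partition_probs <- function(assign) {
  tab <- table(assign)
  as.numeric(tab) / sum(tab)
}

align_partitions <- function(omega, classes) {
  if (!is.null(names(omega)) && !is.null(names(classes))) {
    common <- intersect(names(omega), names(classes))
    if (length(common) == 0L ||
        length(common) != length(omega) || length(common) != length(classes)) {
      abort_validation("partitions must cover the same item set")
    }
    list(omega = omega[common], classes = classes[common])
  } else {
    if (length(omega) != length(classes)) {
      abort_validation("unnamed partitions must have equal length")
    }
    list(omega = omega, classes = classes)
  }
}

#' Entropy of a partition
#'
#' `H = -sum_i p(block_i) log p(block_i)` with natural logarithms.
#'
#' @param assign vector assigning each item to a block (any atomic type).
#' @return entropy in nats (>= 0).
#' @export
partition_entropy <- function(assign) {
  p <- partition_probs(assign)
  -sum(p * log(p))
}

#' Mutual information between two partitions of the same items
#'
#' `MI = sum_ij p(i, j) log( p(i, j) / (p(i) p(j)) )` in nats, with the
#' convention `0 log 0 = 0`.  When both vectors are named, items are matched
#' by name; otherwise positionally.
#'
#' @param omega,classes block assignments of the same item set.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(omega, classes) {
  al <- align_partitions(omega, classes)
  joint <- table(al$omega, al$classes) / length(al$omega)
  po <- rowSums(joint); pc <- colSums(joint)
  terms <- joint * log(joint / outer(po, pc))
  sum(terms[joint > 0])
}

#' Normalized mutual information
#'
#' `NMI = MI / ((H(omega) + H(classes)) / 2)`, symmetric in its arguments
#' and invariant to the logarithm base; 1 for identical partitions, 0 for
#' independent ones.  When both partitions are single-block their entropies
#' vanish; the partitions are then identical and 1 is returned, with a
#' warning.
#'
#' @inheritParams mutual_information
#' @return NMI in [0, 1].
#' @export
nmi <- function(omega, classes) {
  al <- align_partitions(omega, classes)
  h <- partition_entropy(al$omega) + partition_entropy(al$classes)
  if (h == 0) {
    warning("both partitions are single-block; returning 1 (identical partitions)")
    return(1)
  }
  val <- mutual_information(al$omega, al$classes) / (h / 2)
  min(max(val, 0), 1)
}
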