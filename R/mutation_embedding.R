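# The fitting front-end.  mutation_embedding() wires the whole method
# together: vocabulary construction, per-sample context subsampling, SGNS
# training (optionally initialised from pre-trained word vectors), and
# optional retrofitting on a protein-interaction graph.  Which of the four
# model variants is fitted follows from which optional inputs are supplied:
#
#   basic              neither `pretrained` nor `graph`
#   pretrained-init    `pretrained` only
#   retrofitted        `graph` only
#   pretrained-init + retrofitted   both

#' Fit a distributed representation of gene-level mutations
#'
#' Trains skip-gram-with-negative-sampling embeddings of mutated genes from
#' per-sample co-occurrence, treating the genes mutated in the same tumour
#' sample as each other's context.  The embedding lookup layer can be
#' initialised from word vectors pre-trained on a literature corpus, and the
#' trained vectors can be retrofitted onto a protein-interaction network so
#' that one-hop neighbours end up with similar representations.
#'
#' @param profiles a [mutation_profiles] object (see [read_profiles()]).
#' @param pretrained optional matrix of pre-trained token vectors (row names
#'   are tokens; see [read_vectors()]); its dimension must equal `dim`.
#' @param graph optional undirected [igraph::igraph] interaction network
#'   (see [read_edge_list()]).
#' @param dim embedding dimension (default 300).
#' @param draws_per_sample,draw_size context subsampling parameters, see
#'   [sample_profile_contexts()] (defaults 10 and 10).
#' @param negatives,epochs,lr_initial,lr_final,min_count SGNS training
#'   parameters, see [sgns_config()].
#' @param retrofit_iterations sweeps of the retrofitting solver (default 10).
#' @param seed single integer governing every stochastic step.
#' @return an object of class `mutation_embedding` with components
#'   `vectors` (the final gene-by-dimension matrix), `vectors_raw` (before
#'   retrofitting; identical to `vectors` when no graph is given), `model`
#'   (the underlying `embedding_model`), `counts`, `variant`,
#'   `n_initialized`, `n_pairs`, `call`.
#' @examples
#' cohort <- simulate_cohort(n_samples = 60, n_genes = 80, seed = 1)
#' fit <- mutation_embedding(cohort$profiles, dim = 16, epochs = 2, seed = 1)
#' fit
#' head(coef(fit)[, 1:4])
#' @export
mutation_embedding <- function(profiles, pretrained = NULL, graph = NULL,
                               dim = 300L, draws_per_sample = 10L,
                               draw_size = 10L, negatives = 5L, epochs = 5L,
                               lr_initial = 0.025, lr_final = 1e-4,
                               min_count = 1L, retrofit_iterations = 10L,
                               seed = 1L) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  config <- sgns_config(dim = dim, negatives = negatives, epochs = epochs,
                        lr_initial = lr_initial, lr_final = lr_final,
                        min_count = min_count, seed = seed)
  vb <- build_vocab(profiles, min_count = min_count)
  sets <- sample_profile_contexts(profiles, vb$vocab,
                                  draws_per_sample = draws_per_sample,
                                  draw_size = draw_size, seed = seed)
  pairs <- contexts_to_pairs(sets)
  noise <- noise_distribution(vb$counts)
  model <- train_sgns(pairs, vb$vocab, config = config, noise = noise,
                      init = pretrained)
  vectors_raw <- model$U
  vectors <- vectors_raw
  if (!is.null(graph)) {
    vectors <- retrofit_vectors(vectors_raw, graph = graph,
                                iterations = retrofit_iterations)
  }
  variant <- paste0(
    "sgns",
    if (!is.null(pretrained)) "+pretrained-init" else "",
    if (!is.null(graph)) "+retrofit" else ""
  )
  structure(
    list(vectors = vectors, vectors_raw = vectors_raw, model = model,
         counts = vb$counts, variant = variant,
         n_initialized = model$n_initialized, n_pairs = nrow(pairs),
         config = config, retrofit_iterations =
           if (!is.null(graph)) attr(vectors, "iterations") else 0L,
         call = match.call()),
    class = "mutation_embedding"
  )
}

#' @export
print.mutation_embedding <- function(x, ...) {
  cat("Mutation embedding (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d genes embedded in %d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  cat(sprintf("  trained on %d (center, context) pairs, %d epochs, seed %d\n",
              x$n_pairs, x$config$epochs, x$config$seed))
  if (x$n_initialized > 0L) {
    cat(sprintf("  %d rows initialised from pre-trained vectors\n", x$n_initialized))
  }
  invisible(x)
}

#' @export
summary.mutation_embedding <- function(object, ...) {
  norms <- sqrt(rowSums(object$vectors^2))
  out <- list(
    variant = object$variant,
    n_genes = nrow(object$vectors),
    dim = ncol(object$vectors),
    n_pairs = object$n_pairs,
    n_initialized = object$n_initialized,
    retrofit_iterations = object$retrofit_iterations,
    count_summary = summary(as.numeric(object$counts)),
    norm_summary = summary(norms),
    config = object$config
  )
  class(out) <- "summary.mutation_embedding"
  out
}

#' @export
print.summary.mutation_embedding <- function(x, ...) {
  cat("Mutation embedding (", x$variant, ")\n", sep = "")
  cat(sprintf("  genes: %d   dimension: %d   training pairs: %d\n",
              x$n_genes, x$dim, x$n_pairs))
  cat(sprintf("  pre-initialised rows: %d   retrofit sweeps: %d\n",
              x$n_initialized, x$retrofit_iterations))
  cat("  per-gene sample counts:\n"); print(x$count_summary)
  cat("  vector norms:\n"); print(x$norm_summary)
  invisible(x)
}

#' Extract embedding vectors
#'
#' @param object a `mutation_embedding`.
#' @param raw return the pre-retrofit vectors instead (default `FALSE`).
#' @param ... unused.
#' @return numeric gene-by-dimension matrix.
#' @export
coef.mutation_embedding <- function(object, raw = FALSE, ...) {
  if (raw) object$vectors_raw else object$vectors
}

#' Embed genes or new samples
#'
#' For a character vector of gene symbols, returns their embedding rows
#' (case-insensitive; unknown genes give `NA` rows).  For a
#' [mutation_profiles] object, returns one vector per sample: the mean of
#' the member genes' vectors, a simple sample-level representation.
#'
#' @param object a `mutation_embedding`.
#' @param newdata character vector of genes or a [mutation_profiles].
#' @param ... unused.
#' @return numeric matrix, one row per requested gene or sample.
#' @export
predict.mutation_embedding <- function(object, newdata, ...) {
  V <- object$vectors
  if (inherits(newdata, "mutation_profiles")) {
    out <- t(vapply(unclass(newdata), function(g) {
      i <- match(toupper(g), rownames(V))
      i <- i[!is.na(i)]
      if (length(i) == 0L) rep(NA_real_, ncol(V)) else colMeans(V[i, , drop = FALSE])
    }, numeric(ncol(V))))
    rownames(out) <- names(newdata)
    out
  } else {
    i <- match(toupper(as.character(newdata)), rownames(V))
    out <- V[ifelse(is.na(i), 1L, i), , drop = FALSE]
    out[is.na(i), ] <- NA_real_
    rownames(out) <- toupper(as.character(newdata))
    out
  }
}

#' Nearest genes by cosine similarity
#'
#' @param object a `mutation_embedding`.
#' @param gene a gene symbol present in the embedding.
#' @param n how many neighbours to return (default 10).
#' @return named numeric vector of cosine similarities, most similar first.
#' @export
nearest_genes <- function(object, gene, n = 10L) {
  stopifnot(inherits(object, "mutation_embedding"))
  V <- object$vectors
  i <- match(toupper(gene), rownames(V))
  if (is.na(i)) abort_validation(sprintf("gene %s is not embedded", gene))
  norms <- sqrt(rowSums(V^2))
  sims <- as.numeric(V %*% V[i, ]) / (norms * norms[i])
  sims[i] <- -Inf
  ord <- order(sims, decreasing = TRUE)[seq_len(min(n, nrow(V) - 1L))]
  stats::setNames(sims[ord], rownames(V)[ord])
}

#' Plot an embedding on its leading principal components
#'
#' Scatter of the genes on PC1/PC2, optionally coloured by a label table
#' (drivers red, passengers blue).
#'
#' @param x a `mutation_embedding`.
#' @param labels optional named character vector gene -> label.
#' @param genes optional subset of genes to plot (default: all).
#' @param ... passed to [graphics::plot].
#' @return invisibly, the [pca_project()] result.
#' @export
plot.mutation_embedding <- function(x, labels = NULL, genes = NULL, ...) {
  V <- x$vectors
  if (!is.null(genes)) V <- V[intersect(toupper(genes), rownames(V)), , drop = FALSE]
  proj <- pca_project(V, 2L)
  col <- rep("grey40", nrow(V))
  if (!is.null(labels)) {
    lab <- labels[rownames(V)]
    col[lab %in% c("known_driver", "predicted_driver")] <- "red"
    col[lab == "predicted_passenger"] <- "blue"
  }
  graphics::plot(
    proj$coordinates[, 1L], proj$coordinates[, 2L], col = col, pch = 19,
    xlab = sprintf("PC1 (%.1f%%)", 100 * proj$explained_variance_ratio[1L]),
    ylab = sprintf("PC2 (%.1f%%)", 100 * proj$explained_variance_ratio[2L]),
    ...
  )
  invisible(proj)
}
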