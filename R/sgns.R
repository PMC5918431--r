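# Skip-gram with negative sampling (SGNS).
#
# For a training pair (e_i, e_j) and a set D_i of negatives drawn from a
# unigram^0.75 noise distribution, the per-pair loss is
#
#   L = -log sigma(u_i' v_j) - sum_{l in D_i} log(1 - sigma(u_i' v_l))
#
# where u_i is row i of the embedding lookup matrix U and v_j is row j of the
# output matrix V.  Minimising L by SGD maximises the occurrence probability
# of contextual entities and minimises that of non-contextual ones.  The SGD
# inner loop lives in compiled code (src/sgns.cpp) with its own
# deterministic RNG, so training is bit-reproducible under a single seed.

#' SGNS training configuration
#'
#' @param dim embedding dimension (default 300).
#' @param negatives negatives drawn per positive pair (default 5).
#' @param epochs passes over the training pairs (default 5).
#' @param lr_initial,lr_final linear learning-rate schedule endpoints
#'   (defaults 0.025 to 0.0001, the usual word2vec schedule).
#' @param min_count minimum entity count for vocabulary inclusion.
#' @param seed integer seed for initialisation and negative sampling.
#' @return a list of class `sgns_config`.
#' @export
sgns_config <- function(dim = 300L, negatives = 5L, epochs = 5L,
                        lr_initial = 0.025, lr_final = 1e-4,
                        min_count = 1L, seed = 1L) {
  if (dim < 1L) abort_config("dim must be >= 1")
  if (negatives < 1L) abort_config("negatives must be >= 1")
  if (epochs < 0L) abort_config("epochs must be >= 0")
  if (!(lr_initial >= lr_final && lr_final > 0)) {
    abort_config("need lr_initial >= lr_final > 0")
  }
  if (min_count < 1L) abort_config("min_count must be >= 1")
  structure(
    list(dim = as.integer(dim), negatives = as.integer(negatives),
         epochs = as.integer(epochs), lr_initial = lr_initial,
         lr_final = lr_final, min_count = as.integer(min_count),
         seed = as.integer(seed)),
    class = "sgns_config"
  )
}

#' Build the model vocabulary from profiles or a corpus
#'
#' Entities occurring fewer than `min_count` times are excluded.  Order is
#' deterministic: count descending, ties lexicographic.
#'
#' @param x a [mutation_profiles] object or a list of character vectors
#'   (tokenized sentences).
#' @param min_count minimum occurrence count (default 1).
#' @return list with `vocab` (character) and `counts` (named integer,
#'   aligned with `vocab`).
#' @export
build_vocab <- function(x, min_count = 1L) {
  if (min_count < 1L) abort_config("min_count must be >= 1")
  tokens <- unlist(unclass(x), use.names = FALSE)
  tab <- table(tokens)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) abort_config("vocabulary is empty after min_count filtering")
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  list(vocab = names(counts), counts = counts)
}

#' Negative-sampling noise distribution
#'
#' Unigram counts raised to the 3/4 power, renormalised:
#' `p_i = count_i^power / sum_k count_k^power`.
#'
#' @param counts positive entity counts (vocabulary order).
#' @param power exponent (default 0.75).
#' @return numeric probability vector summing to 1.
#' @export
noise_distribution <- function(counts, power = 0.75) {
  counts <- as.numeric(counts)
  if (any(counts <= 0) || !all(is.finite(counts))) {
    abort_validation("counts must be positive and finite")
  }
  w <- counts^power
  w / sum(w)
}

#' SGNS loss and exact gradients for one training pair
#'
#' Reference implementation of the per-pair objective used for testing the
#' compiled trainer: returns the loss together with its analytic gradients
#' with respect to the center vector, the positive context vector and each
#' negative vector.
#'
#' @param u center (input) vector `u_i`.
#' @param v_pos positive context (output) vector `v_j`.
#' @param v_neg matrix of negative vectors, one per row.
#' @return list with `loss`, `grad_u`, `grad_v_pos`, `grad_v_neg`.
#' @export
sgns_loss_grad <- function(u, v_pos, v_neg = matrix(numeric(0), 0L, length(u))) {
  stopifnot(length(v_pos) == length(u), ncol(v_neg) == length(u))
  sig <- function(x) 1 / (1 + exp(-x))
  # log(sigma(x)) computed overflow-safe as -log1p(exp(-x)) split by sign
  log_sig <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
  s_pos <- sum(u * v_pos)
  s_neg <- as.numeric(v_neg %*% u)
  loss <- -log_sig(s_pos) - sum(log_sig(-s_neg))
  g_pos <- sig(s_pos) - 1            # d loss / d s_pos
  g_neg <- sig(s_neg)                # d loss / d s_neg_l
  grad_u <- g_pos * v_pos +
    if (nrow(v_neg)) as.numeric(t(v_neg) %*% g_neg) else 0
  list(
    loss = loss,
    grad_u = grad_u,
    grad_v_pos = g_pos * u,
    grad_v_neg = if (nrow(v_neg)) outer(g_neg, u) else v_neg
  )
}

#' Train an SGNS embedding model
#'
#' Runs single-threaded SGD over the training pairs in their given order for
#' `config$epochs` passes, drawing `config$negatives` negatives per pair
#' from `noise` (i.i.d., rejecting the pair's own positive context).  The
#' learning rate decays linearly from `lr_initial` to `lr_final` over all
#' updates.  U rows start uniform in (-0.5/dim, +0.5/dim), V at zero; rows
#' of U whose token appears in `init` (case-insensitive) are overwritten by
#' the pre-trained vector before training.
#'
#' @param pairs integer matrix with columns center, context (vocab indices).
#' @param vocab character vector of entity tokens.
#' @param config an [sgns_config()].
#' @param noise probability vector over the vocabulary (defaults to uniform).
#' @param init optional pre-trained vector matrix (token row names) used to
#'   initialise the embedding lookup layer, see [init_from_pretrained()].
#' @return an object of class `embedding_model`: list with `vocab`, `U`,
#'   `V`, `dim`, `config`, and `n_initialized` (rows seeded from `init`).
#' @export
train_sgns <- function(pairs, vocab, config = sgns_config(), noise = NULL,
                       init = NULL) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  nv <- length(vocab)
  if (nv < 2L) abort_config("need a vocabulary of at least 2 entities")
  if (nrow(pairs) > 0L && (min(pairs) < 1L || max(pairs) > nv)) {
    abort_validation("pair indices outside the vocabulary")
  }
  if (is.null(noise)) noise <- rep(1 / nv, nv)
  if (length(noise) != nv) abort_config("noise distribution length != vocabulary size")
  d <- config$dim
  U <- with_seed(config$seed,
    matrix(stats::runif(nv * d, -0.5 / d, 0.5 / d), nrow = nv, ncol = d)
  )
  rownames(U) <- vocab
  V <- matrix(0, nrow = nv, ncol = d, dimnames = list(vocab, NULL))
  model <- structure(
    list(vocab = vocab, U = U, V = V, dim = d, config = config,
         n_initialized = 0L),
    class = "embedding_model"
  )
  if (!is.null(init)) model <- init_from_pretrained(model, init)
  if (config$epochs > 0L && nrow(pairs) > 0L) {
    fit <- sgns_train_cpp(
      model$U, model$V,
      as.integer(pairs[, 1L]) - 1L, as.integer(pairs[, 2L]) - 1L,
      config$epochs, config$lr_initial, config$lr_final,
      config$negatives, as.numeric(noise), config$seed
    )
    if (!all(is.finite(fit$U)) || !all(is.finite(fit$V))) {
      abort(
        "non-finite parameters during SGNS training; lower lr_initial",
        "mutembed_numeric_error"
      )
    }
    model$U <- fit$U; model$V <- fit$V
    dimnames(model$U) <- dimnames(model$V) <- list(vocab, NULL)
  }
  model
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("SGNS embedding model: %d entities, dimension %d (%d rows pre-initialised)\n",
              length(x$vocab), x$dim, x$n_initialized))
  invisible(x)
}

#' Initialise the embedding lookup layer from pre-trained vectors
#'
#' Rows of `U` whose token matches a row of `table` (case-insensitive) are
#' overwritten by the pre-trained vector; all other rows keep their random
#' initialisation.  The output matrix `V` is untouched.
#'
#' @param model an `embedding_model`.
#' @param table numeric matrix of pre-trained vectors with token row names.
#' @return the model, with `n_initialized` set to the number of rows
#'   overwritten.
#' @export
init_from_pretrained <- function(model, table) {
  stopifnot(inherits(model, "embedding_model"))
  if (nrow(table) == 0L) {
    model$n_initialized <- 0L
    return(model)
  }
  if (ncol(table) != model$dim) {
    abort_config(sprintf("pre-trained vectors have dimension %d, model has %d",
                         ncol(table), model$dim))
  }
  hit <- match(toupper(model$vocab), toupper(rownames(table)))
  found <- which(!is.na(hit))
  if (length(found)) model$U[found, ] <- table[hit[found], , drop = FALSE]
  model$n_initialized <- length(found)
  model
}

#' Full-softmax skip-gram objective (small-vocabulary oracle)
#'
#' Evaluates the exact mean log-likelihood
#' `J(U, V) = mean over pairs of log softmax(u_i' V)[j]`, enumerating the
#' whole vocabulary in the denominator.  Intended for small vocabularies as
#' an independent check that SGNS training improves the model it is a
#' surrogate for.
#'
#' @param model an `embedding_model`.
#' @param pairs integer matrix with columns center, context.
#' @return mean log-probability (<= 0).
#' @export
softmax_objective <- function(model, pairs) {
  stopifnot(inherits(model, "embedding_model"), is.matrix(pairs), ncol(pairs) == 2L)
  scores <- model$U %*% t(model$V)          # |E| x |E|; row i = u_i' v_.
  m <- apply(scores, 1L, max)
  logZ <- m + log(rowSums(exp(scores - m)))
  mean(scores[cbind(pairs[, 1L], pairs[, 2L])] - logZ[pairs[, 1L]])
}
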