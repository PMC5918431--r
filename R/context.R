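# Conversion of mutation profiles (and, for pre-training, tokenized
# sentences) into (center, context) training pairs.
#
# Mutations within a tumour sample carry no meaningful order, so a sliding
# window makes no sense there.  Instead each sample is subsampled without
# replacement a fixed number of times with a fixed draw size, and every gene
# in a draw is context for every other gene in the same draw.  Because the
# procedure is identical regardless of how many mutations a sample carries,
# hypermutated (noisy) samples contribute each of their genes rarely, while
# small samples are used in full on every draw.

#' Sample context sets from mutation profiles
#'
#' For each sample, performs `draws_per_sample` random draws without
#' replacement of `draw_size` in-vocabulary genes (the whole gene set when
#' the sample has fewer).  Samples with fewer than two in-vocabulary genes
#' yield no context and are skipped with a warning.
#'
#' @param profiles a [mutation_profiles] object.
#' @param vocab character vector of embedded gene symbols; genes outside it
#'   are dropped before sampling.
#' @param draws_per_sample number of draws per sample (default 10).
#' @param draw_size genes per draw (default 10).
#' @param seed integer seed; the draw sequence is deterministic given it.
#' @return list of integer vectors of vocabulary indices, one per draw.
#' @export
sample_profile_contexts <- function(profiles, vocab, draws_per_sample = 10L,
                                    draw_size = 10L, seed = 1L) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  if (draws_per_sample < 1L) abort_config("draws_per_sample must be >= 1")
  if (draw_size < 2L) abort_config("draw_size must be >= 2")
  idx <- lapply(unclass(profiles), function(g) {
    i <- match(g, vocab)
    i[!is.na(i)]
  })
  usable <- lengths(idx) >= 2L
  if (any(!usable)) {
    warning(sprintf("%d sample(s) with < 2 in-vocabulary genes skipped", sum(!usable)))
  }
  idx <- idx[usable]
  with_seed(seed, {
    out <- vector("list", length(idx) * draws_per_sample)
    pos <- 0L
    for (genes in idx) {
      size <- min(draw_size, length(genes))
      for (r in seq_len(draws_per_sample)) {
        pos <- pos + 1L
        out[[pos]] <- genes[sample.int(length(genes), size)]
      }
    }
    out
  })
}

#' Expand context sets into ordered training pairs
#'
#' Every member of a context set is a center predicting every other member,
#' so a set of size s yields all s(s-1) ordered pairs.
#'
#' @param sets list of integer vectors as returned by
#'   [sample_profile_contexts()]; each must have length >= 2.
#' @return integer matrix with columns `center`, `context`.
#' @export
contexts_to_pairs <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("center", "context"))))
  }
  if (any(lengths(sets) < 2L)) abort_validation("every context set needs at least 2 members")
  pieces <- lapply(sets, function(s) {
    n <- length(s)
    cbind(rep(s, each = n - 1L),
          unlist(lapply(seq_len(n), function(i) s[-i]), use.names = FALSE))
  })
  out <- do.call(rbind, pieces)
  dimnames(out) <- list(NULL, c("center", "context"))
  out
}

#' Sliding-window training pairs from a tokenized corpus
#'
#' Standard skip-gram contexts for pre-training on text: for each position t
#' in a sentence, all tokens within `window` positions are contexts.
#' Out-of-vocabulary tokens are skipped both as centers and contexts.
#'
#' @param sentences list of character vectors (tokenized sentences).
#' @param vocab character vector of tokens in the model vocabulary.
#' @param window window half-width (>= 1).
#' @return integer matrix with columns `center`, `context` (vocab indices).
#' @export
window_corpus_contexts <- function(sentences, vocab, window = 5L) {
  if (window < 1L) abort_config("window must be >= 1")
  pieces <- lapply(sentences, function(toks) {
    i <- match(toks, vocab)
    i <- i[!is.na(i)]
    n <- length(i)
    if (n < 2L) return(NULL)
    centers <- contexts <- vector("list", n)
    for (t in seq_len(n)) {
      lo <- max(1L, t - window); hi <- min(n, t + window)
      ctx <- i[setdiff(lo:hi, t)]
      centers[[t]] <- rep(i[t], length(ctx))
      contexts[[t]] <- ctx
    }
    cbind(unlist(centers, use.names = FALSE), unlist(contexts, use.names = FALSE))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  out <- if (length(pieces)) do.call(rbind, pieces) else matrix(integer(0), ncol = 2L)
  dimnames(out) <- list(NULL, c("center", "context"))
  out
}
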