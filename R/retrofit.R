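# Graph retrofitting of trained vectors.
#
# Given trained vectors Q~ and, for each entity i, a set S_i of one-hop
# interaction-network neighbours, retrofitting seeks vectors Q balancing
# fidelity to the trained vector against agreement with neighbours:
#
#   J(Q, Q~) = sum_i ( alpha_i ||q_i - q~_i||^2
#                      + sum_{j in S_i} beta_ij ||q_i - q_j||^2 )
#
# with alpha_i = 1 and beta_ij = |S_i|^-1 by default.  The solver is the
# published iterative update
#
#   q_i <- (alpha_i q~_i + sum_{j in S_i} beta_ij q_j) / (alpha_i + sum_j beta_ij)
#
# swept cyclically.  With the default weights this iteration is Gauss-Seidel
# on the symmetric positive-definite system (2D - A) Q = D Q~ (D the degree
# matrix, A the adjacency matrix), so it converges monotonically in the
# convex quadratic F(Q) = sum_i |S_i| ||q_i - q~_i||^2 + sum_{edges}
# ||q_i - q_j||^2.  Note that F is a degree-reweighted form of J: because
# the beta_ij weights are asymmetric, J itself is not guaranteed to fall at
# every sweep, although the iteration's fixed point is exactly the one the
# update equation defines.  Entities with no neighbours keep their trained
# vector unchanged.

#' One-hop neighbour sets from an interaction graph
#'
#' @param graph an undirected [igraph::igraph] (e.g. from
#'   [read_edge_list()]); vertex names are gene symbols.
#' @param vocab character vector of embedded tokens.
#' @return named list over `vocab`: for each token, the character vector of
#'   its graph neighbours that are themselves in `vocab` (empty when the
#'   token is absent from the graph).
#' @export
build_neighbor_sets <- function(graph, vocab) {
  out <- stats::setNames(rep(list(character(0)), length(vocab)), vocab)
  if (igraph::vcount(graph) == 0L) return(out)
  vnames <- igraph::V(graph)$name
  present <- intersect(vocab, vnames)
  for (g in present) {
    nb <- igraph::neighbors(graph, g)$name
    out[[g]] <- intersect(nb, vocab)
  }
  out
}

resolve_beta <- function(neighbor_sets, beta) {
  sizes <- lengths(neighbor_sets)
  if (is.null(beta)) {
    ifelse(sizes > 0L, 1 / pmax(sizes, 1L), 0)
  } else {
    rep(as.numeric(beta), length(neighbor_sets))
  }
}

#' Retrofit vectors onto an interaction graph
#'
#' Iteratively pulls each vector toward the mean of its one-hop neighbours
#' while anchoring it to its trained value (see the objective above).  Stops
#' after `iterations` sweeps or when the largest per-coordinate change in a
#' sweep falls below `tol`.
#'
#' @param vectors numeric matrix of trained vectors with token row names.
#' @param neighbor_sets named list as from [build_neighbor_sets()]; or pass
#'   `graph` instead.
#' @param graph optional [igraph::igraph]; used to build neighbour sets when
#'   `neighbor_sets` is not given.
#' @param alpha anchor weight `alpha_i` (scalar, default 1).
#' @param beta pairwise weight `beta_ij`: `NULL` (default) for the
#'   `|S_i|^-1` rule, or a single number applied to every directed pair.
#' @param iterations maximum sweeps (default 10).
#' @param tol early-stopping threshold on the max absolute change.
#' @return matrix of retrofitted vectors (same shape and row names); the
#'   number of sweeps performed is in attribute `"iterations"`.
#' @export
retrofit_vectors <- function(vectors, neighbor_sets = NULL, graph = NULL,
                             alpha = 1, beta = NULL, iterations = 10L,
                             tol = 1e-6) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (iterations < 1L) abort_config("iterations must be >= 1")
  if (alpha <= 0) abort_config("alpha must be > 0")
  if (is.null(neighbor_sets)) {
    if (is.null(graph)) abort_config("supply neighbor_sets or graph")
    neighbor_sets <- build_neighbor_sets(graph, rownames(vectors))
  }
  vocab <- rownames(vectors)
  nb_idx <- lapply(vocab, function(g) {
    s <- neighbor_sets[[g]]
    if (is.null(s)) integer(0) else {
      i <- match(s, vocab)
      i[!is.na(i) & vocab[i] != g]
    }
  })
  beta_i <- resolve_beta(stats::setNames(nb_idx, vocab), beta)
  Q <- vectors
  it <- 0L
  for (it in seq_len(iterations)) {
    delta <- 0
    for (i in seq_along(vocab)) {
      s <- nb_idx[[i]]
      if (length(s) == 0L) next
      b <- beta_i[i]
      new_q <- (alpha * vectors[i, ] + b * colSums(Q[s, , drop = FALSE])) /
        (alpha + b * length(s))
      delta <- max(delta, max(abs(new_q - Q[i, ])))
      Q[i, ] <- new_q
    }
    if (delta < tol) break
  }
  attr(Q, "iterations") <- it
  Q
}

#' Retrofitting objective
#'
#' Evaluates `J(Q, Q~)` exactly as defined above: the anchor terms plus one
#' `beta_ij ||q_i - q_j||^2` term for every *directed* neighbour pair (each
#' undirected edge contributes from both endpoints, generally with
#' different weights under the `|S_i|^-1` rule).
#'
#' @param q retrofitted vectors (matrix, token row names).
#' @param q_tilde trained vectors, same shape and row order.
#' @param neighbor_sets named list as from [build_neighbor_sets()].
#' @inheritParams retrofit_vectors
#' @return the objective value (>= 0).
#' @export
retrofit_objective <- function(q, q_tilde, neighbor_sets, alpha = 1, beta = NULL) {
  stopifnot(is.matrix(q), identical(dim(q), dim(q_tilde)))
  vocab <- rownames(q)
  nb_idx <- lapply(vocab, function(g) {
    s <- neighbor_sets[[g]]
    if (is.null(s)) integer(0) else match(intersect(s, vocab), vocab)
  })
  beta_i <- resolve_beta(stats::setNames(nb_idx, vocab), beta)
  J <- alpha * sum((q - q_tilde)^2)
  for (i in seq_along(vocab)) {
    s <- nb_idx[[i]]
    if (length(s)) {
      diffs <- sweep(q[s, , drop = FALSE], 2L, q[i, ])
      J <- J + unname(beta_i[i]) * sum(diffs^2)
    }
  }
  unname(J)
}
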