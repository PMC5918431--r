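# Cluster enrichment statistics: hypergeometric upper-tail test for driver
# enrichment, most-enriched-cluster selection, candidate extraction, and
# one-sided Fisher / Benjamini-Hochberg gene-set over-representation.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with population size `N`, `K` successes in
#' the population, and `n` draws: the probability of seeing at least `k`
#' labelled items in an n-item cluster by chance.  Delegates to
#' [stats::phyper], which works on log scale internally, so extreme tails
#' (p ~ 1e-50) are computed stably.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n number of draws (cluster size).
#' @param k observed successes in the draw.
#' @return the upper-tail p-value.
#' @export
hypergeom_sf <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    abort_validation("need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Select the cluster most enriched in a label class
#'
#' Picks the cluster containing the most genes of `label_class`; ties are
#' broken by smaller hypergeometric p-value, then by lower cluster id.  The
#' population for the test is all clustered (embedded) genes; `K` is the
#' number of them carrying the label.
#'
#' @param partition named integer vector: cluster assignment per gene (as
#'   from [kmeans_cluster()]).
#' @param labels named character vector gene -> label (see [read_labels()]).
#' @param label_class label value that counts as a success (default
#'   `"known_driver"`); may be a vector, e.g.
#'   `c("known_driver", "predicted_driver")`.
#' @return list with `cluster` (the selected id), `genes` (its members) and
#'   `result`: a one-row data.frame with `N`, `K`, `n`, `k`, `p_value`.
#' @export
most_enriched_cluster <- function(partition, labels,
                                  label_class = "known_driver") {
  stopifnot(!is.null(names(partition)))
  hit <- names(partition)[names(partition) %in% names(labels)[labels %in% label_class]]
  if (length(hit) == 0L) {
    abort_validation("no clustered gene carries the requested label class")
  }
  N <- length(partition)
  K <- length(hit)
  ids <- sort(unique(partition))
  k_in <- vapply(ids, function(cl) sum(partition[hit] == cl), 0L)
  n_in <- vapply(ids, function(cl) sum(partition == cl), 0L)
  p <- mapply(function(n, k) hypergeom_sf(N, K, n, k), n_in, k_in)
  ord <- order(-k_in, p, ids)
  best <- ord[1L]
  list(
    cluster = ids[best],
    genes = names(partition)[partition == ids[best]],
    result = data.frame(
      N = N, K = K, n = n_in[best], k = k_in[best], p_value = p[best]
    )
  )
}

#' Candidate driver genes in a cluster
#'
#' Members of the cluster carrying neither a `known_driver` nor a
#' `predicted_driver` label: genes placed among the drivers by the embedding
#' but not referred to as drivers in the database.
#'
#' @param genes character vector of cluster member genes.
#' @param labels named character vector gene -> label.
#' @return lexicographically sorted character vector of candidates.
#' @export
extract_candidates <- function(genes, labels) {
  drivers <- names(labels)[labels %in% c("known_driver", "predicted_driver")]
  sort(setdiff(genes, drivers))
}

#' One-sided Fisher exact test for over-representation
#'
#' For the 2x2 table `[[a, b], [c, d]]` (a = in cluster and in set), the
#' one-sided (greater) p-value equals the hypergeometric upper tail with
#' population `a+b+c+d`, `a+b` successes and `a+c` draws.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return the one-sided p-value.
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort_validation("cell counts must be non-negative")
  hypergeom_sf(N = a + b + c + d, K = a + b, n = a + c, k = a)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (via [stats::p.adjust]), returned
#' in input order.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation of a cluster
#'
#' One-sided Fisher test per gene set against a background universe, with
#' Benjamini-Hochberg correction across sets.  Overlap is reported as
#' `members-in-cluster / set-size-in-background`.
#'
#' @param genes character vector of cluster member genes.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param background character vector of background genes; must contain all
#'   of `genes` (typically the embedded vocabulary).
#' @return data.frame with columns `set`, `p_value`, `adj_p_value`,
#'   `overlap`, sorted by adjusted then raw p-value.
#' @export
geneset_enrichment <- function(genes, sets, background) {
  if (length(background) == 0L) abort_validation("background must be non-empty")
  background <- unique(toupper(background))
  genes <- unique(toupper(genes))
  if (!all(genes %in% background)) {
    abort_validation("background must contain every cluster gene")
  }
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(toupper(sets[[nm]])), background)
    a <- length(intersect(genes, set))
    b <- length(genes) - a
    cc <- length(set) - a
    d <- length(background) - a - b - cc
    data.frame(
      set = nm,
      p_value = fisher_exact_greater(a, b, cc, d),
      overlap = sprintf("%d/%d", a, length(set)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- bh_adjust(out$p_value)
  out <- out[order(out$adj_p_value, out$p_value, out$set), c("set", "p_value", "adj_p_value", "overlap")]
  rownames(out) <- NULL
  out
}
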