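# Synthetic cohorts, interaction networks and gene-mention corpora with
# planted driver structure, so every pipeline stage is testable end to end
# without external downloads.
#
# The cohort generator emulates the salient features of a pan-cancer
# mutation callset: a small number of recurrently co-mutated driver modules
# expressed by a fraction of samples, a large pool of passenger genes hit
# essentially at random, and heavy-tailed per-sample mutation burdens (some
# samples carry a handful of mutations, hypermutated ones carry hundreds) —
# modelled by a Pareto(alpha = 2) multiplier on the passenger count, which
# keeps the mean burden finite while producing occasional extreme samples.

default_modules <- function(n_modules = 2L, module_size = 20L) {
  lapply(seq_len(n_modules), function(m) {
    sprintf("DRV%d_%02d", m, seq_len(module_size))
  })
}

#' Simulate a mutation cohort with planted driver modules
#'
#' Each sample expresses each driver module independently with probability
#' `module_penetrance`; an expressed module contributes each of its genes
#' with probability 0.9.  Passengers are drawn uniformly from the
#' non-module genes, `round(passenger_rate * Pareto(alpha = 2))` of them
#' (capped at the passenger pool).  A sample that would come out empty gets
#' one uniformly chosen gene so that every profile is non-empty.
#'
#' @param n_samples number of samples (default 400).
#' @param n_genes total gene universe (default 500); must cover the modules.
#' @param driver_modules list of disjoint character vectors of driver genes;
#'   default: two modules of 20 genes.
#' @param module_penetrance probability a sample expresses a module
#'   (default 0.5).
#' @param passenger_rate expected passengers per sample before the
#'   heavy-tailed multiplier (default 5).
#' @param seed integer seed.
#' @return list with `profiles` ([mutation_profiles]), `labels` (named
#'   character vector: module genes `known_driver`, all others
#'   `predicted_passenger`), `modules`, and `genes` (the full universe).
#' @export
simulate_cohort <- function(n_samples = 400L, n_genes = 500L,
                            driver_modules = NULL,
                            module_penetrance = 0.5, passenger_rate = 5,
                            seed = 1L) {
  if (is.null(driver_modules)) driver_modules <- default_modules()
  driver_modules <- lapply(driver_modules, toupper)
  module_genes <- unlist(driver_modules, use.names = FALSE)
  if (anyDuplicated(module_genes)) abort_validation("driver modules must be disjoint")
  if (n_genes < length(module_genes)) {
    abort_validation("n_genes must cover the driver modules")
  }
  if (module_penetrance < 0 || module_penetrance > 1) {
    abort_validation("module_penetrance must lie in [0, 1]")
  }
  if (passenger_rate < 0) abort_validation("passenger_rate must be >= 0")
  if (n_samples < 1L) abort_validation("n_samples must be >= 1")
  n_pass <- n_genes - length(module_genes)
  passenger_genes <- if (n_pass > 0L) sprintf("PSG%04d", seq_len(n_pass)) else character(0)
  genes <- c(module_genes, passenger_genes)
  samples <- with_seed(seed, {
    lapply(seq_len(n_samples), function(s) {
      g <- character(0)
      for (mod in driver_modules) {
        if (stats::runif(1) < module_penetrance) {
          g <- c(g, mod[stats::runif(length(mod)) < 0.9])
        }
      }
      if (passenger_rate > 0 && n_pass > 0L) {
        # Pareto(alpha = 2) via inverse CDF; support [1, Inf), mean 2
        mult <- (1 - stats::runif(1))^(-1 / 2)
        count <- min(round(passenger_rate * mult), n_pass)
        if (count > 0) g <- c(g, passenger_genes[sample.int(n_pass, count)])
      }
      if (length(g) == 0L) g <- genes[sample.int(length(genes), 1L)]
      g
    })
  })
  names(samples) <- sprintf("S%04d", seq_len(n_samples))
  labels <- stats::setNames(
    c(rep("known_driver", length(module_genes)), rep("predicted_passenger", n_pass)),
    genes
  )
  list(
    profiles = mutation_profiles(samples),
    labels = labels,
    modules = driver_modules,
    genes = genes
  )
}

#' Simulate a modular protein-interaction network
#'
#' Stochastic block model on the gene universe: gene pairs within the same
#' driver module are connected with probability `intra_p`, all other pairs
#' (cross-module, passenger-passenger, driver-passenger) with probability
#' `inter_p`.
#'
#' @param modules list of character vectors (the blocks), e.g.
#'   `simulate_cohort()$modules`.
#' @param genes full gene universe, e.g. `simulate_cohort()$genes`.
#' @param intra_p within-module edge probability (default 0.3).
#' @param inter_p background edge probability (default 0.01); must satisfy
#'   `0 <= inter_p <= intra_p <= 1`.
#' @param seed integer seed.
#' @return an undirected [igraph::igraph] on `genes`.
#' @export
simulate_ppi <- function(modules, genes, intra_p = 0.3, inter_p = 0.01,
                         seed = 1L) {
  if (!(inter_p >= 0 && inter_p <= intra_p && intra_p <= 1)) {
    abort_validation("need 0 <= inter_p <= intra_p <= 1")
  }
  genes <- toupper(genes)
  block <- rep(0L, length(genes))
  names(block) <- genes
  for (m in seq_along(modules)) block[toupper(modules[[m]])] <- m
  pairs <- utils::combn(length(genes), 2L)
  same <- block[pairs[1L, ]] > 0L & block[pairs[1L, ]] == block[pairs[2L, ]]
  p_edge <- ifelse(same, intra_p, inter_p)
  keep <- with_seed(seed, stats::runif(ncol(pairs)) < p_edge)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(pairs[1L, keep], pairs[2L, keep]))
  }
  g
}

#' Simulate a gene-mention text corpus
#'
#' Emulates the contextual signal that literature pre-training exploits:
#' driver genes co-occur with each other and with a shared "driver-context"
#' filler vocabulary (the in-text analogue of words like "critical" or
#' "drug resistance"), while passenger genes appear in sentences of neutral
#' fillers.  A small mixing probability puts an occasional gene of the
#' other class into a sentence so the two vocabularies are not perfectly
#' separable.
#'
#' @param labels named character vector gene -> label
#'   (`known_driver` / `predicted_passenger`), e.g. from
#'   [simulate_cohort()].
#' @param n_sentences number of sentences (>= 1; default 1000).
#' @param vocab_extra filler tokens per theme (default 20).
#' @param genes_per_sentence genes mentioned per sentence (default 4).
#' @param fillers_per_sentence filler tokens per sentence (default 6).
#' @param mix_p probability a sentence also mentions one gene of the other
#'   class (default 0.1).
#' @param seed integer seed.
#' @return list of character vectors (tokenized sentences).
#' @export
simulate_corpus <- function(labels, n_sentences = 1000L, vocab_extra = 20L,
                            genes_per_sentence = 4L, fillers_per_sentence = 6L,
                            mix_p = 0.1, seed = 1L) {
  if (n_sentences < 1L) abort_validation("n_sentences must be >= 1")
  drivers <- names(labels)[labels %in% c("known_driver", "predicted_driver")]
  passengers <- names(labels)[labels == "predicted_passenger"]
  if (length(drivers) == 0L || length(passengers) == 0L) {
    abort_validation("labels must contain both driver and passenger genes")
  }
  driver_fillers <- sprintf("CTXDRV%02d", seq_len(vocab_extra))
  neutral_fillers <- sprintf("CTXNEU%02d", seq_len(vocab_extra))
  with_seed(seed, {
    lapply(seq_len(n_sentences), function(s) {
      driver_theme <- stats::runif(1) < 0.5
      pool <- if (driver_theme) drivers else passengers
      other <- if (driver_theme) passengers else drivers
      fill <- if (driver_theme) driver_fillers else neutral_fillers
      toks <- c(
        pool[sample.int(length(pool), min(genes_per_sentence, length(pool)))],
        fill[sample.int(length(fill), min(fillers_per_sentence, length(fill)))]
      )
      if (stats::runif(1) < mix_p) {
        toks <- c(toks, other[sample.int(length(other), 1L)])
      }
      sample(toks)
    })
  })
}
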