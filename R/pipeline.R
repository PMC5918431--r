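# File-to-file orchestration of the four model variants, for scripted use
# and for the thin command-line wrapper shipped in inst/cli/mutembed.R.

#' Pipeline configuration
#'
#' Validates a variant/paths/parameters bundle before any computation.
#' Variant `"PI"` and `"PI+R"` require `pretrained`; `"R"` and `"PI+R"`
#' require `ppi`.
#'
#' @param variant one of `"basic"`, `"PI"`, `"R"`, `"PI+R"`.
#' @param profiles path to the mutation-profile TSV.
#' @param out_dir output directory (created if missing).
#' @param pretrained,ppi,labels,gmt optional input paths: word2vec-format
#'   pre-trained vectors, interaction edge list, driver/passenger label
#'   table, GMT gene sets.
#' @param dim,draws_per_sample,draw_size,negatives,epochs,min_count model
#'   parameters (see [mutation_embedding()]).
#' @param eval_k clusters for the driver/passenger evaluation (default 2).
#' @param enrich_k clusters for driver identification (default 200).
#' @param passenger_sample_size passengers sampled for the evaluation subset
#'   (default: as many as there are drivers).
#' @param plot write a PC1/PC2 scatter PNG (default `FALSE`).
#' @param seed integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = c("basic", "PI", "R", "PI+R"),
                            profiles, out_dir, pretrained = NULL, ppi = NULL,
                            labels = NULL, gmt = NULL, dim = 300L,
                            draws_per_sample = 10L, draw_size = 10L,
                            negatives = 5L, epochs = 5L, min_count = 1L,
                            eval_k = 2L, enrich_k = 200L,
                            passenger_sample_size = NULL, plot = FALSE,
                            seed = 1L) {
  variant <- match.arg(variant)
  if (variant %in% c("PI", "PI+R") && is.null(pretrained)) {
    abort_config(sprintf("variant %s requires a pretrained vector path", variant))
  }
  if (variant %in% c("R", "PI+R") && is.null(ppi)) {
    abort_config(sprintf("variant %s requires a PPI edge-list path", variant))
  }
  structure(
    list(variant = variant, profiles = profiles, out_dir = out_dir,
         pretrained = pretrained, ppi = ppi, labels = labels, gmt = gmt,
         dim = as.integer(dim), draws_per_sample = as.integer(draws_per_sample),
         draw_size = as.integer(draw_size), negatives = as.integer(negatives),
         epochs = as.integer(epochs), min_count = as.integer(min_count),
         eval_k = as.integer(eval_k), enrich_k = as.integer(enrich_k),
         passenger_sample_size = passenger_sample_size, plot = isTRUE(plot),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the embedding pipeline end to end
#'
#' Reads the configured inputs, fits the requested model variant, and
#' writes: the vectors in word2vec text format (`vectors.vec`), a JSON
#' sidecar with the full configuration, its hash and the seed
#' (`run_info.json`), and — when a label table is given — a
#' driver/passenger evaluation report (`evaluation.tsv`, k-means +
#' normalized mutual information on the driver/sampled-passenger subset)
#' and a driver-identification report (`enrichment.tsv` and
#' `candidates.txt`, most-enriched-cluster statistics).  With `gmt` also a
#' gene-set over-representation table (`genesets.tsv`).  Reruns with the
#' same configuration reproduce the vectors bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted `mutation_embedding` and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  profiles <- read_profiles(config$profiles)
  pretrained <- if (!is.null(config$pretrained)) read_vectors(config$pretrained)
  graph <- if (!is.null(config$ppi)) read_edge_list(config$ppi)
  labels <- if (!is.null(config$labels)) read_labels(config$labels)
  sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  use_pi <- config$variant %in% c("PI", "PI+R")
  use_r <- config$variant %in% c("R", "PI+R")

  fit <- mutation_embedding(
    profiles,
    pretrained = if (use_pi) pretrained,
    graph = if (use_r) graph,
    dim = config$dim, draws_per_sample = config$draws_per_sample,
    draw_size = config$draw_size, negatives = config$negatives,
    epochs = config$epochs, min_count = config$min_count, seed = config$seed
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vectors = file.path(config$out_dir, "vectors.vec"))
  write_vectors(fit$vectors, paths$vectors)

  if (!is.null(labels)) {
    ev <- evaluate_embedding(fit$vectors, labels, k = config$eval_k,
                             passenger_sample_size = config$passenger_sample_size,
                             seed = config$seed)
    paths$evaluation <- file.path(config$out_dir, "evaluation.tsv")
    utils::write.table(ev$report, paths$evaluation, sep = "\t",
                       quote = FALSE, row.names = FALSE)

    part <- kmeans_cluster(fit$vectors, k = min(config$enrich_k, nrow(fit$vectors)),
                           seed = config$seed)
    enr <- most_enriched_cluster(part, labels)
    cand <- extract_candidates(enr$genes, labels)
    paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(cbind(cluster = enr$cluster, enr$result),
                       paths$enrichment, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$candidates <- file.path(config$out_dir, "candidates.txt")
    writeLines(cand, paths$candidates)

    if (!is.null(sets)) {
      gs <- geneset_enrichment(enr$genes, sets, background = rownames(fit$vectors))
      paths$genesets <- file.path(config$out_dir, "genesets.tsv")
      utils::write.table(gs, paths$genesets, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (config$plot) {
      paths$plot <- file.path(config$out_dir, "pca.png")
      grDevices::png(paths$plot, width = 800, height = 800)
      plot(fit, labels = labels, genes = ev$subset)
      grDevices::dev.off()
    }
  }

  info <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    variant = fit$variant,
    n_genes = nrow(fit$vectors),
    dim = ncol(fit$vectors),
    n_pairs = fit$n_pairs,
    n_initialized = fit$n_initialized
  )
  paths$run_info <- file.path(config$out_dir, "run_info.json")
  jsonlite::write_json(info, paths$run_info, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(list(fit = fit, paths = paths))
}

#' Driver/passenger evaluation of an embedding
#'
#' Clusters the known-driver vectors together with a random sample of
#' passenger vectors (k-means, full dimensionality) and scores the
#' agreement between the clustering and the driver/passenger labelling by
#' normalized mutual information.
#'
#' @param vectors gene-by-dimension matrix (token row names).
#' @param labels named character vector gene -> label.
#' @param k clusters (default 2, one per class).
#' @param passenger_sample_size passengers to sample; default: the number
#'   of drivers present, giving a balanced subset.
#' @param seed integer seed (passenger sampling and k-means restarts).
#' @return list with `nmi`, `partition`, `subset` (the genes used) and a
#'   one-row `report` data.frame.
#' @export
evaluate_embedding <- function(vectors, labels, k = 2L,
                               passenger_sample_size = NULL, seed = 1L) {
  drivers <- intersect(rownames(vectors), names(labels)[labels == "known_driver"])
  passengers <- intersect(rownames(vectors), names(labels)[labels == "predicted_passenger"])
  if (length(drivers) == 0L || length(passengers) == 0L) {
    abort_validation("need embedded genes of both classes")
  }
  if (is.null(passenger_sample_size)) passenger_sample_size <- length(drivers)
  passenger_sample_size <- min(passenger_sample_size, length(passengers))
  picked <- with_seed(seed + 1L,
    passengers[sample.int(length(passengers), passenger_sample_size)]
  )
  subset <- c(drivers, picked)
  part <- kmeans_cluster(vectors[subset, , drop = FALSE], k = k, seed = seed)
  truth <- stats::setNames(
    c(rep("driver", length(drivers)), rep("passenger", length(picked))), subset
  )
  score <- nmi(part, truth)
  list(
    nmi = score, partition = part, subset = subset,
    report = data.frame(
      n_drivers = length(drivers), n_passengers = length(picked),
      k = k, nmi = score
    )
  )
}
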