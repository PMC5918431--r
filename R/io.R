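# Readers and writers for the plain-text formats the pipeline touches:
# mutation profiles (two-column TSV or MAF-lite), word2vec text vectors,
# interaction edge lists, driver/passenger label tables and GMT gene sets.
# Gene symbols are normalised to upper case on ingest everywhere, because
# cohort profiles, literature vectors and interaction networks are joined by
# gene name and need one canonical casing.

VALID_LABELS <- c("known_driver", "predicted_driver", "predicted_passenger")

read_tsv_lines <- function(path) {
  if (!file.exists(path)) abort_empty(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], lineno = which(keep))
}

#' Construct a set of per-sample mutation profiles
#'
#' A `mutation_profiles` object is an ordered collection of tumour samples,
#' each carrying the set of gene symbols mutated in that sample.  It is the
#' training corpus for the embedding: genes mutated in the same sample are
#' treated as each other's context.
#'
#' @param samples named list of character vectors; names are sample
#'   identifiers, elements are the mutated gene symbols of that sample.
#' @return an object of class `mutation_profiles`.
#' @export
mutation_profiles <- function(samples) {
  if (length(samples) == 0L) abort_empty("no samples supplied")
  ids <- names(samples)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    abort_validation("every sample must be named by a sample id")
  }
  if (anyDuplicated(ids)) abort_validation("sample ids must be unique")
  samples <- lapply(samples, function(g) unique(toupper(as.character(g))))
  if (any(lengths(samples) == 0L)) abort_validation("every sample must carry at least one gene")
  structure(samples, class = "mutation_profiles")
}

#' @export
print.mutation_profiles <- function(x, ...) {
  ng <- lengths(x)
  cat(sprintf(
    "mutation profiles: %d samples, %d distinct genes (genes/sample: median %g, range %d-%d)\n",
    length(x), length(unique(unlist(x, use.names = FALSE))),
    stats::median(ng), min(ng), max(ng)
  ))
  invisible(x)
}

#' Read per-sample mutation profiles
#'
#' Ingests the mutated-gene profile of a cohort, either as a headerless
#' two-column TSV (`sample_id<TAB>gene_symbol`, `#` comment lines allowed) or
#' as a tab-delimited MAF-like file from which only the
#' `Tumor_Sample_Barcode` and `Hugo_Symbol` columns are consumed.  Genes are
#' deduplicated per sample and samples keep first-appearance order.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"maf"`.
#' @return a [mutation_profiles] object.
#' @export
read_profiles <- function(path, format = c("tsv", "maf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tl <- read_tsv_lines(path)
    if (length(tl$lines) == 0L) abort_empty(sprintf("no profile records in %s", path))
    parts <- strsplit(tl$lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      abort_format(sprintf("line %d of %s: expected 2 tab-separated fields", tl$lineno[bad[1L]], path))
    }
    sample_id <- vapply(parts, `[[`, "", 1L)
    gene <- vapply(parts, `[[`, "", 2L)
  } else {
    header <- tryCatch(
      utils::read.delim(path, nrows = 1L, check.names = FALSE, comment.char = "#"),
      error = function(e) abort_empty(sprintf("cannot read MAF file %s: %s", path, conditionMessage(e)))
    )
    need <- c("Tumor_Sample_Barcode", "Hugo_Symbol")
    missing_cols <- setdiff(need, names(header))
    if (length(missing_cols)) {
      abort_format(sprintf("MAF file %s lacks required column(s): %s", path, paste(missing_cols, collapse = ", ")))
    }
    maf <- utils::read.delim(path, check.names = FALSE, comment.char = "#", colClasses = "character")
    if (nrow(maf) == 0L) abort_empty(sprintf("no mutation records in %s", path))
    sample_id <- maf[["Tumor_Sample_Barcode"]]
    gene <- maf[["Hugo_Symbol"]]
  }
  sample_id <- as.character(sample_id)
  split_genes <- split(toupper(gene), factor(sample_id, levels = unique(sample_id)))
  mutation_profiles(lapply(split_genes, unique))
}

#' Read vectors in word2vec text format
#'
#' The format is a header line `"<count> <dimension>"` followed by one line
#' per token: the token then its coordinates, whitespace-separated.
#'
#' @param path path to the vector file.
#' @return a numeric matrix with one row per token; row names are the tokens.
#' @export
read_vectors <- function(path) {
  if (!file.exists(path)) abort_empty(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort_empty(sprintf("empty vector file: %s", path))
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    abort_format(sprintf("%s: header must be '<count> <dimension>'", path))
  }
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    abort_format(sprintf("%s: header promises %d rows, found %d", path, n, length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != d + 1L)) {
    bad <- which(lengths(parts) != d + 1L)[1L]
    abort_format(sprintf("%s: row %d has %d coordinates, expected %d", path, bad, lengths(parts)[bad] - 1L, d))
  }
  tokens <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(tokens)) abort_format(sprintf("%s: duplicate tokens in vector table", path))
  mat <- matrix(
    as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
    nrow = n, ncol = d, byrow = TRUE, dimnames = list(tokens, NULL)
  )
  if (!all(is.finite(mat))) abort_format(sprintf("%s: non-finite coordinates", path))
  mat
}

#' Write vectors in word2vec text format
#'
#' @param vectors numeric matrix with token row names.
#' @param path output path.
#' @param digits decimal places for the coordinates (default 6, the usual
#'   precision of text-format vector files).
#' @export
write_vectors <- function(vectors, path, digits = 6L) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(vectors), ncol(vectors)), con)
  fmt <- paste0("%.", digits, "f")
  rows <- vapply(seq_len(nrow(vectors)), function(i) {
    paste(c(rownames(vectors)[i], sprintf(fmt, vectors[i, ])), collapse = " ")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' Two-column TSV of gene pairs.  The graph is undirected: reversed duplicate
#' pairs are collapsed and self-loops dropped.  An empty file yields the empty
#' graph.
#'
#' @param path path to the edge list.
#' @return an undirected, simplified [igraph::igraph] object.
#' @export
read_edge_list <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort_format(sprintf("line %d of %s: expected 2 tab-separated fields", tl$lineno[bad[1L]], path))
  }
  a <- toupper(vapply(parts, `[[`, "", 1L))
  b <- toupper(vapply(parts, `[[`, "", 2L))
  keep <- a != b
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  igraph::simplify(g)
}

#' Read a driver/passenger label table
#'
#' Two-column TSV `gene<TAB>label` with labels restricted to
#' `known_driver`, `predicted_driver`, `predicted_passenger`.  When a gene
#' appears more than once the last label wins, with a warning.
#'
#' @param path path to the label table.
#' @return named character vector mapping gene symbol to label.
#' @export
read_labels <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) abort_empty(sprintf("no labels in %s", path))
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort_format(sprintf("line %d of %s: expected 2 tab-separated fields", tl$lineno[bad[1L]], path))
  }
  gene <- toupper(vapply(parts, `[[`, "", 1L))
  label <- vapply(parts, `[[`, "", 2L)
  unknown <- setdiff(unique(label), VALID_LABELS)
  if (length(unknown)) {
    abort_validation(sprintf(
      "unknown label(s) %s in %s; expected one of %s",
      paste(sQuote(unknown), collapse = ", "), path, paste(VALID_LABELS, collapse = ", ")
    ))
  }
  if (anyDuplicated(gene)) {
    warning(sprintf("duplicate gene(s) in %s; keeping the last label of each", path))
  }
  out <- stats::setNames(label, gene)
  out[!duplicated(gene, fromLast = TRUE)][unique(gene)]
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description and then the member genes,
#' tab-separated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of upper-cased gene symbols.
#' @export
read_gmt <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) abort_empty(sprintf("no gene sets in %s", path))
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort_format(sprintf("line %d of %s: GMT lines need at least 3 fields", tl$lineno[bad[1L]], path))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) abort_validation(sprintf("duplicate gene-set names in %s", path))
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  stats::setNames(sets, nm)
}
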