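Package: mutembed
Title: Distributed Representations of Cancer Mutations from Co-Occurrence Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns dense gene-level embeddings of somatic cancer mutations
    from per-sample mutated-gene profiles using skip-gram with negative
    sampling, treating the mutations that co-occur in a tumour sample as each
    other's context.  Embeddings can be initialised from word vectors
    pre-trained on a text corpus and post-processed by graph retrofitting on a
    protein-protein interaction network so that one-hop neighbours receive
    similar vectors.  Includes tools to evaluate embeddings with principal
    component projection, k-means clustering and normalized mutual
    information against driver/passenger labels, to prioritise candidate
    driver genes by hypergeometric cluster enrichment, to run gene-set
    over-representation tests with Benjamini-Hochberg correction, and to
    simulate cohorts, interaction networks and gene-mention corpora with
    planted driver structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
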