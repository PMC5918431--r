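test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeom_sf(10, 4, 3, 2), hyper_tail_enum(10, 4, 3, 2), tolerance = 1e-14)
  expect_equal(hyper_tail_enum(10, 4, 3, 2), 1 / 3, tolerance = 1e-14)
  expect_equal(hypergeom_sf(100, 10, 5, 0), 1)

  set.seed(23)
  for (rep in 1:200) {
    N <- sample(2:25, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_sf(N, K, n, k), hyper_tail_enum(N, K, n, k), tolerance = 1e-12)
  }

  # monotone non-increasing in k
  p <- vapply(0:5, function(k) hypergeom_sf(50, 10, 8, k), 0)
  expect_true(all(diff(p) <= 1e-15))

  expect_error(hypergeom_sf(10, 12, 3, 1), class = "mutembed_validation_error")
  expect_error(hypergeom_sf(10, 4, 3, 4), class = "mutembed_validation_error")
})

test_that("most enriched cluster maximises driver count with p-value tie-break", {
  genes <- sprintf("g%02d", 1:60)
  part <- setNames(rep(1:3, each = 20), genes)
  drivers <- c(genes[21:25], genes[41:42])  # 5 in cluster 2, 2 in cluster 3
  labels <- setNames(rep("known_driver", length(drivers)), drivers)
  res <- most_enriched_cluster(part, labels)
  expect_identical(res$cluster, 2L)
  expect_identical(res$result$k, 5L)
  expect_identical(res$result$N, 60L)
  expect_identical(res$result$K, 7L)
  expect_equal(res$result$p_value, hyper_tail_enum(60, 7, 20, 5), tolerance = 1e-12)

  # tie on the count: the smaller cluster is more surprising and wins
  part2 <- setNames(c(rep(1, 10), rep(2, 50)), sprintf("h%02d", 1:60))
  lab2 <- setNames(rep("known_driver", 10),
                   c(sprintf("h%02d", 1:5), sprintf("h%02d", 11:15)))
  res2 <- most_enriched_cluster(part2, lab2)
  expect_identical(res2$cluster, 1)

  expect_error(most_enriched_cluster(part, c(ZZZ = "known_driver")),
               class = "mutembed_validation_error")
})

test_that("candidate extraction removes every driver-labelled gene", {
  labels <- c(TP53 = "known_driver", ALK = "predicted_driver", PSG1 = "predicted_passenger")
  expect_identical(extract_candidates(c("TP53", "XYZ", "ALK", "ABC"), labels),
                   c("ABC", "XYZ"))
  expect_identical(extract_candidates(c("TP53", "ALK"), labels), character(0))
  # cluster partitions into known + predicted-only + candidates
  cl <- c("TP53", "ALK", "PSG1", "NEW1")
  known <- sum(labels[cl] == "known_driver", na.rm = TRUE)
  pred <- sum(labels[cl] == "predicted_driver", na.rm = TRUE)
  expect_identical(length(extract_candidates(cl, labels)), length(cl) - known - pred)
})

test_that("one-sided Fisher agrees with the hypergeometric mapping and fisher.test", {
  expect_equal(fisher_exact_greater(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_exact_greater(0, 3, 5, 7), 1)

  set.seed(29)
  for (rep in 1:100) {
    tb <- sample(0:8, 4, replace = TRUE)
    p <- fisher_exact_greater(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, hyper_tail_enum(sum(tb), tb[1] + tb[2], tb[1] + tb[3], tb[1]),
                 tolerance = 1e-12)
    if (sum(tb) > 0) {
      ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE), alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment is the step-up procedure in input order", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03), tolerance = 1e-12)
  p <- c(0.4, 0.01, 0.9, 0.02)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # order statistics of adjusted values are monotone
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mutembed_validation_error")
})

test_that("gene-set enrichment composes Fisher tests with BH across sets", {
  background <- sprintf("g%02d", 1:50)
  cluster <- background[1:10]
  sets <- list(
    exact = cluster,
    disjoint = background[41:50],
    partial = background[6:15]
  )
  tab <- geneset_enrichment(cluster, sets, background)
  expect_identical(tab$set[1], "exact")
  expect_equal(tab$p_value[tab$set == "disjoint"], 1)
  expect_identical(tab$overlap[tab$set == "exact"], "10/10")
  expect_equal(sort(tab$adj_p_value), sort(bh_adjust(tab$p_value)), tolerance = 1e-12)

  expect_error(geneset_enrichment(cluster, sets, character(0)),
               class = "mutembed_validation_error")
  expect_error(geneset_enrichment(c(cluster, "NOT_IN_BG"), sets, background),
               class = "mutembed_validation_error")
})
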