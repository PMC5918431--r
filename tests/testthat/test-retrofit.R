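make_graph <- function(edges) {
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

test_that("neighbour sets are one-hop graph neighbours intersected with the vocabulary", {
  g <- make_graph(rbind(c("A", "B"), c("B", "C")))
  nb <- build_neighbor_sets(g, c("A", "B", "C"))
  expect_setequal(nb$B, c("A", "C"))
  expect_identical(nb$A, "B")

  nb2 <- build_neighbor_sets(make_graph(rbind(c("B", "C"))), c("A", "B"))
  expect_identical(nb2$B, character(0))  # C out of vocab
  expect_identical(nb2$A, character(0))

  nb3 <- build_neighbor_sets(igraph::make_empty_graph(0, directed = FALSE), c("A", "B"))
  expect_true(all(lengths(nb3) == 0))
})

test_that("retrofitting with no edges is an exact identity", {
  Q <- matrix(rnorm(20), 5, 4, dimnames = list(LETTERS[1:5], NULL))
  out <- retrofit_vectors(Q, graph = igraph::make_empty_graph(0, directed = FALSE))
  expect_identical(unname(unclass(out)[, ]), unname(Q[, ]))
})

test_that("two-node problem converges to the exact fixed point (2/3,1/3)", {
  Q <- rbind(A = c(1, 0), B = c(0, 1))
  nb <- list(A = "B", B = "A")
  out <- retrofit_vectors(Q, nb, alpha = 1, beta = 1, iterations = 200, tol = 1e-14)
  expect_equal(unname(out["A", ]), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(unname(out["B", ]), c(1 / 3, 2 / 3), tolerance = 1e-10)
  # with |S_i| = 1 the default degree rule gives the same weights
  out2 <- retrofit_vectors(Q, nb, iterations = 200, tol = 1e-14)
  expect_equal(unname(out2), unname(out[, ]), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the converged solution is stationary under the update map", {
  set.seed(21)
  Q <- matrix(rnorm(30), 10, 3, dimnames = list(LETTERS[1:10], NULL))
  edges <- t(combn(LETTERS[1:10], 2))
  edges <- edges[runif(nrow(edges)) < 0.3, , drop = FALSE]
  g <- make_graph(edges)
  nb <- build_neighbor_sets(g, rownames(Q))
  out <- retrofit_vectors(Q, nb, iterations = 500, tol = 1e-13)
  # the update map (anchored at the original Q) should leave the limit fixed
  resid <- 0
  for (i in rownames(Q)) {
    s <- nb[[i]]
    if (length(s) == 0) next
    b <- 1 / length(s)
    upd <- (Q[i, ] + b * colSums(out[s, , drop = FALSE])) / (1 + b * length(s))
    resid <- max(resid, max(abs(upd - out[i, ])))
  }
  expect_lt(resid, 1e-8)
})

test_that("each update is a convex combination of the anchor and neighbours", {
  Q <- rbind(A = c(0, 0), B = c(4, 0), C = c(0, 4))
  nb <- list(A = c("B", "C"), B = "A", C = "A")
  out <- retrofit_vectors(Q, nb, iterations = 50)
  # every coordinate of q_A must lie within the range spanned by
  # {q~_A, q_B, q_C} at all times; check the limit
  expect_true(all(out["A", ] >= 0 & out["A", ] <= 4))
  expect_true(all(out["B", ] >= 0 & out["B", ] <= 4))
})

test_that("vanishing beta leaves the trained vectors unchanged", {
  set.seed(3)
  Q <- matrix(rnorm(24), 8, 3, dimnames = list(LETTERS[1:8], NULL))
  g <- make_graph(cbind(LETTERS[1:7], LETTERS[2:8]))
  out <- retrofit_vectors(Q, graph = g, beta = 1e-9, iterations = 50)
  expect_equal(unname(out[, ]), unname(Q), tolerance = 1e-7)
})

test_that("the iteration monotonically decreases its descent functional", {
  # the update is Gauss-Seidel on (2D - A) Q = D Qt, i.e. exact coordinate
  # descent on F(Q) = sum_i |S_i| ||q_i - q~_i||^2 + sum_edges ||q_i - q_j||^2
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    Qt <- matrix(rnorm(n * 3), n, dimnames = list(LETTERS[1:n], NULL))
    A <- matrix(runif(n * n) < 0.4, n); A <- A | t(A); diag(A) <- FALSE
    nb <- lapply(seq_len(n), function(i) LETTERS[which(A[i, ])])
    names(nb) <- LETTERS[1:n]
    deg <- pmax(rowSums(A), 0)
    F_of <- function(Q) {
      sum(deg * rowSums((Q - Qt)^2)) +
        sum(vapply(seq_len(n), function(i) {
          j <- which(A[i, ]); if (length(j)) sum(sweep(Q[j, , drop = FALSE], 2, Q[i, ])^2) else 0
        }, 0)) / 2
    }
    prev <- F_of(Qt)
    for (it in 1:12) {
      Q <- retrofit_vectors(Qt, nb, iterations = it, tol = 0)
      cur <- F_of(Q)
      expect_lte(cur, prev + 1e-10)
      prev <- cur
    }
  }
})

test_that("objective evaluates the printed directed sum", {
  Q <- rbind(A = c(1, 0), B = c(0, 1))
  nb <- list(A = "B", B = "A")
  # at Q = Q~ the anchors vanish and each directed edge term is ||(1,0)-(0,1)||^2 = 2
  expect_equal(retrofit_objective(Q, Q, nb, alpha = 1, beta = 1), 4, tolerance = 1e-12)
  expect_equal(retrofit_objective(Q, Q, list(A = character(0), B = character(0))), 0)

  # homogeneity: scaling all vectors scales the objective by c^2
  set.seed(11)
  Q1 <- matrix(rnorm(12), 4, 3, dimnames = list(LETTERS[1:4], NULL))
  Q2 <- matrix(rnorm(12), 4, 3, dimnames = list(LETTERS[1:4], NULL))
  nb4 <- list(A = "B", B = c("A", "C"), C = "B", D = character(0))
  expect_equal(retrofit_objective(3 * Q1, 3 * Q2, nb4),
               9 * retrofit_objective(Q1, Q2, nb4), tolerance = 1e-10)

  # matches the independent direct evaluation
  nb_idx <- list(2L, c(1L, 3L), 2L, integer(0))
  expect_equal(retrofit_objective(Q1, Q2, nb4),
               retrofit_obj_direct(Q1, Q2, nb_idx), tolerance = 1e-12)
})

test_that("retrofitting from a trained state keeps anchored and neighbour geometry sane", {
  cohort <- tiny_cohort()
  g <- simulate_ppi(cohort$modules, cohort$genes, intra_p = 0.5, inter_p = 0, seed = 2)
  fit0 <- mutation_embedding(cohort$profiles, dim = 16, epochs = 2, seed = 2)
  Q <- retrofit_vectors(fit0$vectors_raw, graph = g)
  mods <- default_modules_for_tests()
  m1 <- intersect(mods[[1]], rownames(Q))
  d_before <- mean(dist(fit0$vectors_raw[m1, ]))
  d_after <- mean(dist(Q[m1, ]))
  expect_lt(d_after, d_before)  # neighbours pulled together
  # isolated genes (inter_p = 0 keeps passengers edge-free... mostly) unchanged
  iso <- names(which(igraph::degree(g) == 0))
  iso <- intersect(iso, rownames(Q))
  if (length(iso)) expect_equal(Q[iso, ], fit0$vectors_raw[iso, ], tolerance = 1e-12)
})
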