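test_that("vocabulary construction filters by count and orders deterministically", {
  x <- list(s1 = c("A", "B"), s2 = c("A"), s3 = c("A", "C"), s4 = c("B"))
  vb <- build_vocab(mutation_profiles(x), min_count = 2)
  expect_identical(vb$vocab, c("A", "B"))
  expect_identical(unname(vb$counts), c(3L, 2L))

  vb1 <- build_vocab(mutation_profiles(x), min_count = 1)
  expect_identical(vb1$vocab, c("A", "B", "C"))  # tie B/C broken... B=2 > C=1

  # lexicographic tie-break is stable
  y <- list(s1 = c("ZZ", "AA"), s2 = c("AA", "ZZ"))
  expect_identical(build_vocab(mutation_profiles(y))$vocab, c("AA", "ZZ"))

  expect_error(build_vocab(mutation_profiles(x), min_count = 10),
               class = "mutembed_config_error")
})

test_that("noise distribution is the 3/4-power unigram distribution", {
  p <- noise_distribution(c(A = 4, B = 1))
  expect_equal(p[1], 4^0.75 / (4^0.75 + 1), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  expect_equal(noise_distribution(c(3, 9, 27), power = 0),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(noise_distribution(rep(7, 5)), rep(0.2, 5), tolerance = 1e-12)
  expect_error(noise_distribution(c(1, 0)), class = "mutembed_validation_error")
})

test_that("per-pair loss matches its closed forms in forced cases", {
  d <- 4
  z <- rep(0, d)
  res <- sgns_loss_grad(z, z, matrix(0, 1, d))
  expect_equal(res$loss, 2 * log(2), tolerance = 1e-12)

  # saturated positive pair, no negatives: loss -> 0
  u <- c(100, 0, 0, 0)
  expect_lt(sgns_loss_grad(u, u)$loss, 1e-10)
  expect_gte(sgns_loss_grad(rnorm(d), rnorm(d), matrix(rnorm(3 * d), 3))$loss, 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  fd <- function(f, x, eps = 1e-6) {
    vapply(seq_along(x), function(i) {
      e <- rep(0, length(x)); e[i] <- eps
      (f(x + e) - f(x - e)) / (2 * eps)
    }, 0)
  }
  for (rep in 1:25) {
    d <- sample(2:6, 1)
    u <- rnorm(d); v <- rnorm(d); W <- matrix(rnorm(2 * d), 2)
    g <- sgns_loss_grad(u, v, W)
    expect_equal(g$grad_u, fd(function(x) sgns_loss_grad(x, v, W)$loss, u), tolerance = 1e-5)
    expect_equal(g$grad_v_pos, fd(function(x) sgns_loss_grad(u, x, W)$loss, v), tolerance = 1e-5)
    expect_equal(g$grad_v_neg[1, ],
                 fd(function(x) sgns_loss_grad(u, v, rbind(x, W[2, ]))$loss, W[1, ]),
                 tolerance = 1e-5)
  }
})

test_that("full-softmax objective matches direct enumeration", {
  vocab <- c("A", "B")
  m <- train_sgns(matrix(c(1L, 2L), 1), vocab, sgns_config(dim = 3, epochs = 0, seed = 1))
  m$U[] <- 0; m$V[] <- 0
  expect_equal(softmax_objective(m, matrix(c(1L, 2L), 1)), log(0.5), tolerance = 1e-12)

  # |E| = 3 toy model vs hand-rolled softmax sums
  set.seed(1)
  m3 <- train_sgns(matrix(c(1L, 2L), 1), c("A", "B", "C"),
                   sgns_config(dim = 2, epochs = 0, seed = 2))
  m3$U <- matrix(rnorm(6), 3); m3$V <- matrix(rnorm(6), 3)
  pairs <- cbind(c(1L, 2L, 3L, 1L), c(2L, 3L, 1L, 3L))
  direct <- mean(vapply(seq_len(nrow(pairs)), function(r) {
    s <- as.numeric(m3$V %*% m3$U[pairs[r, 1], ])
    s[pairs[r, 2]] - log(sum(exp(s)))
  }, 0))
  expect_equal(softmax_objective(m3, pairs), direct, tolerance = 1e-12)

  # raising the observed-pair score strictly increases the objective
  before <- softmax_objective(m3, pairs)
  m3$U[1, ] <- m3$U[1, ] + 0.1 * m3$V[2, ]
  expect_gt(softmax_objective(m3, cbind(1L, 2L)), before - 1e-12)
})

test_that("training is deterministic and zero epochs returns the initialization", {
  cohort <- tiny_cohort()
  vb <- build_vocab(cohort$profiles)
  pairs <- contexts_to_pairs(sample_profile_contexts(cohort$profiles, vb$vocab, seed = 4))
  cfg <- sgns_config(dim = 16, epochs = 2, seed = 4)
  noise <- noise_distribution(vb$counts)

  m0 <- train_sgns(pairs, vb$vocab, sgns_config(dim = 16, epochs = 0, seed = 4), noise)
  expect_true(all(abs(m0$U) <= 0.5 / 16))
  expect_true(all(m0$V == 0))

  m1 <- train_sgns(pairs, vb$vocab, cfg, noise)
  m2 <- train_sgns(pairs, vb$vocab, cfg, noise)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$V, m2$V)
  expect_false(identical(m1$U, m0$U))
})

test_that("training separates planted modules in cosine similarity", {
  cohort <- tiny_cohort()
  vb <- build_vocab(cohort$profiles)
  pairs <- contexts_to_pairs(sample_profile_contexts(cohort$profiles, vb$vocab, seed = 4))
  m <- train_sgns(pairs, vb$vocab, sgns_config(dim = 32, epochs = 5, seed = 4),
                  noise_distribution(vb$counts))
  mods <- default_modules_for_tests()
  U <- m$U / sqrt(rowSums(m$U^2))
  within <- function(g) { S <- U[g, ] %*% t(U[g, ]); mean(S[upper.tri(S)]) }
  between <- mean(U[mods[[1]], ] %*% t(U[mods[[2]], ]))
  expect_gt(within(intersect(mods[[1]], rownames(U))), between)
  expect_gt(within(intersect(mods[[2]], rownames(U))), between)
})

test_that("SGNS training increases the full-softmax objective on a tiny corpus", {
  set.seed(8)
  vocab <- LETTERS[1:8]
  # two blocks that co-occur internally
  sets <- c(rep(list(1:4), 40), rep(list(5:8), 40))
  pairs <- contexts_to_pairs(sets)
  cfg0 <- sgns_config(dim = 8, epochs = 0, seed = 8)
  cfg  <- sgns_config(dim = 8, epochs = 10, negatives = 7, lr_initial = 0.05, seed = 8)
  noise <- rep(1 / 8, 8)
  before <- softmax_objective(train_sgns(pairs, vocab, cfg0, noise), pairs)
  after <- softmax_objective(train_sgns(pairs, vocab, cfg, noise), pairs)
  expect_gt(after, before)
})

test_that("pre-trained initialization overwrites matching rows only, case-insensitively", {
  m <- train_sgns(matrix(c(1L, 2L), 1), c("TP53", "KRAS"),
                  sgns_config(dim = 3, epochs = 0, seed = 1))
  tab <- matrix(c(9, 9, 9), 1, dimnames = list("tp53", NULL))
  m2 <- init_from_pretrained(m, tab)
  expect_identical(m2$n_initialized, 1L)
  expect_equal(m2$U["TP53", ], c(9, 9, 9))
  expect_identical(m2$U["KRAS", ], m$U["KRAS", ])
  expect_identical(m2$V, m$V)

  # idempotent
  m3 <- init_from_pretrained(m2, tab)
  expect_identical(m3$U, m2$U)

  # empty table: unchanged, count 0
  m4 <- init_from_pretrained(m, matrix(numeric(0), 0, 3))
  expect_identical(m4$U, m$U)
  expect_identical(m4$n_initialized, 0L)

  expect_error(init_from_pretrained(m, matrix(1, 1, 5, dimnames = list("TP53", NULL))),
               class = "mutembed_config_error")
})
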