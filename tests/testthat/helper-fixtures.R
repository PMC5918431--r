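# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; the oracles deliberately avoid the code paths they
# check (direct enumeration with choose(), direct formula evaluation).

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Upper-tail hypergeometric by exhaustive enumeration of the pmf.
hyper_tail_enum <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# NMI by direct evaluation of the three defining formulas.
nmi_brute <- function(omega, classes) {
  n <- length(omega)
  po <- table(omega) / n
  pc <- table(classes) / n
  H <- function(p) -sum(p * log(p))
  mi <- 0
  for (i in names(po)) for (j in names(pc)) {
    pij <- sum(omega == i & classes == j) / n
    if (pij > 0) mi <- mi + pij * log(pij / (po[[i]] * pc[[j]]))
  }
  mi / ((H(po) + H(pc)) / 2)
}

# Random partition of m items into at most b blocks (no empty-label fuss:
# labels are whatever appears).
random_partition <- function(m, b) sample.int(b, m, replace = TRUE)

# A small two-module cohort used across training tests.
tiny_cohort <- function(seed = 42L) {
  simulate_cohort(
    n_samples = 120L, n_genes = 120L,
    driver_modules = default_modules_for_tests(),
    module_penetrance = 0.6, passenger_rate = 4, seed = seed
  )
}

default_modules_for_tests <- function() {
  list(sprintf("DRVA%02d", 1:20), sprintf("DRVB%02d", 1:20))
}

# Directed-sum retrofitting objective evaluated straight from its formula,
# independent of retrofit_objective().
retrofit_obj_direct <- function(Q, Qt, nb_idx, alpha = 1, beta = NULL) {
  J <- alpha * sum((Q - Qt)^2)
  for (i in seq_len(nrow(Q))) {
    s <- nb_idx[[i]]
    if (length(s)) {
      b <- if (is.null(beta)) 1 / length(s) else beta
      for (j in s) J <- J + b * sum((Q[i, ] - Q[j, ])^2)
    }
  }
  J
}
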