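test_that("transition probabilities: identity at t=0, stochastic rows, JC closed form", {
  models <- list(substitution_model("JC"),
                 substitution_model("K80", kappa = 5),
                 substitution_model("HKY", base_freqs = c(.35, .15, .2, .3), kappa = 3),
                 substitution_model("GTR", base_freqs = c(.1, .2, .3, .4),
                                    rates = c(1, 4, .6, 2, 5, 1)))
  for (m in models) {
    expect_equal(transition_probabilities(m, 0), diag(4), ignore_attr = TRUE)
    for (t in c(0.01, 0.3, 2)) {
      P <- transition_probabilities(m, t)
      expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(P >= 0))
    }
    expect_error(transition_probabilities(m, -0.1), ">= 0")
  }
  jc <- substitution_model("JC")
  P <- transition_probabilities(jc, 0.1)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-4 * 0.1 / 3), 4),
               tolerance = 1e-12)
})

# small Dirichlet sampler so the test has no extra dependency
gtools_rdirichlet <- function() {
  x <- stats::rgamma(4, 2, 1)
  x / sum(x)
}

test_that("detailed balance and the semigroup property hold", {
  set.seed(11)
  for (i in 1:5) {
    pi <- as.numeric(gtools_rdirichlet())
    m <- substitution_model("GTR", base_freqs = pi,
                            rates = stats::runif(6, 0.2, 5))
    F <- pi * m$Q
    expect_equal(F, t(F), tolerance = 1e-12)
    t1 <- stats::runif(1, 0, 1); t2 <- stats::runif(1, 0, 1)
    expect_equal(transition_probabilities(m, t1 + t2),
                 transition_probabilities(m, t1) %*% transition_probabilities(m, t2),
                 tolerance = 1e-10)
  }
})

test_that("discrete gamma categories: trivial cases and quadrature oracle", {
  expect_identical(discretize_gamma(0.7, 1), 1)
  for (alpha in c(0.2, 0.5, 2, 10)) for (n in c(2, 4, 8))
    expect_equal(mean(discretize_gamma(alpha, n)), 1, tolerance = 1e-12)

  # oracle: numerically integrate x * dgamma over each quantile interval
  alpha <- 0.5; n <- 4
  bounds <- qgamma(seq(0, 1, length.out = n + 1), alpha, rate = alpha)
  oracle <- vapply(seq_len(n), function(i) {
    n * stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                         bounds[i], bounds[i + 1])$value
  }, numeric(1))
  expect_equal(discretize_gamma(alpha, n), oracle / mean(oracle), tolerance = 1e-6)
})

test_that("pairwise distances: JC closed form and model collapse", {
  jc <- substitution_model("JC")
  s <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  expect_identical(pairwise_distance(s, s, jc), 0)
  s2 <- s; s2[1:10] <- "C"
  expect_equal(pairwise_distance(s, s2, jc), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-9)

  # GTR+Gamma with equal frequencies/exchangeabilities and a huge shape
  # collapses to JC on simulated pairs
  chr <- simulate_yule_chronogram(2, 2, 31)
  m <- substitution_model("JC")
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.08), m, 20000,
                          seed = 32)
  a <- unclass(sim$alignment)[1, ]; b <- unclass(sim$alignment)[2, ]
  gtr <- substitution_model("GTR", rates = rep(1, 6), gamma_shape = 500)
  expect_equal(pairwise_distance(a, b, gtr), pairwise_distance(a, b, jc),
               tolerance = 1e-3)
})

test_that("saturated pairs raise an error instead of returning infinity", {
  jc <- substitution_model("JC")
  set.seed(5)
  a <- sample(c("A", "C", "G", "T"), 400, TRUE)
  b <- vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  expect_error(pairwise_distance(a, b, jc), "satur")
})

test_that("pruning log-likelihood: degenerate, brute-force and invariance checks", {
  # two identical tips at t = 0: lnL = sum over sites of log(pi[state])
  m <- substitution_model("HKY", base_freqs = c(.4, .1, .2, .3), kappa = 2)
  seqs <- c("A", "A", "C", "G", "T", "A")
  A <- as_alignment(rbind(a = seqs, b = seqs))
  tr <- read_newick("(a:0,b:0);")
  expect_equal(log_likelihood(tr, A, m),
               sum(log(m$base_freqs[c(1, 1, 2, 3, 4, 1)])), tolerance = 1e-10)

  # three taxa: brute-force sum over the internal node state
  set.seed(21)
  A3 <- random_alignment(3, 60, seed = 21, taxa = c("a", "b", "c"))
  bl <- c(a = 0.1, b = 0.25, c = 0.4)
  tr3 <- read_newick("(a:0.1,b:0.25,c:0.4);")
  P <- lapply(bl, function(t) transition_probabilities(m, t))
  states <- stats::setNames(1:4, c("A", "C", "G", "T"))
  oracle <- sum(log(apply(unclass(A3), 2, function(col) {
    sum(vapply(1:4, function(i)
      m$base_freqs[i] * P$a[i, states[col["a"]]] * P$b[i, states[col["b"]]] *
        P$c[i, states[col["c"]]], numeric(1)))
  })))
  expect_equal(log_likelihood(tr3, A3, m), oracle, tolerance = 1e-8)

  # re-rooting invariance (model reversibility), mixed gaps, gamma + I
  mg <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 4,
                           gamma_shape = 0.6, p_invariant = 0.2)
  for (s in 1:3) {
    tr <- random_bl_tree(6, seed = s)
    A6 <- random_alignment(6, 150, seed = s, gap_frac = 0.05,
                           taxa = tr$tip.label)
    base <- log_likelihood(tr, A6, mg)
    tip <- sample(6, 1)
    len <- tr$edge.length[tr$edge[, 2] == tip]
    rr <- phytools::reroot(tr, tip, position = len / 2)
    expect_equal(log_likelihood(rr, A6, mg), base, tolerance = 1e-8)
  }
})

test_that("pattern compression leaves the log-likelihood exactly unchanged", {
  # duplicating columns must add their site log-likelihoods exactly
  tr <- random_bl_tree(5, seed = 13)
  A <- random_alignment(5, 80, seed = 13, gap_frac = 0.03, taxa = tr$tip.label)
  m <- substitution_model("GTR", base_freqs = c(.3, .25, .2, .25),
                          rates = c(1, 3, .5, 1.2, 4, 1), gamma_shape = 0.8)
  l1 <- log_likelihood(tr, A, m)
  dup <- as_alignment(cbind(unclass(A), unclass(A)[, 1:40]))
  l_first <- log_likelihood(tr, subset_columns(A, 1:40), m)
  expect_equal(log_likelihood(tr, dup, m), l1 + l_first, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent implementation", {
  tr <- random_bl_tree(7, seed = 4)
  A <- random_alignment(7, 300, seed = 4, gap_frac = 0.04, taxa = tr$tip.label)
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 4,
                          gamma_shape = 0.7, n_gamma_categories = 4)
  fit <- phangorn::pml(tr, phangorn::phyDat(unclass(A), type = "DNA"),
                       bf = c(.3, .2, .2, .3), Q = c(1, 4, 1, 1, 4, 1),
                       k = 4, shape = 0.7)
  expect_equal(log_likelihood(tr, A, m), fit$logLik, tolerance = 1e-6)
})

test_that("taxon mismatches are reported with the offending labels", {
  A <- random_alignment(4, 30, seed = 1)
  tr <- read_newick("((t1:1,t2:1):1,(t3:1,zz:1):1);")
  expect_error(log_likelihood(tr, A, substitution_model("JC")), "zz")
})

test_that("branch-length optimization is monotone and recovers truth", {
  # JC simulation on a fixed tree; optimized lengths within 10% at 50 kb
  chr <- simulate_yule_chronogram(6, 0.6, 71)
  jc <- substitution_model("JC")
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), jc, 50000,
                          seed = 72)
  # compare on the unrooted tree: the two root-child lengths are not
  # separately identifiable under a reversible model
  true_tree <- ape::unroot(chronogram_phylo(chr, rep(0.02, nrow(chr$tree$edge))))
  start <- true_tree
  start$edge.length <- rep(0.05, nrow(start$edge))
  ll0 <- log_likelihood(start, sim$alignment, jc)
  fit <- optimize_branch_lengths(start, sim$alignment, jc)
  expect_gte(fit$loglik, ll0)
  true_bl <- edge_lengths_by_split(true_tree)
  est_bl <- edge_lengths_by_split(fit$tree)
  true_bl <- true_bl[names(est_bl)]
  big <- true_bl > 0.005   # relative error on resolvable branches
  expect_lt(max(abs(est_bl[big] - true_bl[big]) / true_bl[big]), 0.10)
})

test_that("fitted kappa recovers the simulating value at 50 kb", {
  chr <- simulate_yule_chronogram(6, 0.6, 81)
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 4)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), m, 50000,
                          seed = 82)
  tr <- chronogram_phylo(chr, rep(0.02, nrow(chr$tree$edge)))
  fit <- fit_model(tr, sim$alignment, "HKY", rounds = 2)
  expect_gt(fit$model$kappa, 3.5)
  expect_lt(fit$model$kappa, 4.5)
})

test_that("AIC model selection: arithmetic, ordering and simulation ranking", {
  chr <- simulate_yule_chronogram(6, 0.6, 91)
  jc <- substitution_model("JC")
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), jc, 20000,
                          seed = 92)
  tr <- chronogram_phylo(chr, rep(0.02, nrow(chr$tree$edge)))
  tab <- select_model(sim$alignment, tr, candidates = c("JC", "GTR+G4+I"),
                      rounds = 1)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$loglik, tolerance = 1e-9)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_identical(tab$model[1], "JC")

  # strong rate heterogeneity and uneven rates favour GTR+G over JC
  g <- substitution_model("GTR", base_freqs = c(.35, .15, .15, .35),
                          rates = c(1, 6, .4, 1.5, 8, 1), gamma_shape = 0.3)
  sim2 <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), g, 50000,
                           seed = 93)
  tab2 <- select_model(sim2$alignment, tr, candidates = c("JC", "GTR+G4"),
                       rounds = 1)
  expect_identical(tab2$model[1], "GTR+G4")
})
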