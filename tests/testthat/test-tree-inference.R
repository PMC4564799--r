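test_that("neighbour joining: closed form, additivity, degenerate input, errors", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- edge_lengths_by_split(tr)
  # pendant edge of "a" is keyed by its complement {b,c}
  expect_equal(unname(bl[c("b,c", "b", "c")]), c(0.05, 0.15, 0.25),
               tolerance = 1e-12)

  # additive matrices from random trees are recovered exactly
  for (s in 1:10) {
    t0 <- random_bl_tree(sample(6:10, 1), seed = s)
    tr <- neighbor_joining(cophenetic(t0))
    expect_identical(topology_key(tr), topology_key(t0))
    est <- edge_lengths_by_split(tr)
    truth <- edge_lengths_by_split(t0)
    expect_equal(est, truth[names(est)], tolerance = 1e-8)
  }

  # equidistant taxa: all internal edges collapse to zero
  n <- 5
  d <- matrix(1, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  bl5 <- edge_lengths_by_split(tr)
  sz <- lengths(strsplit(names(bl5), ","))
  internal <- bl5[sz >= 2 & sz <= n - 2]
  expect_true(all(abs(internal) < 1e-12))

  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
  d2 <- d; d2[1, 2] <- 2
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("Fitch length: worked columns, missing data, invariances", {
  quartet <- function(states, topo) {
    m <- matrix(states, 4, 1, dimnames = list(c("a", "b", "c", "d"), NULL))
    fitch_length(read_newick(topo), as_alignment(m))
  }
  expect_identical(quartet(c("A", "A", "G", "G"), "((a,b),(c,d));"), 1L)
  expect_identical(quartet(c("A", "A", "G", "G"), "((a,c),(b,d));"), 2L)
  expect_identical(quartet(c("A", "A", "G", "-"), "((a,b),(c,d));"), 1L)

  A <- as_alignment(matrix("C", 4, 10, dimnames = list(letters[1:4], NULL)))
  expect_identical(fitch_length(read_newick("((a,b),(c,d));"), A), 0L)

  # rooting and taxon-order invariance; cross-check with phangorn
  for (s in 1:3) {
    tr <- random_bl_tree(7, seed = s)
    A <- random_alignment(7, 120, seed = s, gap_frac = 0.05,
                          taxa = tr$tip.label)
    f0 <- fitch_length(tr, A)
    expect_identical(fitch_length(ape::unroot(tr), A), f0)
    rr <- root_with_outgroup(tr, sample(tr$tip.label, 1))
    expect_identical(fitch_length(rr, A), f0)
    perm <- unclass(A)[sample(nrow(A)), ]
    expect_identical(fitch_length(tr, as_alignment(perm)), f0)
    expect_equal(f0, as.numeric(phangorn::parsimony(
      tr, phangorn::phyDat(unclass(A), type = "DNA"), method = "fitch")))
  }
})

test_that("Fitch equals the minimum over exhaustive six-taxon topologies", {
  all6 <- phangorn::allTrees(6, tip.label = paste0("t", 1:6), rooted = FALSE)
  for (s in 1:3) {
    A <- random_alignment(6, 40, seed = s)
    scores <- vapply(all6, fitch_length, numeric(1), alignment = A)
    best <- parsimony_search(A, n_addition_replicates = 3, seed = s)
    expect_equal(best$score, min(scores))
  }
})

test_that("parsimony search: monotone swapping and high-signal recovery", {
  # long internal branches, short tips: strong signal
  hits <- 0L
  for (s in 1:10) {
    set.seed(s + 400)
    t0 <- ape::rtree(7)
    ntip <- 7
    t0$edge.length <- ifelse(t0$edge[, 2] > ntip, 0.4, 0.02)
    sim <- evolve_sequences(as_chronogram(force_ultrametric(t0)),
                            list(kind = "strict", rate = 1),
                            substitution_model("JC"), 2000, seed = s + 500)
    res <- parsimony_search(sim$alignment, n_addition_replicates = 3,
                            seed = s)
    if (any(vapply(res$trees, function(tt)
      topology_key(tt) == topology_key(sim$chronogram$tree), logical(1))))
      hits <- hits + 1L
    # swapping can only improve on stepwise addition
    res0 <- parsimony_search(sim$alignment, n_addition_replicates = 3,
                             swap = "none", seed = s)
    expect_lte(res$score, res0$score)
  }
  expect_gte(hits, 9L)
})

test_that("NNI ML search: local optimum, monotonicity, convergence from NJ", {
  chr <- simulate_yule_chronogram(8, 0.6, 301)
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, 20000,
                          seed = 302)
  A <- sim$alignment
  true_topo <- chr$tree

  res <- nni_ml_search(A, m, true_topo)    # start at the truth: stays there
  expect_identical(topology_key(res$tree), topology_key(true_topo))

  njt <- nj_tree(A)
  start_fit <- optimize_branch_lengths(ape::unroot(njt), A, m)
  res2 <- nni_ml_search(A, m, njt)
  expect_gte(res2$loglik, start_fit$loglik - 1e-6)
  expect_identical(topology_key(res2$tree), topology_key(true_topo))
})

test_that("bootstrap: saturation, determinism, support range", {
  # zero-homoplasy data with long branches: every split fully supported
  set.seed(77)
  t0 <- ape::rtree(6)
  t0$edge.length <- rep(0.5, nrow(t0$edge))
  sim <- evolve_sequences(as_chronogram(force_ultrametric(t0)),
                          list(kind = "strict", rate = 0.3),
                          substitution_model("JC"), 4000, seed = 78)
  b <- bootstrap_tree(sim$alignment, "nj", n_replicates = 30, seed = 5)
  expect_true(all(b$supports >= 0 & b$supports <= 100))
  expect_true(all(b$supports >= 95))

  b2 <- bootstrap_tree(sim$alignment, "nj", n_replicates = 30, seed = 5)
  expect_identical(b$supports, b2$supports)
  b3 <- bootstrap_tree(sim$alignment, "parsimony", n_replicates = 10, seed = 5)
  expect_true(all(b3$supports >= 0 & b3$supports <= 100))
})

test_that("bootstrap support for the true clade grows with alignment length", {
  # moderate-signal clade; supports at 500 vs 10000 columns
  chr <- simulate_yule_chronogram(6, 1, 611)
  m <- substitution_model("JC")
  sup <- vapply(c(500, 10000), function(L) {
    sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, L,
                            seed = 612)
    b <- bootstrap_tree(sim$alignment, "nj", n_replicates = 40, seed = 6,
                        point_tree = chr$tree)
    mean(b$supports)
  }, numeric(1))
  expect_gte(sup[2], sup[1])
  expect_gte(sup[2], 90)
})

test_that("majority consensus: identity, hand-counted splits, library agreement", {
  tr <- read_newick("((a,b),(c,d),e);")
  cons <- majority_consensus(list(tr, tr, tr))
  expect_identical(topology_key(cons), topology_key(tr))
  expect_true(all(stats::na.omit(as.numeric(cons$node.label)) == 100))

  trees <- list(read_newick("((a,b),(c,d),e);"),
                read_newick("((a,b),(c,e),d);"),
                read_newick("((a,b),c,(d,e));"))
  cons <- majority_consensus(trees)
  # only the {a,b} split appears in more than half (3/3); others 1/3 each
  sp <- tree_splits(cons)
  expect_identical(sp, "c,d,e")  # complement of {a,b} (side without "a")
  expect_identical(topology_key(cons),
                   topology_key(ape::consensus(trees, p = 0.5)))
  expect_error(majority_consensus(list(tr, read_newick("((a,b),(c,x),e);"))),
               "identical taxon set")
})

test_that("out-group rooting is reversible and validates the taxon", {
  for (s in 1:3) {
    tr <- random_bl_tree(6, seed = s + 40)
    rt <- root_with_outgroup(tr, "t2")
    expect_true(ape::is.rooted(rt))
    expect_identical(topology_key(rt), topology_key(tr))
    kids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1, 2]
    expect_true(which(rt$tip.label == "t2") %in% kids)
  }
  expect_error(root_with_outgroup(random_bl_tree(5), "zz"), "zz")
})

test_that("NJ, parsimony and ML agree on clean simulated data", {
  chr <- simulate_yule_chronogram(8, 0.8, 901)
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, 10000,
                          seed = 902)
  A <- sim$alignment
  k_nj <- topology_key(nj_tree(A, m))
  k_mp <- topology_key(parsimony_search(A, n_addition_replicates = 3,
                                        seed = 1)$trees[[1]])
  k_ml <- topology_key(nni_ml_search(A, m, nj_tree(A))$tree)
  expect_identical(k_nj, k_mp)
  expect_identical(k_mp, k_ml)
})
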