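test_that("Yule chronograms are ultrametric, ordered and seed-deterministic", {
  for (s in 1:5) {
    chr <- simulate_yule_chronogram(sample(3:9, 1), runif(1, 0.2, 2), s)
    e <- chr$tree$edge
    expect_true(all(chr$ages[e[, 1]] > chr$ages[e[, 2]]))
    expect_true(all(chr$ages[seq_len(chr$ntip)] == 0))
  }
  a <- simulate_yule_chronogram(7, 1.3, 99)
  b <- simulate_yule_chronogram(7, 1.3, 99)
  expect_identical(write_newick(chronogram_phylo(a)),
                   write_newick(chronogram_phylo(b)))
})

test_that("near-zero branch lengths leave all sequences identical to the root", {
  chr <- simulate_yule_chronogram(4, 1, 5)
  m <- substitution_model("HKY", kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 1e-12), m, 500,
                          seed = 6)
  seqs <- unlist(sim$sequences)
  expect_identical(length(unique(seqs)), 1L)
})

test_that("observed divergence matches the model expectation (3 binomial SDs)", {
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 4)
  chr <- simulate_yule_chronogram(2, 1, 3)
  d <- 2 * root_age(chr) * 0.02
  L <- 50000
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), m, L,
                          seed = 4)
  obs <- pairwise_differences(sim$alignment, "t1", "t2") / L
  P <- transition_probabilities(m, d)
  expected <- 1 - sum(m$base_freqs * diag(P))
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / L))
})

test_that("transition:transversion counts reflect the simulating kappa", {
  m <- substitution_model("HKY", base_freqs = c(.3, .2, .2, .3), kappa = 4)
  chr <- simulate_yule_chronogram(2, 1, 13)
  d <- 2 * root_age(chr) * 0.02
  L <- 50000
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), m, L,
                          seed = 14)
  a <- unclass(sim$alignment)[1, ]; b <- unclass(sim$alignment)[2, ]
  diff <- a != b
  ts <- sum((a %in% c("A", "G") & b %in% c("A", "G") & diff) |
              (a %in% c("C", "T") & b %in% c("C", "T") & diff))
  tv <- sum(diff) - ts
  # expected counts from the model's own transition matrix
  P <- transition_probabilities(m, d)
  M <- m$base_freqs * P
  is_ts <- matrix(FALSE, 4, 4); is_ts[1, 3] <- is_ts[3, 1] <- TRUE
  is_ts[2, 4] <- is_ts[4, 2] <- TRUE
  p_ts <- sum(M[is_ts]); p_tv <- 1 - sum(diag(M)) - p_ts
  expect_lt(abs(ts - L * p_ts), 3 * sqrt(L * p_ts))
  expect_lt(abs(tv - L * p_tv), 3 * sqrt(L * p_tv))
})

test_that("indel-on and indel-off runs share substitution outcomes on
           ungapped columns (same seed)", {
  chr <- simulate_yule_chronogram(5, 0.8, 51)
  m <- substitution_model("HKY", kappa = 3)
  on <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, 2000,
                         indel_rate = 2e-3, seed = 52)
  off <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, 2000,
                          indel_rate = 0, seed = 52)
  expect_gt(on$n_indel_events, 0)
  A_on <- unclass(on$alignment)[rownames(off$alignment), , drop = FALSE]
  gapless <- A_on[, colSums(A_on == "-") == 0, drop = FALSE]
  # gap-free columns of the indel run appear, in order, in the indel-free run
  A_off <- unclass(off$alignment)
  j <- 1L; ok <- TRUE
  for (col in seq_len(ncol(gapless))) {
    found <- FALSE
    while (j <= ncol(A_off)) {
      hit <- all(A_off[, j] == gapless[, col])
      j <- j + 1L
      if (hit) { found <- TRUE; break }
    }
    if (!found) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("quadripartite structure emits IRb as the reverse complement of IRa", {
  st <- plastome_structure(lsc_length = 400, ssc_length = 100, ir_length = 150)
  chr <- simulate_yule_chronogram(4, 1, 61)
  m <- substitution_model("HKY", kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, st,
                          indel_rate = 1e-3, seed = 62)
  comp <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-")
  ps <- attr(sim$alignment, "partition")
  ir_cols <- partition_columns(ps, "IR")
  # IR columns come in two blocks; second block reversed+complemented = first
  half <- length(ir_cols) / 2
  ira <- unclass(sim$alignment)[, ir_cols[seq_len(half)], drop = FALSE]
  irb <- unclass(sim$alignment)[, rev(ir_cols[(half + 1):length(ir_cols)]),
                                drop = FALSE]
  expect_identical(unname(ira), unname(matrix(comp[irb], nrow = nrow(irb))))
  expect_identical(sort(names(ps$partitions)), c("IR", "LSC", "SSC"))
})

test_that("mean pairwise distance approaches the chronogram expectation with
           length", {
  chr <- simulate_yule_chronogram(5, 0.8, 71)
  m <- substitution_model("JC")
  rel_err <- vapply(c(1000, 20000), function(L) {
    sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, L,
                            seed = 72)
    D <- distance_matrix(sim$alignment, m)
    truth <- cophenetic(chronogram_phylo(chr)) * 0.01
    truth <- truth[rownames(D), colnames(D)]
    mean(abs(D[upper.tri(D)] - truth[upper.tri(truth)]) /
           truth[upper.tri(truth)])
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.15)
})

test_that("fixture bundles are written completely and reproducibly", {
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_fixture("tiny", seed = 5, dir = d1)
  f2 <- make_fixture("tiny", seed = 5, dir = d2)
  expected_files <- c("alignment.fasta", "sequences.fasta", "true_tree.nwk",
                      "chronogram.nwk", "partitions.txt", "manifest.txt")
  expect_true(all(file.exists(file.path(d1, expected_files))))
  for (f in expected_files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # manifest records the parameters needed to regenerate
  man <- readLines(file.path(d1, "manifest.txt"))
  expect_true(any(grepl("^profile=tiny", man)))
  expect_true(any(grepl("^seed=5", man)))
  # stress profile produces saturation-range divergence
  fx <- make_fixture("stress", seed = 3)
  D <- pairwise_difference_matrix(fx$alignment)
  p <- max(D[upper.tri(D)]) / ncol(fx$alignment)
  expect_gt(p, 0.5)
})
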