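test_that("chronogram construction enforces ultrametric age order", {
  tr <- read_newick("((a,b),c);")
  expect_s3_class(chronogram(tr, c(2, 1)), "chronogram")
  expect_error(chronogram(tr, c(1, 2)), "non-ultrametric")
  expect_error(as_chronogram(read_newick("((a:1,b:2):1,c:3);")),
               "not ultrametric")
})

test_that("Yule log prior: closed form and scaling of the rate MLE", {
  tr <- read_newick("((a,b),c);")
  chr <- chronogram(tr, c(2, 1))
  # L = (2-1) + 2 + 1 + 1 = 5; (n-1) log(lambda) - lambda L
  expect_equal(yule_log_prior(chr, 1), -5, tolerance = 1e-12)
  expect_equal(yule_log_prior(chr, 2), 2 * log(2) - 10, tolerance = 1e-12)

  # scaling ages by c scales the lambda MLE by 1/c
  lam_mle <- function(chr) {
    opt <- optimize(function(l) -yule_log_prior(chr, l), c(1e-6, 50))
    opt$minimum
  }
  for (s in 1:3) {
    chr <- simulate_yule_chronogram(6, 1, s)
    chr3 <- chronogram(chr$tree, chr$ages[7:11] * 3)
    expect_equal(lam_mle(chr3), lam_mle(chr) / 3, tolerance = 1e-3)
  }
})

test_that("forward Yule simulation matches the prior's expected root age", {
  # under the labelled-history density lambda^(n-1) exp(-lambda L), the root
  # age is a sum of Exp(k * lambda) waits for k = 2..n
  ra <- vapply(1:4000, function(s) root_age(simulate_yule_chronogram(5, 1, s)),
               numeric(1))
  expected <- sum(1 / (2:5))
  expect_lt(abs(mean(ra) - expected), 3 * stats::sd(ra) / sqrt(length(ra)))
  # n = 2: single split, root age ~ Exp(2 lambda)
  ra2 <- vapply(1:4000, function(s) root_age(simulate_yule_chronogram(2, 1, s)),
                numeric(1))
  expect_lt(abs(mean(ra2) - 0.5), 3 * stats::sd(ra2) / sqrt(length(ra2)))
})

test_that("HPD interval: degenerate input, brute-force oracle, errors", {
  expect_identical(hpd_interval(rep(3.3, 10)), c(3.3, 3.3))
  expect_error(hpd_interval(1), "at least 2")

  brute_hpd <- function(x, mass) {       # literal minimum-width window scan
    s <- sort(x); n <- length(s); m <- ceiling(mass * n)
    best <- c(-Inf, Inf)
    for (i in seq_len(n - m + 1))
      if (s[i + m - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + m - 1])
    best
  }
  set.seed(404)
  for (i in 1:30) {
    x <- switch(1 + (i %% 3), rnorm(200), rexp(150), rlnorm(120))
    mass <- sample(c(0.5, 0.9, 0.95), 1)
    expect_identical(hpd_interval(x, mass), brute_hpd(x, mass))
  }
})

test_that("effective sample size behaves like n for white noise and
           collapses under autocorrelation", {
  set.seed(42)
  x <- rnorm(2000)
  expect_gt(effective_sample_size(x), 0.8 * 2000)
  expect_lte(effective_sample_size(x), 2000)
  y <- as.numeric(stats::filter(rnorm(2000), 0.95, method = "recursive"))
  expect_lt(effective_sample_size(y), 500)
  expect_identical(effective_sample_size(rep(1, 50)), 50L)
})

test_that("chronogram likelihood: strict-clock definition, rate-time
           rescaling, relaxed collapse", {
  chr <- simulate_yule_chronogram(5, 1, 9)
  m <- substitution_model("HKY", kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.02), m, 1500,
                          seed = 10)
  A <- sim$alignment
  ll <- chronogram_log_likelihood(chr, list(kind = "strict", rate = 0.02), A, m)
  phy <- chronogram_phylo(chr, rep(0.02, nrow(chr$tree$edge)))
  expect_equal(ll, log_likelihood(phy, A, m), tolerance = 1e-12)

  # doubling rates and halving ages leaves the likelihood unchanged
  chr_half <- chronogram(chr$tree, chr$ages[6:9] / 2)
  ll2 <- chronogram_log_likelihood(chr_half,
                                   list(kind = "strict", rate = 0.04), A, m)
  expect_equal(ll2, ll, tolerance = 1e-10)

  # relaxed clock with all branch rates equal collapses to strict
  n_e <- nrow(chr$tree$edge)
  ll3 <- chronogram_log_likelihood(chr, list(kind = "relaxed_lognormal",
                                             branch_rates = rep(0.02, n_e)),
                                   A, m)
  expect_equal(ll3, ll, tolerance = 1e-12)
})

test_that("dating MCMC validates its inputs", {
  A <- random_alignment(4, 60, seed = 3)
  topo <- read_newick("((t1,t2),(t3,t4));")
  expect_error(run_dating_mcmc(A, ape::unroot(topo), "strict",
                               list(calibration(c("t1", "t2"), "normal", 5, 1))),
               "rooted")
  # a non-root, non-monophyletic clade is rejected (a pair spanning the
  # root is allowed: it calibrates the root age)
  cat_topo <- read_newick("(((t1,t2),t3),t4);")
  expect_error(run_dating_mcmc(A, cat_topo, "strict",
                               list(calibration(c("t1", "t3"), "normal", 5, 1))),
               "monophyletic")
  expect_error(run_dating_mcmc(A, topo, "strict", list()), "calibration")
})

test_that("same seed reproduces the trace; different seeds agree within MC error", {
  A <- random_alignment(4, 200, seed = 8)
  topo <- read_newick("((t1,t2),(t3,t4));")
  cal <- list(calibration(paste0("t", 1:4), "normal", 10, 1))
  cfg <- mcmc_config(chain_length = 6000, sample_every = 10, burn_in = 2000,
                     seed = 11)
  f1 <- run_dating_mcmc(A, topo, "strict", cal, cfg, model_spec = "HKY")
  f2 <- run_dating_mcmc(A, topo, "strict", cal, cfg, model_spec = "HKY")
  expect_identical(f1$trace, f2$trace)

  cfg3 <- mcmc_config(chain_length = 6000, sample_every = 10, burn_in = 2000,
                      seed = 99)
  f3 <- run_dating_mcmc(A, topo, "strict", cal, cfg3, model_spec = "HKY")
  se <- function(f) {
    x <- f$trace$age_5
    stats::sd(x) / sqrt(effective_sample_size(x))
  }
  expect_lt(abs(mean(f1$trace$age_5) - mean(f3$trace$age_5)),
            4 * (se(f1) + se(f3)))
})

test_that("posterior summaries carry means, HPDs, ESS and clade labels", {
  chr <- simulate_yule_chronogram(5, 0.8, 21)
  m <- substitution_model("HKY", kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "strict", rate = 0.01), m, 4000,
                          seed = 22)
  cal <- list(calibration(chr$tree$tip.label, "normal", root_age(chr),
                          0.1 * root_age(chr)))
  cfg <- mcmc_config(chain_length = 8000, sample_every = 10, burn_in = 2000,
                     seed = 23)
  fit <- run_dating_mcmc(sim$alignment, chr$tree, "strict", cal, cfg,
                         model_spec = "HKY")
  s <- summarize_dating(fit)
  expect_true(all(s$hpd_lo <= s$hpd_hi))
  expect_true(all(s$ess > 0))
  root_row <- s[s$parameter == "age_6", ]
  expect_identical(root_row$clade,
                   paste(sort(chr$tree$tip.label), collapse = ","))
  # HPD contains at least the nominal share of the sampled values
  x <- fit$trace$age_6
  inside <- mean(x >= root_row$hpd_lo & x <= root_row$hpd_hi)
  expect_gte(inside, 0.95)
  mc <- mean_chronogram(fit)
  expect_s3_class(mc, "chronogram")
})

test_that("relaxed-clock posteriors are wider than strict at matched nodes
           when branch rates truly vary", {
  chr <- simulate_yule_chronogram(6, 0.8, 31)
  m <- substitution_model("HKY", kappa = 3)
  sim <- evolve_sequences(chr, list(kind = "relaxed_lognormal",
                                    mean_log = log(0.02), sd_log = 0.8),
                          m, 4000, seed = 32)
  cal <- list(calibration(chr$tree$tip.label, "normal", root_age(chr),
                          0.05 * root_age(chr)))
  cfg <- mcmc_config(chain_length = 12000, sample_every = 10, burn_in = 4000,
                     seed = 33)
  fs <- run_dating_mcmc(sim$alignment, chr$tree, "strict", cal, cfg,
                        model_spec = "HKY")
  fr <- run_dating_mcmc(sim$alignment, chr$tree, "relaxed_lognormal", cal, cfg,
                        model_spec = "HKY")
  width <- function(f) {
    cols <- grep("^age_", colnames(f$trace), value = TRUE)
    cols <- setdiff(cols, "age_7")  # root is pinned by the calibration
    mean(vapply(cols, function(cn) diff(hpd_interval(f$trace[[cn]])),
                numeric(1)))
  }
  expect_gt(width(fr), width(fs))
})
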