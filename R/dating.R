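# --- chronogram container ----------------------------------------------------

#' Construct a chronogram (rooted ultrametric tree with node ages)
#'
#' @param tree Rooted binary `phylo`.
#' @param ages Numeric vector of ages (Myr) for internal nodes, named or
#'   ordered by node id `ntip+1 ... ntip+Nnode`; tips are at age 0.
#' @return Object of class `chronogram` with `tree`, `ages` (full vector over
#'   all node ids, tips 0).
#' @export
chronogram <- function(tree, ages) {
  ntip <- length(tree$tip.label)
  if (!ape::is.rooted(tree)) stop("chronogram requires a rooted tree")
  if (!ape::is.binary(tree)) stop("chronogram requires a binary tree")
  full <- numeric(ntip + tree$Nnode)
  full[(ntip + 1):(ntip + tree$Nnode)] <- ages
  for (k in seq_len(nrow(tree$edge))) {
    a <- full[tree$edge[k, 1]]; b <- full[tree$edge[k, 2]]
    if (a <= b) stop("non-ultrametric ages: parent age ", a,
                     " <= child age ", b)
  }
  structure(list(tree = tree, ages = full, ntip = ntip), class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("<chronogram> ", x$ntip, " tips, root age ",
      signif(root_age(x), 5), " Myr\n", sep = "")
  invisible(x)
}

root_node <- function(tree) length(tree$tip.label) + 1L

#' Root age of a chronogram
#' @param chr A [chronogram()].
#' @return Age in Myr.
#' @export
root_age <- function(chr) chr$ages[root_node(chr$tree)]

#' Convert a chronogram to an ultrametric phylo (edge lengths in Myr)
#' @param chr A [chronogram()].
#' @param rates Optional per-edge rate multipliers (subs/site/Myr) turning
#'   durations into substitution branch lengths.
#' @return `phylo`.
#' @export
chronogram_phylo <- function(chr, rates = NULL) {
  phy <- chr$tree
  dur <- chr$ages[phy$edge[, 1]] - chr$ages[phy$edge[, 2]]
  phy$edge.length <- if (is.null(rates)) dur else dur * rates
  phy
}

#' Build a chronogram from an ultrametric phylo
#' @param phy Rooted binary ultrametric `phylo` with edge lengths (ages
#'   recovered as depths below the root height).
#' @param tol Ultrametricity tolerance.
#' @return A [chronogram()].
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(ntip)])
  if (any(abs(depth[seq_len(ntip)] - h) > tol * max(h, 1)))
    stop("tree is not ultrametric")
  ages <- h - depth
  ages[seq_len(ntip)] <- 0
  chronogram(phy, ages[(ntip + 1):(ntip + phy$Nnode)])
}

# Node id of the most recent common ancestor of a taxon set; checks presence.
mrca_node <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("calibration taxa not in tree: ", paste(miss, collapse = ", "))
  if (length(taxa) == 1) return(which(tree$tip.label == taxa))
  ape::getMRCA(tree, taxa)
}

clade_is_monophyletic <- function(tree, taxa) {
  if (length(taxa) <= 1) return(TRUE)
  node <- mrca_node(tree, taxa)
  setequal(unrooted_tips_below(tree, node), taxa)
}

# --- priors ------------------------------------------------------------------

#' Yule (pure-birth) log prior for a chronogram
#'
#' Log density of the labelled-history Yule process, up to a constant:
#' `(n-1) log(lambda) - lambda * L` where `L` is the total branch duration.
#' This matches the forward model in [simulate_yule_chronogram()] (present
#' taken at the moment the (n+1)-th lineage would arise).
#'
#' @param chr A [chronogram()].
#' @param birth_rate Speciation rate lambda (> 0, per Myr).
#' @return Log density (scalar).
#' @export
yule_log_prior <- function(chr, birth_rate) {
  stopifnot(birth_rate > 0)
  n <- chr$ntip
  L <- sum(chr$ages[chr$tree$edge[, 1]] - chr$ages[chr$tree$edge[, 2]])
  (n - 1) * log(birth_rate) - birth_rate * L
}

#' Define a node-age calibration
#'
#' @param taxa Tip labels whose MRCA is calibrated.
#' @param density `"normal"`, `"lognormal"` or `"uniform"`.
#' @param par1,par2 Density parameters: mean/sd (normal), meanlog/sdlog
#'   (lognormal), lower/upper (uniform); units Myr.
#' @return Object of class `calibration`.
#' @export
calibration <- function(taxa, density = c("normal", "lognormal", "uniform"),
                        par1, par2) {
  density <- match.arg(density)
  structure(list(taxa = taxa, density = density, par1 = par1, par2 = par2),
            class = "calibration")
}

calibration_logdens <- function(cal, age) {
  switch(cal$density,
         normal = stats::dnorm(age, cal$par1, cal$par2, log = TRUE),
         lognormal = stats::dlnorm(age, cal$par1, cal$par2, log = TRUE),
         uniform = stats::dunif(age, cal$par1, cal$par2, log = TRUE))
}

# Calibrated-Yule log prior over node ages. Root calibrations use the exact
# conditional construction: given root age t and n tips, the n-2 non-root
# node ages are iid truncated-Exp(lambda) on [0, t], so the root marginal is
# exactly the calibration density. Non-root calibrations multiply the plain
# Yule density by their calibration density (approximate construction).
calibrated_yule_log_prior <- function(chr, birth_rate, calibrations, cal_nodes) {
  root <- root_node(chr$tree)
  root_cal_idx <- which(cal_nodes == root)
  lp <- 0
  if (length(root_cal_idx)) {
    rc <- calibrations[[root_cal_idx[1]]]
    t_root <- chr$ages[root]
    others <- chr$ages[setdiff((chr$ntip + 1):(chr$ntip + chr$tree$Nnode), root)]
    lp <- calibration_logdens(rc, t_root) +
      sum(log(birth_rate) - birth_rate * others) -
      (chr$ntip - 2) * log1p(-exp(-birth_rate * t_root))
    extra <- setdiff(seq_along(calibrations), root_cal_idx[1])
  } else {
    lp <- yule_log_prior(chr, birth_rate)
    extra <- seq_along(calibrations)
  }
  for (i in extra)
    lp <- lp + calibration_logdens(calibrations[[i]], chr$ages[cal_nodes[i]])
  lp
}

# --- likelihood under a clock ------------------------------------------------

#' Log-likelihood of an alignment given a chronogram and clock model
#'
#' Branch lengths in substitutions/site are branch durations times branch
#' rates; the pruning likelihood is summed over partitions when a
#' partitioned alignment and per-partition models are supplied.
#'
#' @param chr A [chronogram()].
#' @param clock List: `kind = "strict"` with `rate`, or
#'   `kind = "relaxed_lognormal"` with `branch_rates` (per edge,
#'   subs/site/Myr).
#' @param alignment A [as_alignment()] matrix (optionally with partition).
#' @param models A `subst_model` or named list per partition.
#' @return Log-likelihood.
#' @export
chronogram_log_likelihood <- function(chr, clock, alignment, models) {
  rates <- clock_edge_rates(clock, nrow(chr$tree$edge))
  phy <- chronogram_phylo(chr, rates)
  log_likelihood(phy, alignment, models, attr(alignment, "partition"))
}

clock_edge_rates <- function(clock, n_edges) {
  if (clock$kind == "strict") rep(clock$rate, n_edges)
  else if (clock$kind == "relaxed_lognormal") {
    stopifnot(length(clock$branch_rates) == n_edges)
    clock$branch_rates
  } else stop("unknown clock kind: ", clock$kind)
}

# --- MCMC --------------------------------------------------------------------

#' Default MCMC configuration for divergence dating
#'
#' Chain settings follow the only chain parameters printed in the study
#' design this package mirrors (1.1e6 steps, sampling every 200, burn-in
#' 1e5); tests and the bundled analyses scale these down.
#'
#' @param chain_length,sample_every,burn_in,seed Standard MCMC controls.
#' @param use_likelihood Set `FALSE` to sample from the prior only.
#' @return List of settings.
#' @export
mcmc_config <- function(chain_length = 1100000L, sample_every = 200L,
                        burn_in = 100000L, seed = 1L, use_likelihood = TRUE) {
  stopifnot(burn_in < chain_length, sample_every >= 1)
  list(chain_length = as.integer(chain_length),
       sample_every = as.integer(sample_every),
       burn_in = as.integer(burn_in), seed = as.integer(seed),
       use_likelihood = isTRUE(use_likelihood))
}

#' Bayesian divergence dating on a fixed rooted topology
#'
#' Metropolis-Hastings over internal node ages (uniform slides within
#' parent/child bounds; multiplicative root scale), the Yule birth rate, the
#' clock parameters (strict global rate, or lognormal mean/sd plus per-branch
#' rates) and the substitution parameters (kappa and gamma shape per
#' partition). The posterior combines the pruning likelihood, the
#' calibrated-Yule prior and weakly informative parameter priors
#' (`lambda ~ 1/lambda`, `rate ~ 1/rate`, `kappa ~ LogNormal(1, 1.25)`,
#' `alpha ~ Exp(1)`, relaxed-clock `sd ~ Exp(1)`).
#'
#' @param alignment A [as_alignment()] matrix (partition attribute honoured).
#' @param fixed_topology Rooted binary `phylo` over the alignment taxa.
#' @param clock_kind `"strict"` or `"relaxed_lognormal"`.
#' @param calibrations List of [calibration()] objects (>= 1); each clade
#'   must be monophyletic in the fixed topology.
#' @param config See [mcmc_config()].
#' @param model_spec Substitution model for every partition (study default
#'   HKY with four gamma categories).
#' @return Object of class `dating_mcmc`: `trace` (data.frame of sampled
#'   states), `node_clades` (named list mapping age columns to tip sets),
#'   `acceptance` (per-move-type rates), `topology`, `clock_kind`, `config`.
#' @export
run_dating_mcmc <- function(alignment, fixed_topology,
                            clock_kind = c("strict", "relaxed_lognormal"),
                            calibrations, config = mcmc_config(),
                            model_spec = "HKY+G4") {
  clock_kind <- match.arg(clock_kind)
  phy <- fixed_topology
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("fixed topology must be rooted and binary")
  if (!setequal(phy$tip.label, rownames(alignment)))
    stop("topology tips and alignment taxa differ: ",
         paste(c(setdiff(phy$tip.label, rownames(alignment)),
                 setdiff(rownames(alignment), phy$tip.label)), collapse = ", "))
  if (length(calibrations) < 1) stop("at least one calibration is required")
  for (cal in calibrations) {
    node <- mrca_node(phy, cal$taxa)
    # a pair spanning the root (e.g. two outgroup-side taxa) legitimately
    # calibrates the root age; otherwise the clade must be monophyletic
    if (node != length(phy$tip.label) + 1L &&
        !clade_is_monophyletic(phy, cal$taxa))
      stop("calibration clade is not monophyletic in the topology: ",
           paste(cal$taxa, collapse = ", "))
  }
  cal_nodes <- vapply(calibrations, function(cal) mrca_node(phy, cal$taxa),
                      integer(1))
  ntip <- length(phy$tip.label)
  n_int <- phy$Nnode
  root <- ntip + 1L
  n_edges <- nrow(phy$edge)

  # per-partition compressed data and parameter state
  part <- attr(alignment, "partition")
  part_names <- if (is.null(part)) "all" else {
    nm <- names(part$partitions)
    assigned <- unlist(lapply(nm, partition_columns, ps = part))
    if (length(assigned) < ncol(alignment)) c(nm, "default") else nm
  }
  pds <- lapply(part_names, function(nm) {
    cols <- if (is.null(part)) seq_len(ncol(alignment))
            else if (nm == "default")
              setdiff(seq_len(ncol(alignment)),
                      unlist(lapply(names(part$partitions), partition_columns, ps = part)))
            else partition_columns(part, nm)
    aln <- subset_columns(alignment, cols)
    list(pd = compress_patterns(aln), freqs = empirical_base_freqs(aln))
  })
  names(pds) <- part_names
  proto <- parse_model_spec(model_spec)
  has_gamma <- !is.null(proto$gamma_shape)
  build_models <- function(kappas, alphas) {
    lapply(seq_along(part_names), function(i)
      substitution_model(proto$name, base_freqs = pds[[i]]$freqs,
                         kappa = kappas[i],
                         gamma_shape = if (has_gamma) alphas[i] else NULL,
                         n_gamma_categories = proto$n_gamma_categories,
                         p_invariant = proto$p_invariant))
  }

  # initial state: ages from node depth ranks scaled to the calibration
  target_root <- init_root_age(calibrations, cal_nodes, root)
  ages <- init_ages(phy, target_root)
  lambda <- max(1e-4, (ntip - 1) / sum_durations(phy, ages))
  kappas <- rep(if (proto$name %in% c("K80", "HKY")) proto$kappa else 1, length(part_names))
  alphas <- rep(if (has_gamma) proto$gamma_shape else 1, length(part_names))
  rate <- init_clock_rate(alignment, target_root)
  mean_log <- log(rate); sd_log <- 0.3
  branch_rates <- rep(rate, n_edges)

  chr_of <- function(a) chronogram(phy, a[(ntip + 1):(ntip + n_int)])
  loglik_of <- function(a, brates, kap, alp) {
    if (!config$use_likelihood) return(0)
    models <- build_models(kap, alp)
    chr <- chr_of(a)
    tot <- 0
    for (i in seq_along(part_names)) {
      phy_bl <- chronogram_phylo(chr, brates)
      tot <- tot + log_likelihood(phy_bl, pds[[i]]$pd, models[[i]])
    }
    tot
  }
  prior_of <- function(a, lam, rt, ml, sl, brates, kap, alp) {
    if (any(a[phy$edge[, 1]] <= a[phy$edge[, 2]])) return(-Inf)
    chr <- chr_of(a)
    lp <- calibrated_yule_log_prior(chr, lam, calibrations, cal_nodes)
    if (lam < 1e-6 || lam > 1e3) return(-Inf)
    lp <- lp - log(lam)
    if (clock_kind == "strict") {
      if (rt < 1e-9 || rt > 1e2) return(-Inf)
      lp <- lp - log(rt)
    } else {
      if (exp(ml) < 1e-9 || exp(ml) > 1e2 || sl < 0) return(-Inf)
      lp <- lp - ml + stats::dexp(sl, 1, log = TRUE) +
        sum(stats::dlnorm(brates, ml, max(sl, 1e-6), log = TRUE))
    }
    lp <- lp + sum(stats::dlnorm(kap, 1, 1.25, log = TRUE))
    if (has_gamma) lp <- lp + sum(stats::dexp(alp, 1, log = TRUE))
    lp
  }

  cur_rates <- function() if (clock_kind == "strict") rep(rate, n_edges) else branch_rates
  set.seed(config$seed)
  cur_ll <- loglik_of(ages, cur_rates(), kappas, alphas)
  cur_lp <- prior_of(ages, lambda, rate, mean_log, sd_log, branch_rates, kappas, alphas)
  if (!is.finite(cur_lp)) stop("initial state has zero prior probability")

  move_types <- c("age_slide", "root_scale", "updown_scale", "lambda_scale",
                  if (clock_kind == "strict") "rate_scale"
                  else c("meanlog_slide", "sdlog_scale", "branch_rate_scale"),
                  "kappa_scale", if (has_gamma) "alpha_scale")
  move_w <- c(age_slide = max(1, n_int - 1), root_scale = 1, updown_scale = 3,
              lambda_scale = 1,
              rate_scale = 2, meanlog_slide = 2, sdlog_scale = 1,
              branch_rate_scale = max(1, n_edges / 2),
              kappa_scale = length(part_names), alpha_scale = length(part_names))
  w <- move_w[move_types] / sum(move_w[move_types])
  att <- acc <- stats::setNames(numeric(length(move_types)), move_types)

  children <- lapply(seq_len(ntip + n_int), function(v) phy$edge[phy$edge[, 1] == v, 2])
  parent <- integer(ntip + n_int)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  internal_nonroot <- setdiff((ntip + 1L):(ntip + n_int), root)

  n_samples <- (config$chain_length - config$burn_in) %/% config$sample_every
  age_cols <- paste0("age_", (ntip + 1):(ntip + n_int))
  trace_cols <- c("state", "posterior", "loglik", "prior", "lambda",
                  if (clock_kind == "strict") "clock_rate" else c("clock_meanlog", "clock_sdlog"),
                  paste0("kappa_", part_names),
                  if (has_gamma) paste0("alpha_", part_names), age_cols)
  trace <- matrix(NA_real_, n_samples, length(trace_cols),
                  dimnames = list(NULL, trace_cols))
  s_i <- 0L

  for (it in seq_len(config$chain_length)) {
    mv <- sample(move_types, 1, prob = w)
    att[mv] <- att[mv] + 1
    new_ages <- ages; new_lambda <- lambda; new_rate <- rate
    new_ml <- mean_log; new_sl <- sd_log; new_br <- branch_rates
    new_kap <- kappas; new_alp <- alphas
    log_hastings <- 0
    affects_lik <- TRUE
    if (mv == "age_slide") {
      v <- if (length(internal_nonroot) == 1) internal_nonroot
           else sample(internal_nonroot, 1)
      lo <- max(ages[children[[v]]]); hi <- ages[parent[v]]
      new_ages[v] <- stats::runif(1, lo, hi)
    } else if (mv == "root_scale") {
      u <- stats::runif(1, -0.2, 0.2)
      new_ages[root] <- ages[root] * exp(u)
      log_hastings <- u
    } else if (mv == "updown_scale") {
      # joint scale along the rate-time ridge: ages up, rates down; branch
      # lengths (duration x rate) are unchanged, so the likelihood is too
      u <- stats::runif(1, -0.15, 0.15)
      idx <- (ntip + 1L):(ntip + n_int)
      new_ages[idx] <- ages[idx] * exp(u)
      if (clock_kind == "strict") {
        new_rate <- rate * exp(-u)
        log_hastings <- (n_int - 1) * u
      } else {
        new_br <- branch_rates * exp(-u)
        new_ml <- mean_log - u
        log_hastings <- (n_int - n_edges) * u
      }
      affects_lik <- FALSE
    } else if (mv == "lambda_scale") {
      u <- stats::runif(1, -0.5, 0.5)
      new_lambda <- lambda * exp(u); log_hastings <- u
      affects_lik <- FALSE
    } else if (mv == "rate_scale") {
      u <- stats::runif(1, -0.2, 0.2)
      new_rate <- rate * exp(u); log_hastings <- u
    } else if (mv == "meanlog_slide") {
      new_ml <- mean_log + stats::rnorm(1, 0, 0.1)
      affects_lik <- FALSE
    } else if (mv == "sdlog_scale") {
      u <- stats::runif(1, -0.3, 0.3)
      new_sl <- sd_log * exp(u); log_hastings <- u
      affects_lik <- FALSE
    } else if (mv == "branch_rate_scale") {
      e <- sample.int(n_edges, 1)
      u <- stats::runif(1, -0.3, 0.3)
      new_br[e] <- branch_rates[e] * exp(u); log_hastings <- u
    } else if (mv == "kappa_scale") {
      i <- sample.int(length(part_names), 1)
      u <- stats::runif(1, -0.2, 0.2)
      new_kap[i] <- kappas[i] * exp(u); log_hastings <- u
    } else if (mv == "alpha_scale") {
      i <- sample.int(length(part_names), 1)
      u <- stats::runif(1, -0.3, 0.3)
      new_alp[i] <- alphas[i] * exp(u); log_hastings <- u
    }
    new_lp <- prior_of(new_ages, new_lambda, new_rate, new_ml, new_sl,
                       new_br, new_kap, new_alp)
    if (is.finite(new_lp)) {
      new_ll <- if (affects_lik) {
        brs <- if (clock_kind == "strict") rep(new_rate, n_edges) else new_br
        loglik_of(new_ages, brs, new_kap, new_alp)
      } else cur_ll
      log_r <- (new_lp + new_ll) - (cur_lp + cur_ll) + log_hastings
      if (log(stats::runif(1)) < log_r) {
        ages <- new_ages; lambda <- new_lambda; rate <- new_rate
        mean_log <- new_ml; sd_log <- new_sl; branch_rates <- new_br
        kappas <- new_kap; alphas <- new_alp
        cur_lp <- new_lp; cur_ll <- new_ll
        acc[mv] <- acc[mv] + 1
      }
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$sample_every == 0) {
      s_i <- s_i + 1L
      row <- c(it, cur_lp + cur_ll, cur_ll, cur_lp, lambda,
               if (clock_kind == "strict") rate else c(mean_log, sd_log),
               kappas, if (has_gamma) alphas,
               ages[(ntip + 1):(ntip + n_int)])
      trace[s_i, ] <- row
    }
  }
  node_clades <- stats::setNames(
    lapply((ntip + 1):(ntip + n_int), function(v) sort(unrooted_tips_below(phy, v))),
    age_cols)
  structure(list(trace = as.data.frame(trace[seq_len(s_i), , drop = FALSE]),
                 node_clades = node_clades,
                 acceptance = ifelse(att > 0, acc / att, NA),
                 topology = phy, clock_kind = clock_kind, config = config),
            class = "dating_mcmc")
}

sum_durations <- function(phy, ages) {
  sum(ages[phy$edge[, 1]] - ages[phy$edge[, 2]])
}

init_root_age <- function(calibrations, cal_nodes, root) {
  means <- vapply(calibrations, function(cal) switch(cal$density,
    normal = cal$par1, lognormal = exp(cal$par1 + cal$par2^2 / 2),
    uniform = (cal$par1 + cal$par2) / 2), numeric(1))
  if (any(cal_nodes == root)) means[which(cal_nodes == root)[1]]
  else 2 * max(means)
}

init_ages <- function(phy, target_root) {
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth(phy)  # number of descendant tips
  ages <- numeric(ntip + phy$Nnode)
  idx <- (ntip + 1):(ntip + phy$Nnode)
  ages[idx] <- target_root * (depth[idx] - 1) / max(depth[idx] - 1)
  # enforce strict parent > child with a small nudge where ranks tie
  repeat {
    bad <- which(ages[phy$edge[, 1]] <= ages[phy$edge[, 2]])
    if (!length(bad)) break
    for (k in bad)
      ages[phy$edge[k, 1]] <- ages[phy$edge[k, 2]] +
        max(1e-6, 0.05 * target_root / ntip)
  }
  ages
}

init_clock_rate <- function(alignment, root_age) {
  d <- tryCatch({
    m <- pairwise_difference_matrix(alignment)
    mean(m[upper.tri(m)]) / ncol(alignment)
  }, error = function(e) 0.01)
  max(d / (2 * root_age), 1e-6)
}

#' @export
print.dating_mcmc <- function(x, ...) {
  cat("<dating_mcmc> ", x$clock_kind, " clock, ", nrow(x$trace),
      " samples\n", sep = "")
  invisible(x)
}

# --- posterior summaries -----------------------------------------------------

#' Highest posterior density interval
#'
#' The narrowest contiguous window of sorted samples containing
#' `ceiling(mass * n)` samples.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Target probability mass.
#' @return Numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples for an HPD interval")
  m <- ceiling(mass * n)
  s <- sort(samples)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[(m):n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive-sequence rule (consecutive lag pairs kept while
#' their sum is positive).
#'
#' @param samples Numeric vector.
#' @return Scalar ESS (equals `n` for white noise, capped at `n`).
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 4 || stats::var(samples) == 0) return(n)
  rho <- as.vector(stats::acf(samples, lag.max = min(n - 2, 2000),
                              plot = FALSE)$acf)[-1]
  tot <- 0
  m <- 1
  while (m + 1 <= length(rho)) {
    g <- rho[m] + rho[m + 1]
    if (g <= 0) break
    tot <- tot + g
    m <- m + 2
  }
  min(n, n / (1 + 2 * tot))
}

#' Summarize a dating MCMC run
#'
#' Per-parameter and per-node posterior mean, 95% HPD and ESS; node rows are
#' annotated with their clade's tip labels (the topology is fixed, so clade
#' summaries are exact and no MCC-tree search is needed).
#'
#' @param fit A `dating_mcmc` result.
#' @param mass HPD mass.
#' @return `data.frame` of class `posterior_summary` with columns
#'   `parameter`, `mean`, `hpd_lo`, `hpd_hi`, `ess`, `clade`.
#' @export
summarize_dating <- function(fit, mass = 0.95) {
  tr <- fit$trace
  if (nrow(tr) < 2) stop("need at least 2 post-burn-in samples to summarize")
  cols <- setdiff(colnames(tr), "state")
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- tr[[cn]]
    h <- hpd_interval(x, mass)
    data.frame(parameter = cn, mean = mean(x), hpd_lo = h[1], hpd_hi = h[2],
               ess = effective_sample_size(x), stringsAsFactors = FALSE)
  }))
  out$clade <- vapply(out$parameter, function(p) {
    if (p %in% names(fit$node_clades))
      paste(fit$node_clades[[p]], collapse = ",") else ""
  }, character(1))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Posterior-mean chronogram from a dating run
#' @param fit A `dating_mcmc` result.
#' @return A [chronogram()] with posterior-mean node ages.
#' @export
mean_chronogram <- function(fit) {
  ntip <- length(fit$topology$tip.label)
  ages <- vapply(paste0("age_", (ntip + 1):(ntip + fit$topology$Nnode)),
                 function(cn) mean(fit$trace[[cn]]), numeric(1))
  chronogram(fit$topology, ages)
}
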