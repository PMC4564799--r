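# IUPAC code -> 4-state partial likelihood columns (A, C, G, T)
iupac_partial_table <- function() {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"))
  tab <- sapply(codes, function(st) as.numeric(c("A", "C", "G", "T") %in% st))
  rownames(tab) <- c("A", "C", "G", "T")
  tab
}
IUPAC_PARTIAL <- iupac_partial_table()

#' Compress an alignment into site patterns for likelihood computation
#'
#' Identical columns are collapsed to one pattern with a weight; each taxon
#' gets a 4 x n_patterns partial-likelihood matrix (gaps/N/ambiguity give a
#' row of ones, i.e. missing data).
#'
#' @param alignment A [as_alignment()] matrix.
#' @return List with `patterns` (character matrix taxa x n_patterns),
#'   `weights`, `tip_partials` (named list of 4 x n_patterns matrices) and
#'   `invariant_compat` (4 x n_patterns 0/1 matrix: state i can explain the
#'   whole pattern).
#' @export
compress_patterns <- function(alignment) {
  mat <- unclass(alignment)
  keys <- do.call(paste0, lapply(seq_len(nrow(mat)), function(i) mat[i, ]))
  u <- unique(keys)
  idx <- match(keys, u)
  w <- tabulate(idx, nbins = length(u))
  first <- match(seq_along(u), idx)
  pat <- mat[, first, drop = FALSE]
  tips <- lapply(rownames(mat), function(tx) {
    IUPAC_PARTIAL[, pat[tx, ], drop = FALSE]
  })
  names(tips) <- rownames(mat)
  compat <- Reduce(`*`, tips)
  list(patterns = pat, weights = w, tip_partials = tips,
       invariant_compat = compat, n_sites = ncol(mat))
}

# Internal: per-category postorder partials at the root of `phy`.
# Returns list(cats -> 4 x P root partial matrix).
root_partials <- function(phy, pd, model) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  P <- length(pd$weights)
  ord <- match(phy$tip.label, names(pd$tip_partials))
  if (anyNA(ord)) stop("tree tips not in alignment: ",
                       paste(setdiff(phy$tip.label, names(pd$tip_partials)), collapse = ", "))
  lapply(model$gamma_rates, function(r) {
    part <- vector("list", nnode)
    for (i in seq_len(ntip)) part[[i]] <- pd$tip_partials[[ord[i]]]
    for (k in seq_len(nrow(phy$edge))) {
      par <- phy$edge[k, 1]; chi <- phy$edge[k, 2]
      Pm <- transition_probabilities(model, phy$edge.length[k], r)
      msg <- Pm %*% part[[chi]]
      part[[par]] <- if (is.null(part[[par]])) msg else part[[par]] * msg
    }
    part[[ntip + 1L]]
  })
}

#' Felsenstein pruning log-likelihood of an alignment on a tree
#'
#' Site patterns are compressed; discrete-gamma categories are averaged with
#' equal weights; with `p_invariant` the invariant class is mixed in; gaps
#' and ambiguity codes act as missing data. With a partitioned alignment and
#' a list of models, per-partition log-likelihoods (shared topology and
#' branch lengths) are summed; columns outside every partition form a
#' `"default"` partition and need a model under that name (or a single
#' fallback model).
#'
#' @param tree `phylo` tree with branch lengths in substitutions/site; tips
#'   must match the alignment taxa.
#' @param alignment A [as_alignment()] matrix (or a precompressed pattern
#'   list from [compress_patterns()]).
#' @param model A `subst_model`, or a named list of models when `partition`
#'   is given.
#' @param partition Optional [partition_set()] (defaults to the alignment's
#'   attached partition).
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(tree, alignment, model, partition = NULL) {
  if (is.null(partition) && !is.null(attr(alignment, "partition")) && is.list(model) &&
      !inherits(model, "subst_model"))
    partition <- attr(alignment, "partition")
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "partition_set"))
    if (inherits(model, "subst_model")) {
      models <- stats::setNames(rep(list(model), length(partition$partitions)),
                                names(partition$partitions))
    } else models <- model
    total <- 0
    assigned <- integer(0)
    for (nm in names(partition$partitions)) {
      cols <- partition_columns(partition, nm)
      assigned <- c(assigned, cols)
      if (length(cols) == 0L) next
      m <- models[[nm]]
      if (is.null(m)) stop("missing model for partition '", nm, "'")
      total <- total + log_likelihood(tree, subset_columns(alignment, cols), m)
    }
    rest <- setdiff(seq_len(ncol(alignment)), assigned)
    if (length(rest)) {
      m <- models[["default"]]
      if (is.null(m) && inherits(model, "subst_model")) m <- model
      if (is.null(m)) stop("missing model for partition 'default' (unassigned columns)")
      total <- total + log_likelihood(tree, subset_columns(alignment, rest), m)
    }
    return(total)
  }
  pd <- if (is.list(alignment) && !is.null(alignment$tip_partials)) alignment
        else compress_patterns(alignment)
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  roots <- root_partials(tree, pd, model)
  site_l <- Reduce(`+`, lapply(roots, function(rp)
    as.vector(model$base_freqs %*% rp))) / length(roots)
  if (!is.null(model$p_invariant)) {
    inv <- as.vector(model$base_freqs %*% pd$invariant_compat)
    site_l <- model$p_invariant * inv + (1 - model$p_invariant) * site_l
  }
  if (any(site_l <= 0)) return(-Inf)
  sum(pd$weights * log(site_l))
}

# Internal: messages toward parent for every edge plus "above" partials,
# enabling O(1-edge) likelihood as a function of one branch length.
edge_context <- function(phy, pd, model) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ncat <- length(model$gamma_rates)
  ord <- match(phy$tip.label, names(pd$tip_partials))
  down <- vector("list", ncat)   # down[[cat]][[node]]: partial below node
  msg <- vector("list", ncat)    # msg[[cat]][[edge k]]: P(t_k) %*% down[child]
  for (ci in seq_len(ncat)) {
    r <- model$gamma_rates[ci]
    part <- vector("list", nnode)
    for (i in seq_len(ntip)) part[[i]] <- pd$tip_partials[[ord[i]]]
    em <- vector("list", nrow(phy$edge))
    for (k in seq_len(nrow(phy$edge))) {
      par <- phy$edge[k, 1]; chi <- phy$edge[k, 2]
      Pm <- transition_probabilities(model, phy$edge.length[k], r)
      em[[k]] <- Pm %*% part[[chi]]
      part[[par]] <- if (is.null(part[[par]])) em[[k]] else part[[par]] * em[[k]]
    }
    down[[ci]] <- part
    msg[[ci]] <- em
  }
  # preorder "above" partials (include base freqs at the root)
  root <- ntip + 1L
  pre <- rev(seq_len(nrow(phy$edge)))
  above <- vector("list", ncat)
  for (ci in seq_len(ncat)) {
    ab <- vector("list", nnode)
    ab[[root]] <- matrix(model$base_freqs, 4, length(pd$weights))
    for (k in pre) {
      par <- phy$edge[k, 1]; chi <- phy$edge[k, 2]
      sibs <- which(phy$edge[, 1] == par & phy$edge[, 2] != chi)
      partner <- ab[[par]]
      for (s in sibs) partner <- partner * msg[[ci]][[s]]
      r <- model$gamma_rates[ci]
      Pm <- transition_probabilities(model, phy$edge.length[k], r)
      ab[[chi]] <- crossprod(Pm, partner)
    }
    above[[ci]] <- ab
  }
  list(phy = phy, down = down, msg = msg, above = above, ncat = ncat)
}

#' Optimize branch lengths by coordinate-wise 1-D search
#'
#' Each branch is optimized in turn with Brent search on the single-branch
#' likelihood (all other branches held fixed, partials recomputed exactly),
#' cycling until the log-likelihood improves by less than `tol` in a full
#' pass. Monotone by construction.
#'
#' @param tree `phylo` with starting branch lengths (zeros allowed).
#' @param alignment Alignment or compressed patterns.
#' @param model A `subst_model`.
#' @param tol Convergence tolerance on the log-likelihood per pass.
#' @param max_passes Cap on full passes.
#' @param max_brlen Upper bound of the per-branch search.
#' @return List with `tree` (optimized lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, tol = 1e-4,
                                    max_passes = 20L, max_brlen = 10) {
  pd <- if (is.list(alignment) && !is.null(alignment$tip_partials)) alignment
        else compress_patterns(alignment)
  phy <- ape::reorder.phylo(tree, "postorder")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.05, nrow(phy$edge))
  phy$edge.length[phy$edge.length < 0] <- 0
  ll <- log_likelihood(phy, pd, model)
  pinv <- if (is.null(model$p_invariant)) 0 else model$p_invariant
  inv_term <- if (pinv > 0) as.vector(model$base_freqs %*% pd$invariant_compat) else 0
  for (pass in seq_len(max_passes)) {
    ctx <- edge_context(phy, pd, model)
    for (k in seq_len(nrow(phy$edge))) {
      par <- ctx$phy$edge[k, 1]; chi <- ctx$phy$edge[k, 2]
      partners <- lapply(seq_len(ctx$ncat), function(ci) {
        p <- ctx$above[[ci]][[par]]
        for (s in which(ctx$phy$edge[, 1] == par & ctx$phy$edge[, 2] != chi))
          p <- p * ctx$msg[[ci]][[s]]
        p
      })
      downs <- lapply(seq_len(ctx$ncat), function(ci) ctx$down[[ci]][[chi]])
      f <- function(t) {
        sl <- 0
        for (ci in seq_len(ctx$ncat)) {
          Pm <- transition_probabilities(model, t, model$gamma_rates[ci])
          sl <- sl + colSums(crossprod(Pm, partners[[ci]]) * downs[[ci]])
        }
        sl <- sl / ctx$ncat
        if (pinv > 0) sl <- pinv * inv_term + (1 - pinv) * sl
        if (any(sl <= 0)) return(Inf)
        -sum(pd$weights * log(sl))
      }
      cur <- f(ctx$phy$edge.length[k])
      opt <- stats::optimize(f, c(0, max_brlen), tol = 1e-8)
      if (opt$objective < cur) {
        ctx$phy$edge.length[k] <- opt$minimum
        # partials are stale after the change; rebuild context
        ctx <- edge_context(ctx$phy, pd, model)
      }
    }
    phy <- ctx$phy
    new_ll <- log_likelihood(phy, pd, model)
    if (new_ll < ll - 1e-9)
      stop("internal error: branch optimization decreased lnL")
    if (new_ll - ll < tol) { ll <- new_ll; break }
    ll <- new_ll
  }
  list(tree = phy, loglik = ll)
}

#' Fit substitution-model parameters on a fixed topology
#'
#' Maximizes the log-likelihood over branch lengths and the free parameters
#' of the model family (kappa, GTR exchangeabilities, gamma shape, invariant
#' fraction) by cyclic bounded 1-D search; base frequencies are empirical.
#'
#' @param tree Starting `phylo` (topology fixed; branch lengths refined).
#' @param alignment A [as_alignment()] matrix.
#' @param model_spec Model string such as `"HKY+G4"` (see
#'   [parse_model_spec()]).
#' @param rounds Number of parameter/branch alternations.
#' @param brlen_tol Branch-length convergence tolerance per round.
#' @return List of class `model_fit`: `model`, `tree`, `loglik`, `k`
#'   (free model parameter count), `spec`.
#' @export
fit_model <- function(tree, alignment, model_spec, rounds = 3L,
                      brlen_tol = 1e-3) {
  pd <- compress_patterns(alignment)
  emp <- empirical_base_freqs(alignment)
  fam <- strsplit(toupper(model_spec), "+", fixed = TRUE)[[1]][1]
  model <- parse_model_spec(model_spec,
                            base_freqs = if (fam %in% c("HKY", "GTR")) emp else rep(0.25, 4))
  rebuild <- function(kappa, rates, alpha, pinv) {
    substitution_model(model$name,
                       base_freqs = model$base_freqs, kappa = kappa, rates = rates,
                       gamma_shape = alpha,
                       n_gamma_categories = model$n_gamma_categories,
                       p_invariant = pinv)
  }
  kappa <- model$kappa; rates <- model$rates
  alpha <- model$gamma_shape; pinv <- model$p_invariant
  fit <- optimize_branch_lengths(tree, pd, model, tol = brlen_tol)
  phy <- fit$tree; ll <- fit$loglik
  opt1 <- function(f, lower, upper, cur) {
    o <- stats::optimize(f, c(lower, upper), tol = 1e-6)
    if (o$objective < -ll) list(val = o$minimum, ll = -o$objective)
    else list(val = cur, ll = ll)
  }
  for (r in seq_len(rounds)) {
    if (model$name %in% c("K80", "HKY")) {
      res <- opt1(function(lk) -log_likelihood(phy, pd, rebuild(exp(lk), rates, alpha, pinv)),
                  log(0.02), log(100), log(kappa))
      kappa <- exp(res$val); ll <- res$ll
    }
    if (model$name == "GTR") {
      # joint transition-rate direction first (the nested HKY axis): a far
      # better start than cycling raw exchangeabilities from equal rates
      res <- opt1(function(lm) {
        rr <- rates; rr[c(2, 5)] <- rates[c(2, 5)] * exp(lm)
        -log_likelihood(phy, pd, rebuild(kappa, rr, alpha, pinv))
      }, log(0.05), log(50), 0)
      rates[c(2, 5)] <- rates[c(2, 5)] * exp(res$val); ll <- res$ll
      for (i in 1:5) {  # GT fixed at 1
        res <- opt1(function(lx) {
          rr <- rates; rr[i] <- exp(lx)
          -log_likelihood(phy, pd, rebuild(kappa, rr, alpha, pinv))
        }, log(1e-3), log(1e3), log(rates[i]))
        rates[i] <- exp(res$val); ll <- res$ll
      }
    }
    if (!is.null(alpha)) {
      res <- opt1(function(la) -log_likelihood(phy, pd, rebuild(kappa, rates, exp(la), pinv)),
                  log(0.02), log(50), log(alpha))
      alpha <- exp(res$val); ll <- res$ll
    }
    if (!is.null(pinv)) {
      res <- opt1(function(p) -log_likelihood(phy, pd, rebuild(kappa, rates, alpha, p)),
                  0, 0.95, pinv)
      pinv <- res$val; ll <- res$ll
    }
    model <- rebuild(kappa, rates, alpha, pinv)
    fit <- optimize_branch_lengths(phy, pd, model, tol = brlen_tol)
    phy <- fit$tree
    if (fit$loglik - ll < brlen_tol && r > 1) { ll <- fit$loglik; break }
    ll <- fit$loglik
  }
  k <- free_parameter_count(model)
  structure(list(model = model, tree = phy, loglik = ll, k = k,
                 spec = model_spec_string(model)), class = "model_fit")
}

empirical_base_freqs <- function(alignment) {
  tab <- table(factor(unclass(alignment), levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  pmax(f, 1e-6) / sum(pmax(f, 1e-6))
}

free_parameter_count <- function(model) {
  k <- 0L
  if (model$name %in% c("HKY", "GTR")) k <- k + 3L           # frequencies
  if (model$name %in% c("K80", "HKY")) k <- k + 1L           # kappa
  if (model$name == "GTR") k <- k + 5L                       # exchangeabilities
  if (!is.null(model$gamma_shape)) k <- k + 1L               # alpha
  if (!is.null(model$p_invariant)) k <- k + 1L               # p_inv
  k
}

#' AIC-based substitution model selection
#'
#' Fits each candidate model on the given topology and ranks by
#' AIC = 2k - 2 lnL (k = free model parameters: 3 for estimated frequencies,
#' 1 for kappa, 5 for GTR exchangeabilities, 1 each for gamma shape and
#' invariant fraction). Ties break toward fewer parameters.
#'
#' @param alignment A [as_alignment()] matrix.
#' @param tree Topology used for every fit (e.g. a quick NJ tree).
#' @param candidates Character vector of model specs.
#' @param ... Passed to [fit_model()].
#' @return data.frame (ascending AIC): `model`, `k`, `loglik`, `AIC`,
#'   `delta_AIC`; fitted objects in `attr(, "fits")`.
#' @export
select_model <- function(alignment, tree,
                         candidates = c("JC", "K80", "HKY", "GTR",
                                        "JC+G4", "K80+G4", "HKY+G4", "GTR+G4",
                                        "HKY+G4+I", "GTR+G4+I"),
                         ...) {
  fits <- lapply(candidates, function(sp) fit_model(tree, alignment, sp, ...))
  tab <- data.frame(model = candidates,
                    k = vapply(fits, `[[`, integer(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  tab$AIC <- 2 * tab$k - 2 * tab$loglik
  ord <- order(tab$AIC, tab$k)
  tab <- tab[ord, ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
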