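#' Nucleotide substitution models
#'
#' Constructs a time-reversible nucleotide substitution model (JC, K80, HKY
#' or GTR, optionally +Gamma and/or +I). The instantaneous rate matrix is
#' scaled so that one unit of branch length equals one expected substitution
#' per site, accounting for the invariant-site fraction (rates are divided by
#' `1 - p_invariant`) and for the discrete-gamma rates (mean 1 by
#' construction).
#'
#' @param name One of `"JC"`, `"K80"`, `"HKY"`, `"GTR"`.
#' @param base_freqs Stationary frequencies (A, C, G, T); must be positive
#'   and sum to 1. Ignored (set equal) for JC/K80.
#' @param kappa Transition/transversion rate ratio (K80/HKY).
#' @param rates GTR exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (GT is conventionally fixed to 1).
#' @param gamma_shape Shape of the discrete-gamma rate distribution, or
#'   `NULL` for rate homogeneity.
#' @param n_gamma_categories Number of equal-probability gamma categories.
#' @param p_invariant Proportion of invariant sites in `[0, 1)`, or `NULL`.
#' @return An object of class `subst_model` carrying the scaled rate matrix
#'   and its symmetric eigendecomposition.
#' @export
substitution_model <- function(name = c("JC", "K80", "HKY", "GTR"),
                               base_freqs = rep(0.25, 4),
                               kappa = 2, rates = rep(1, 6),
                               gamma_shape = NULL, n_gamma_categories = 4L,
                               p_invariant = NULL) {
  name <- match.arg(name)
  if (name %in% c("JC", "K80")) base_freqs <- rep(0.25, 4)
  stopifnot(length(base_freqs) == 4, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8)
  base_freqs <- base_freqs / sum(base_freqs)
  ex <- switch(name,
    JC  = rep(1, 6),
    K80 = c(1, kappa, 1, 1, kappa, 1),
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = { stopifnot(length(rates) == 6, all(rates > 0)); rates })
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0, n_gamma_categories >= 1)
  if (!is.null(p_invariant)) stopifnot(p_invariant >= 0, p_invariant < 1)

  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- ex  # column-wise: (C,A)(G,A)(T,A)(G,C)(T,C)(T,G) = AC,AG,AT,CG,CT,GT
  R <- R + t(R)
  Q <- R %*% diag(base_freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  pinv <- if (is.null(p_invariant)) 0 else p_invariant
  if (pinv > 0) Q <- Q / (1 - pinv)
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))

  # detailed balance => diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(base_freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  gamma_rates <- if (is.null(gamma_shape)) 1 else
    discretize_gamma(gamma_shape, n_gamma_categories)

  structure(list(
    name = name, base_freqs = base_freqs, kappa = kappa, rates = ex,
    gamma_shape = gamma_shape, n_gamma_categories = as.integer(n_gamma_categories),
    p_invariant = if (is.null(p_invariant)) NULL else p_invariant,
    Q = Q, gamma_rates = gamma_rates,
    eig_values = eig$values,
    eig_right = diag(1 / sp) %*% eig$vectors,
    eig_left = t(eig$vectors) %*% diag(sp)
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> ", model_spec_string(x), "\n", sep = "")
  cat("  base freqs:", sprintf("%.4f", x$base_freqs), "\n")
  if (x$name %in% c("K80", "HKY")) cat("  kappa:", signif(x$kappa, 5), "\n")
  if (x$name == "GTR") cat("  exchangeabilities:", signif(x$rates, 4), "\n")
  invisible(x)
}

model_spec_string <- function(m) {
  paste0(m$name,
         if (!is.null(m$gamma_shape)) paste0("+G", m$n_gamma_categories) else "",
         if (!is.null(m$p_invariant)) "+I" else "")
}

#' Parse a model specification string such as `"GTR+G4+I"`
#'
#' @param spec String: family (`JC`, `K80`, `HKY`, `GTR`) with optional
#'   `+G<n>` (discrete gamma, default 4 categories) and `+I` suffixes.
#' @param ... Passed to [substitution_model()] (frequencies, kappa, rates,
#'   shape, p_invariant starting values).
#' @return A `subst_model`.
#' @export
parse_model_spec <- function(spec, ...) {
  toks <- strsplit(toupper(spec), "+", fixed = TRUE)[[1]]
  fam <- toks[1]
  if (!fam %in% c("JC", "K80", "HKY", "GTR")) stop("unknown model family: ", fam)
  args <- list(name = fam, ...)
  for (tk in toks[-1]) {
    if (grepl("^G\\d*$", tk)) {
      if (is.null(args$gamma_shape)) args$gamma_shape <- 0.5
      ncat <- sub("^G", "", tk)
      args$n_gamma_categories <- if (nzchar(ncat)) as.integer(ncat) else 4L
    } else if (tk == "I") {
      if (is.null(args$p_invariant)) args$p_invariant <- 0.1
    } else stop("unknown model suffix: +", tk)
  }
  do.call(substitution_model, args)
}

#' Discrete-gamma category rates (mean-of-quantile-interval scheme)
#'
#' The gamma(shape = alpha, rate = alpha) distribution (mean 1) is cut into
#' `n` equal-probability intervals; each category rate is the conditional
#' mean within its interval, then the vector is renormalized so its mean is
#' exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param n Number of categories (>= 1).
#' @return Numeric vector of `n` increasing rates with mean 1.
#' @export
discretize_gamma <- function(alpha, n = 4L) {
  stopifnot(alpha > 0, n >= 1)
  if (n == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = n + 1), shape = alpha, rate = alpha)
  # E[X ; a < X < b] for Gamma(alpha, alpha) = P(a < Y < b) with Y ~ Gamma(alpha+1, alpha)
  seg <- diff(stats::pgamma(bounds, shape = alpha + 1, rate = alpha))
  r <- n * seg
  r / mean(r)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the symmetric eigendecomposition of the scaled reversible
#' rate matrix; rows sum to 1 and P(0) is the identity.
#'
#' @param model A [substitution_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param rate Optional rate multiplier (e.g. a gamma category rate).
#' @return A 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0, got ", t)
  P <- model$eig_right %*% (exp(model$eig_values * t * rate) * model$eig_left)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Pairwise evolutionary distance between two sequences
#'
#' JC uses the closed form `d = -3/4 log(1 - 4p/3)`. For K80/HKY/GTR
#' (optionally +Gamma) the two-sequence log-likelihood is maximized
#' numerically over the divergence `t`, with base frequencies taken
#' empirically from the pair and exchangeabilities/shape from `model`.
#'
#' @param seq_a,seq_b Equal-length character vectors (or strings) of aligned
#'   sequences; gaps/N/ambiguities are treated as missing.
#' @param model A `subst_model` (its family selects the distance).
#' @param t_max Upper bound of the search; hitting it raises a saturation
#'   error.
#' @return Distance in expected substitutions per site.
#' @export
pairwise_distance <- function(seq_a, seq_b, model, t_max = 10) {
  if (length(seq_a) == 1L) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1L) seq_b <- strsplit(seq_b, "")[[1]]
  if (length(seq_a) != length(seq_b)) stop("sequences differ in length")
  ok <- !(seq_a %in% IUPAC_MISSING) & !(seq_b %in% IUPAC_MISSING)
  if (!any(ok)) stop("no jointly non-missing columns")
  a <- factor(seq_a[ok], levels = c("A", "C", "G", "T"))
  b <- factor(seq_b[ok], levels = c("A", "C", "G", "T"))
  counts <- table(a, b)
  n <- sum(counts)
  if (model$name == "JC") {
    p <- (n - sum(diag(counts))) / n
    if (p >= 0.75) stop("saturated pair (p = ", signif(p, 4), " >= 3/4) under JC")
    return(-0.75 * log(1 - 4 * p / 3))
  }
  if (sum(diag(counts)) == n) return(0)
  emp <- (rowSums(counts) + colSums(counts)) / (2 * n)
  emp <- pmax(emp, 1e-6); emp <- emp / sum(emp)
  m2 <- substitution_model(model$name, base_freqs = emp, kappa = model$kappa,
                           rates = model$rates, gamma_shape = model$gamma_shape,
                           n_gamma_categories = model$n_gamma_categories,
                           p_invariant = model$p_invariant)
  negll <- function(t) {
    P <- Reduce(`+`, lapply(m2$gamma_rates, function(r)
      transition_probabilities(m2, t, r))) / length(m2$gamma_rates)
    M <- m2$base_freqs * P
    if (!is.null(m2$p_invariant))
      M <- m2$p_invariant * diag(m2$base_freqs) + (1 - m2$p_invariant) * M
    -sum(counts * log(pmax(M, 1e-300)))
  }
  opt <- stats::optimize(negll, c(0, t_max), tol = 1e-9)
  if (opt$minimum > 0.99 * t_max)
    stop("pairwise distance did not converge below t_max = ", t_max,
         " (saturation)")
  opt$minimum
}

#' Model-based distance matrix for an alignment
#'
#' @param alignment A [as_alignment()] matrix.
#' @param model A `subst_model`; defaults to JC.
#' @param gap_mode Passed through: `"delete_columns"` strips gapped columns
#'   before computing distances.
#' @return Symmetric numeric matrix of distances (substitutions/site).
#' @export
distance_matrix <- function(alignment, model = substitution_model("JC"),
                            gap_mode = c("missing", "delete_columns")) {
  gap_mode <- match.arg(gap_mode)
  if (gap_mode == "delete_columns") alignment <- strip_gap_columns(alignment)
  taxa <- rownames(alignment)
  n <- length(taxa)
  if (n < 2) stop("need >= 2 taxa")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pairwise_distance(alignment[i, ], alignment[j, ], model)
  }
  d
}
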