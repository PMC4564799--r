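#' Nonparametric bootstrap supports for a phylogeny
#'
#' Columns are resampled with replacement; a tree is inferred per replicate
#' with the requested method; supports are the percentage of replicates
#' containing each bipartition of the point-estimate tree and are attached
#' to its internal nodes. Reproducible given `seed`.
#'
#' @param alignment A [as_alignment()] matrix.
#' @param method `"nj"`, `"parsimony"` or `"ml"`.
#' @param n_replicates Number of pseudo-replicates (the study default is
#'   1000; tests use fewer).
#' @param seed Integer seed.
#' @param model `subst_model` used for NJ distances / ML.
#' @param point_tree Optional precomputed point-estimate tree; inferred from
#'   the full alignment when `NULL`.
#' @param gap_mode Passed to the distance computation for NJ.
#' @return List of class `bootstrap_result`: `tree` (point estimate with
#'   `node.label` supports in percent), `supports` (named vector keyed by
#'   split), `n_replicates`.
#' @export
bootstrap_tree <- function(alignment, method = c("nj", "parsimony", "ml"),
                           n_replicates = 100L, seed = 1L,
                           model = substitution_model("JC"),
                           point_tree = NULL, gap_mode = "missing") {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1)
  infer <- function(aln, sd) {
    switch(method,
      nj = nj_tree(aln, model, gap_mode),
      parsimony = {
        # PAUP-style bootstrap: one addition replicate per pseudo-replicate
        fd <- fitch_data(aln)
        set.seed(sd)
        tr <- stepwise_addition(fd, sample(sort(rownames(aln))))
        swap_hill_climb(tr, fd, "NNI")$tree
      },
      ml = {
        start <- nj_tree(aln, model, gap_mode)
        nni_ml_search(aln, model, start, quick_tol = 0.5, quick_passes = 1L,
                      max_sweeps = 5L)$tree
      })
  }
  if (is.null(point_tree)) point_tree <- if (method == "parsimony") {
    parsimony_search(alignment, n_addition_replicates = 5L, seed = seed)$trees[[1]]
  } else infer(alignment, seed)
  ref_splits <- tree_splits(point_tree)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  ncols <- ncol(alignment)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(ncols, ncols, replace = TRUE)
    aln_r <- subset_columns(alignment, cols)
    tr <- infer(aln_r, rep_seeds[r])
    sp <- tree_splits(tr)
    hit <- ref_splits %in% sp
    hits[hit] <- hits[hit] + 1
  }
  supports <- 100 * hits / n_replicates
  structure(list(tree = attach_supports(point_tree, supports),
                 supports = supports, n_replicates = n_replicates),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$n_replicates, " replicates; supports: ",
      paste(sprintf("%.0f", sort(unname(x$supports))), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Write per-split support percentages into node labels of `phy`.
attach_supports <- function(phy, supports) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  phy2 <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy2$tip.label[i]
  lab <- rep("", phy2$Nnode)
  first <- min(phy$tip.label)
  for (k in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[k, 1]; chi <- phy2$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
    if (chi > ntip) {
      s <- below[[chi]]
      if (length(s) >= 2 && length(s) <= ntip - 2) {
        if (first %in% s) s <- setdiff(phy2$tip.label, s)
        key <- paste(sort(s), collapse = ",")
        if (key %in% names(supports))
          lab[chi - ntip] <- sprintf("%.1f", supports[[key]])
      }
    }
  }
  phy2$node.label <- lab
  phy2
}
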