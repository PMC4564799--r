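#' Maximum-likelihood topology search by NNI from a start tree
#'
#' Repeated nearest-neighbour-interchange sweeps over the current tree:
#' every NNI neighbour is scored with (coarsely) re-optimized branch
#' lengths; the best strictly improving neighbour is accepted and fully
#' re-optimized; the search stops when a full sweep yields no improvement.
#' Monotone in log-likelihood by construction.
#'
#' @param alignment A [as_alignment()] matrix.
#' @param model A `subst_model` (e.g. `parse_model_spec("GTR+G4+I")`).
#' @param start_tree Starting `phylo` (e.g. the NJ tree); branch lengths are
#'   re-estimated.
#' @param quick_tol,quick_passes Branch-optimization settings used when
#'   screening neighbours (full settings are used on accepted trees).
#' @param max_sweeps Cap on NNI sweeps.
#' @return List of class `ml_result`: `tree` (with ML branch lengths),
#'   `loglik`, `n_sweeps`.
#' @export
nni_ml_search <- function(alignment, model, start_tree,
                          quick_tol = 0.05, quick_passes = 2L,
                          max_sweeps = 20L) {
  pd <- compress_patterns(alignment)
  cur <- optimize_branch_lengths(ape::unroot(start_tree), pd, model,
                                 tol = 1e-4)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    nb <- nni_neighbors(cur$tree)
    improved <- FALSE
    best_ll <- cur$loglik
    best_fit <- NULL
    for (tr in nb) {
      fit <- optimize_branch_lengths(tr, pd, model, tol = quick_tol,
                                     max_passes = quick_passes)
      if (fit$loglik > best_ll + 1e-6) {
        best_ll <- fit$loglik
        best_fit <- fit
        improved <- TRUE
      }
    }
    if (!improved || sweeps >= max_sweeps) break
    cur <- optimize_branch_lengths(best_fit$tree, pd, model, tol = 1e-4)
  }
  structure(list(tree = cur$tree, loglik = cur$loglik, n_sweeps = sweeps),
            class = "ml_result")
}

#' @export
print.ml_result <- function(x, ...) {
  cat("<ml_result> lnL ", sprintf("%.4f", x$loglik), " after ", x$n_sweeps,
      " NNI sweep(s)\n", sep = "")
  invisible(x)
}
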