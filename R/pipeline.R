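#' Configuration for a full plastome phylogenomic run
#'
#' Defaults mirror the study design this package reproduces: gaps treated as
#' missing, 1000 bootstrap replicates, AIC model choice, GTR+G+I for the ML
#' search and HKY with four gamma categories for dating.
#'
#' @param alignment A [as_alignment()] matrix or path to an aligned FASTA.
#' @param outgroup Out-group taxon label (rooting and site-count exclusion).
#' @param gap_mode `"missing"` or `"delete_columns"`.
#' @param bootstrap_replicates Bootstrap pseudo-replicates per method.
#' @param model_selection `TRUE` to run the AIC table stage.
#' @param ml_model Model spec for the ML search.
#' @param dating `NULL` to skip dating, else a list with `calibrations`
#'   (list of [calibration()]), and optionally `clock`
#'   (`"strict"`/`"relaxed_lognormal"`), `model` (spec string),
#'   `chain_length`, `sample_every`, `burn_in`.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(alignment, outgroup, gap_mode = "missing",
                       bootstrap_replicates = 1000L, model_selection = TRUE,
                       ml_model = "GTR+G4+I", dating = NULL, seed = 1L,
                       out_dir = "plastochron_run") {
  if (is.character(alignment) && !is.matrix(alignment))
    alignment <- as_alignment(read_fasta(alignment))
  if (!outgroup %in% rownames(alignment))
    stop("outgroup '", outgroup, "' not in alignment")
  structure(list(alignment = alignment, outgroup = outgroup,
                 gap_mode = gap_mode,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 model_selection = isTRUE(model_selection),
                 ml_model = ml_model, dating = dating,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: site statistics and pairwise differences, AIC model
#' selection, NJ (GTR+gamma distances) with bootstrap, maximum parsimony
#' (TBR) with bootstrap, ML (NNI from the NJ tree), out-group rooting, and
#' (optionally) Bayesian divergence dating on the rooted topology. Every
#' output file is written under `config$out_dir` and recorded with an MD5
#' hash in `MANIFEST.txt`; identical config and seed give identical outputs.
#' Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return List of class `run_report` with the per-stage results and the
#'   output file manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- config$alignment
  logf <- file.path(config$out_dir, "run.log")
  cat("plastochron run\n", "seed=", config$seed, "\n", "taxa=",
      paste(rownames(aln), collapse = ","), "\n", "columns=", ncol(aln), "\n",
      sep = "", file = logf)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    cat(name, ": ", sprintf("%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        " s\n", sep = "", file = logf, append = TRUE)
    res
  }
  out <- list()

  out$site_stats <- stage("stats", {
    sc <- classify_sites(aln, gap_mode = config$gap_mode,
                         exclude_taxa = config$outgroup)
    df <- data.frame(metric = c("column_count", "n_constant", "n_variable",
                                "n_parsimony_informative", "n_singleton",
                                "n_excluded"),
                     value = c(sc$column_count, sc$n_constant, sc$n_variable,
                               sc$n_parsimony_informative, sc$n_singleton,
                               sc$n_excluded))
    utils::write.table(df, file.path(config$out_dir, "site_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pdm <- pairwise_difference_matrix(aln, config$gap_mode)
    utils::write.table(pdm, file.path(config$out_dir, "pairwise_differences.tsv"),
                       sep = "\t", quote = FALSE)
    list(classification = sc, pairwise = pdm)
  })

  guide_tree <- stage("guide_tree", nj_tree(aln, substitution_model("JC"),
                                            config$gap_mode))

  out$model_selection <- if (config$model_selection) stage("modeltest", {
    tab <- select_model(aln, guide_tree,
                        candidates = c("JC", "K80", "HKY", "GTR",
                                       "HKY+G4", "GTR+G4", "GTR+G4+I"))
    utils::write.table(tab, file.path(config$out_dir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  }) else NULL

  dist_model <- stage("distance_model", {
    # GTR + gamma distances, exchangeabilities fitted on the guide tree
    fit <- fit_model(guide_tree, aln, "GTR+G4", rounds = 1L, brlen_tol = 0.05)
    fit$model
  })

  out$nj <- stage("nj", {
    bs <- bootstrap_tree(aln, "nj", config$bootstrap_replicates,
                         seed = config$seed, model = dist_model,
                         gap_mode = config$gap_mode)
    write_newick(bs$tree, file.path(config$out_dir, "nj.nwk"))
    bs
  })

  out$parsimony <- stage("parsimony", {
    ps <- parsimony_search(aln, n_addition_replicates = 5L, seed = config$seed)
    bs <- bootstrap_tree(aln, "parsimony", config$bootstrap_replicates,
                         seed = config$seed, point_tree = ps$trees[[1]])
    write_newick(bs$tree, file.path(config$out_dir, "parsimony.nwk"))
    list(search = ps, bootstrap = bs)
  })

  out$ml <- stage("ml", {
    ml_fit <- fit_model(out$nj$tree, aln, config$ml_model, rounds = 1L,
                        brlen_tol = 0.1)
    res <- nni_ml_search(aln, ml_fit$model, out$nj$tree)
    write_newick(res$tree, file.path(config$out_dir, "ml.nwk"))
    res
  })

  out$rooted <- stage("rooting", {
    tr <- root_with_outgroup(out$ml$tree, config$outgroup)
    write_newick(tr, file.path(config$out_dir, "ml_rooted.nwk"))
    tr
  })

  if (!is.null(config$dating)) out$dating <- stage("dating", {
    d <- config$dating
    topo <- resolve_dating_topology(out$rooted)
    cfg <- mcmc_config(chain_length = d$chain_length %||% 1100000L,
                       sample_every = d$sample_every %||% 200L,
                       burn_in = d$burn_in %||% 100000L,
                       seed = config$seed)
    fit <- run_dating_mcmc(aln, topo, d$clock %||% "strict", d$calibrations,
                           cfg, model_spec = d$model %||% "HKY+G4")
    utils::write.table(fit$trace, file.path(config$out_dir, "dating_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_dating(fit)
    utils::write.table(summ, file.path(config$out_dir, "dating_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(chronogram_phylo(mean_chronogram(fit)),
                 file.path(config$out_dir, "chronogram.nwk"))
    list(fit = fit, summary = summ)
  })

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, c("MANIFEST.txt", "run.log")))
  md5 <- tools::md5sum(files)
  writeLines(paste(basename(names(md5)), unname(md5), sep = "\t"),
             file.path(config$out_dir, "MANIFEST.txt"))
  out$manifest <- md5
  out$congruent <- length(unique(c(topology_key(out$nj$tree),
                                   topology_key(out$parsimony$search$trees[[1]]),
                                   topology_key(out$ml$tree)))) == 1L
  cat("congruent_topologies=", out$congruent, "\n", sep = "",
      file = logf, append = TRUE)
  class(out) <- "run_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The ML tree rooted on the outgroup may have a zero-resolved root; ensure
# the dating topology is strictly binary.
resolve_dating_topology <- function(tree) {
  tr <- ape::multi2di(tree, random = FALSE)
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$site_stats$classification)
  cat("  NJ/MP/ML congruent: ", x$congruent, "\n", sep = "")
  if (!is.null(x$dating)) cat("  dating: ", nrow(x$dating$fit$trace),
                              " posterior samples\n", sep = "")
  invisible(x)
}
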