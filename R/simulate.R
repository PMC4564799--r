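# --- Yule chronogram simulation ---------------------------------------------

#' Simulate a Yule (pure-birth) chronogram
#'
#' Forward labelled-history simulation: with `k` lineages the waiting time to
#' the next speciation is `Exp(k * birth_rate)`; the lineage that splits is
#' chosen uniformly; the present is the moment the `(n+1)`-th lineage would
#' arise (so the youngest node age is positive). This is the exact forward
#' model of the Yule prior used in dating ([yule_log_prior()]).
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate per Myr (> 0).
#' @param seed Integer seed (mandatory: no silent nondeterminism).
#' @param labels Optional tip labels (default `t1..tn`).
#' @return A [chronogram()].
#' @export
simulate_yule_chronogram <- function(n_taxa, birth_rate, seed,
                                     labels = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 2, birth_rate > 0, length(labels) == n_taxa)
  set.seed(as.integer(seed))
  w <- stats::rexp(n_taxa - 1, rate = birth_rate * (2:n_taxa))
  total <- sum(w)
  split_ages <- total - c(0, cumsum(w)[seq_len(n_taxa - 2)])  # event j age
  # lineage bookkeeping: origin event per lineage; events 1..n-1
  origin <- c(1L, 1L)            # two lineages born at the root event
  alive <- c(1L, 2L)
  end_event <- integer(0)        # per lineage: event that ends it (0 = tip)
  end_event[1:2] <- 0L
  for (j in 2:(n_taxa - 1)) {
    if (n_taxa == 2) break
    pick <- alive[sample.int(length(alive), 1)]
    end_event[pick] <- j
    id1 <- length(origin) + 1L; id2 <- id1 + 1L
    origin[c(id1, id2)] <- j
    end_event[c(id1, id2)] <- 0L
    alive <- c(setdiff(alive, pick), id1, id2)
  }
  tips <- alive
  ntip <- length(tips)
  node_of_event <- ntip + seq_len(n_taxa - 1)
  tip_id <- stats::setNames(seq_len(ntip), as.character(tips))
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  for (ln in seq_along(origin)) {
    from <- node_of_event[origin[ln]]
    if (end_event[ln] == 0L) {
      to <- tip_id[[as.character(ln)]]
      lens <- c(lens, split_ages[origin[ln]])
    } else {
      to <- node_of_event[end_event[ln]]
      lens <- c(lens, split_ages[origin[ln]] - split_ages[end_event[ln]])
    }
    edges <- rbind(edges, c(from, to))
  }
  phy <- structure(list(edge = edges, edge.length = lens,
                        tip.label = labels[seq_len(ntip)],
                        Nnode = n_taxa - 1L), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  chronogram(phy, split_ages)
}

# --- sequence evolution with indels and plastome structure -------------------

#' Quadripartite plastome structure
#'
#' @param lsc_length,ssc_length,ir_length Region lengths in bp; total genome
#'   length is `lsc + ssc + 2 * ir` with IRb the exact reverse complement of
#'   IRa.
#' @return Object of class `plastome_structure`.
#' @export
plastome_structure <- function(lsc_length = 80700L, ssc_length = 12400L,
                               ir_length = 20800L) {
  stopifnot(lsc_length > 0, ssc_length > 0, ir_length > 0)
  structure(list(lsc_length = as.integer(lsc_length),
                 ssc_length = as.integer(ssc_length),
                 ir_length = as.integer(ir_length),
                 total = as.integer(lsc_length + ssc_length + 2L * ir_length)),
            class = "plastome_structure")
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-", N = "N")

revcomp_chars <- function(x) unname(REVCOMP[rev(x)])

#' Evolve sequences along a chronogram
#'
#' The root sequence is drawn from the model's stationary frequencies;
#' substitutions are applied branch-wise via the model's transition
#' probabilities on branch length `rate * duration` (per-site discrete-gamma
#' category rates are drawn once and inherited along the tree). Indels are
#' Poisson events per branch (rate per site per Myr) with geometric lengths
#' and a 1:1 insertion:deletion ratio; the true alignment is tracked through
#' a shared column registry, so the output alignment is exact. With a
#' [plastome_structure()], a single core `LSC + IR + SSC` is evolved and the
#' second inverted repeat is emitted as the reverse complement of the first
#' (perfect IR homogenization), with region partitions attached.
#'
#' @param chr A [chronogram()].
#' @param clock List: `kind = "strict"` with `rate` (subs/site/Myr), or
#'   `kind = "relaxed_lognormal"` with `mean_log`, `sd_log` (branch rates
#'   drawn iid).
#' @param model A `subst_model` describing the substitution process.
#' @param length_or_structure Integer sequence length, or a
#'   [plastome_structure()].
#' @param indel_rate Indel events per site per Myr (0 disables indels).
#' @param indel_mean_length Mean indel length (geometric distribution).
#' @param indel_max_age Branch segments older than this age (Myr) do not
#'   accumulate indels, emulating the strong length conservation of plastomes
#'   over deep time; default `Inf` (indels everywhere).
#' @param seed Integer seed. Substitutions and indels are driven by two
#'   independent streams derived from it, so switching indels off leaves the
#'   substitution outcomes at every shared column unchanged.
#' @return List: `alignment` (true alignment, [as_alignment()] with region
#'   partition when structured), `sequences` (ungapped strings),
#'   `chronogram`, `branch_rates` (per edge), `n_indel_events`.
#' @export
evolve_sequences <- function(chr, clock, model, length_or_structure,
                             indel_rate = 0, indel_mean_length = 3,
                             indel_max_age = Inf, seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  structured <- inherits(length_or_structure, "plastome_structure")
  L <- if (structured) {
    length_or_structure$lsc_length + length_or_structure$ir_length +
      length_or_structure$ssc_length
  } else as.integer(length_or_structure)
  phy <- chr$tree
  ntip <- length(phy$tip.label)
  n_edges <- nrow(phy$edge)
  branch_rates <- if (clock$kind == "strict") rep(clock$rate, n_edges)
    else if (clock$kind == "relaxed_lognormal")
      stats::rlnorm(n_edges, clock$mean_log, clock$sd_log)
    else stop("unknown clock kind: ", clock$kind)

  nuc <- c("A", "C", "G", "T")
  cat_rates <- model$gamma_rates
  ncat <- length(cat_rates)

  # --- pass 1 (substitution stream): evolve the L core sites on the tree
  root_states <- sample.int(4, L, replace = TRUE, prob = model$base_freqs)
  site_cat <- sample.int(ncat, L, replace = TRUE)
  substitute_states <- function(states, cats, t_subs) {
    out <- states
    for (ci in unique(cats)) {
      P <- transition_probabilities(model, t_subs, cat_rates[ci])
      for (s in 1:4) {
        idx <- which(states == s & cats == ci)
        if (length(idx))
          out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    out
  }
  tip_states <- matrix(0L, ntip, L)
  recurse1 <- function(node, states) {
    for (k in which(phy$edge[, 1] == node)) {
      chi <- phy$edge[k, 2]
      t_subs <- (chr$ages[node] - chr$ages[chi]) * branch_rates[k]
      st <- substitute_states(states, site_cat, t_subs)
      if (chi <= ntip) tip_states[chi, ] <<- st else recurse1(chi, st)
    }
  }
  recurse1(root_node(phy), root_states)

  # --- pass 2 (indel stream): indel events and inserted-site evolution
  col_env <- new.env(parent = emptyenv())
  col_env$order <- seq_len(L)
  col_env$next_id <- L + 1L
  col_env$region <- if (structured) {
    rep(c("LSC", "IR", "SSC"),
        c(length_or_structure$lsc_length, length_or_structure$ir_length,
          length_or_structure$ssc_length))
  } else rep("all", L)
  tip_cols <- lapply(seq_len(ntip), function(i) seq_len(L))
  ins_states <- list()   # inserted column id -> named tip-state vector
  n_indels <- 0L

  if (indel_rate > 0) {
    set.seed(seed + 7919L)  # independent indel stream
    geo_p <- 1 / indel_mean_length
    # evolve a single inserted site from its birth down the remaining tree
    evolve_inserted <- function(edge_k, frac_remaining, state, cat) {
      res <- integer(0)
      chi <- phy$edge[edge_k, 2]
      t_subs <- (chr$ages[phy$edge[edge_k, 1]] - chr$ages[chi]) *
        branch_rates[edge_k] * frac_remaining
      P <- transition_probabilities(model, t_subs, cat_rates[cat])
      st <- sample.int(4, 1, prob = P[state, ])
      if (chi <= ntip) return(stats::setNames(st, chi))
      for (k2 in which(phy$edge[, 1] == chi))
        res <- c(res, evolve_inserted(k2, 1, st, cat))
      res
    }
    recurse2 <- function(node, cols) {
      for (k in which(phy$edge[, 1] == node)) {
        chi <- phy$edge[k, 2]
        dur_i <- max(0, min(chr$ages[node], indel_max_age) - chr$ages[chi])
        cc <- cols
        n_ev <- if (dur_i > 0) stats::rpois(1, indel_rate * length(cc) * dur_i) else 0L
        for (ev in seq_len(n_ev)) {
          n_indels <<- n_indels + 1L
          len <- 1L + stats::rgeom(1, geo_p)
          pos <- sample.int(length(cc), 1)
          frac <- stats::runif(1)  # how far down the branch the event sits
          if (stats::runif(1) < 0.5 && length(cc) > len + 1) {       # deletion
            cc <- cc[-(pos:min(pos + len - 1L, length(cc)))]
          } else {                                                    # insertion
            ids <- col_env$next_id + seq_len(len) - 1L
            col_env$next_id <- col_env$next_id + len
            at <- match(cc[pos], col_env$order)
            col_env$order <- append(col_env$order, ids, after = at)
            col_env$region <- append(col_env$region,
                                     rep(col_env$region[at], len), after = at)
            for (id in ids) {
              st0 <- sample.int(4, 1, prob = model$base_freqs)
              ct0 <- sample.int(ncat, 1)
              ins_states[[as.character(id)]] <<-
                evolve_inserted(k, 1 - frac, st0, ct0)
            }
            cc <- append(cc, ids, after = pos)
          }
        }
        if (chi <= ntip) tip_cols[[chi]] <<- cc else recurse2(chi, cc)
      }
    }
    recurse2(root_node(phy), seq_len(L))
  }

  # --- compose the true alignment over the master column order
  order_idx <- stats::setNames(seq_along(col_env$order), col_env$order)
  ncol_all <- length(col_env$order)
  mat <- matrix("-", ntip, ncol_all, dimnames = list(phy$tip.label, NULL))
  for (i in seq_len(ntip)) {
    cols <- tip_cols[[i]]
    core <- cols[cols <= L]
    mat[i, order_idx[as.character(core)]] <- nuc[tip_states[i, core]]
    ins <- cols[cols > L]
    for (id in ins) {
      st <- ins_states[[as.character(id)]]
      if (as.character(i) %in% names(st))
        mat[i, order_idx[[as.character(id)]]] <- nuc[st[[as.character(i)]]]
    }
  }
  keep <- colSums(mat != "-") > 0
  mat <- mat[, keep, drop = FALSE]
  region <- col_env$region[keep]

  if (structured) {
    ir_cols <- which(region == "IR")
    irb <- mat[, rev(ir_cols), drop = FALSE]
    irb[] <- REVCOMP[irb]
    mat <- cbind(mat, irb)
    region <- c(region, rep("IRB", ncol(irb)))
  }
  part <- region_partition(region)
  aln <- as_alignment(mat, partition = part)
  seqs <- apply(mat, 1, function(x) paste(x[x != "-"], collapse = ""))
  list(alignment = aln, sequences = as.list(seqs), chronogram = chr,
       branch_rates = branch_rates, n_indel_events = n_indels)
}

# Run-length encode a region label vector into a partition_set (IRB columns
# are pooled with IR: both copies are the same partition).
region_partition <- function(region) {
  region[region == "IRB"] <- "IR"
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  parts <- list()
  for (i in seq_along(r$values)) {
    nm <- r$values[i]
    parts[[nm]] <- rbind(parts[[nm]], c(starts[i], ends[i]))
  }
  partition_set(parts, length(region))
}

# --- fixture bundles ---------------------------------------------------------

#' Generate a named synthetic dataset bundle
#'
#' Profiles: `"tiny"` (5 taxa x 2 kb, quick end-to-end runs), `"aa_like"`
#' (10 shallow ingroup taxa with ~1 Myr crown, an outgroup diverging at
#' 4.4 Myr and a calibration taxon pair spanning a 50 Myr root — the
#' geometry of a rice AA-genome plastome study — on a full quadripartite
#' ~134.7 kb plastome), and `"stress"` (6 deep taxa at saturating
#' divergence). All randomness flows from `seed`; the same seed reproduces
#' byte-identical files.
#'
#' @param profile `"tiny"`, `"aa_like"` or `"stress"`.
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes
#'   `alignment.fasta`, `sequences.fasta` (ungapped), `true_tree.nwk`
#'   (substitutions/site), `chronogram.nwk` (Myr), `partitions.txt`
#'   (charset lines) and `manifest.txt` (key=value).
#' @return List: `alignment`, `sequences`, `chronogram`, `true_tree`,
#'   `branch_rates`, `params`, `files` (when written).
#' @export
make_fixture <- function(profile = c("tiny", "aa_like", "stress"), seed = 1L,
                         dir = NULL) {
  profile <- match.arg(profile)
  seed <- as.integer(seed)
  if (profile == "tiny") {
    params <- list(n_taxa = 5L, birth_rate = 0.5, clock_rate = 0.02,
                   kappa = 3, gamma_shape = 0.5, length = 2000L,
                   indel_rate = 1e-3, indel_max_age = Inf)
    chr <- simulate_yule_chronogram(params$n_taxa, params$birth_rate, seed)
    model <- substitution_model("HKY", base_freqs = c(0.31, 0.19, 0.19, 0.31),
                                kappa = params$kappa,
                                gamma_shape = params$gamma_shape)
    sim <- evolve_sequences(chr, list(kind = "strict", rate = params$clock_rate),
                            model, params$length,
                            indel_rate = params$indel_rate, seed = seed + 1L)
  } else if (profile == "aa_like") {
    params <- list(n_ingroup = 10L, crown_age = 1.0, outgroup_age = 4.4,
                   second_calib_age = 40, root_age = 50,
                   clock_rate = 0.0016, kappa = 3.5, gamma_shape = 0.5,
                   lsc = 80700L, ssc = 12400L, ir = 20800L,
                   indel_rate = 8e-5, indel_max_age = 5)
    chr <- aa_like_chronogram(params, seed)
    model <- substitution_model("HKY", base_freqs = c(0.31, 0.19, 0.18, 0.32),
                                kappa = params$kappa,
                                gamma_shape = params$gamma_shape)
    sim <- evolve_sequences(chr, list(kind = "strict", rate = params$clock_rate),
                            model,
                            plastome_structure(params$lsc, params$ssc, params$ir),
                            indel_rate = params$indel_rate,
                            indel_max_age = params$indel_max_age,
                            seed = seed + 1L)
  } else {
    params <- list(n_taxa = 6L, birth_rate = 0.05, clock_rate = 0.05,
                   kappa = 2, gamma_shape = NULL, length = 5000L,
                   indel_rate = 0, indel_max_age = Inf)
    chr <- simulate_yule_chronogram(params$n_taxa, params$birth_rate, seed)
    model <- substitution_model("HKY", kappa = params$kappa)
    sim <- evolve_sequences(chr, list(kind = "strict", rate = params$clock_rate),
                            model, params$length, seed = seed + 1L)
  }
  true_tree <- chronogram_phylo(sim$chronogram, sim$branch_rates)
  out <- list(alignment = sim$alignment, sequences = sim$sequences,
              chronogram = sim$chronogram, true_tree = true_tree,
              branch_rates = sim$branch_rates,
              n_indel_events = sim$n_indel_events,
              params = c(profile = profile, seed = seed, params))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(dir, x)
    write_fasta(apply(sim$alignment, 1, paste, collapse = ""), f("alignment.fasta"))
    write_fasta(sim$sequences, f("sequences.fasta"))
    write_newick(true_tree, f("true_tree.nwk"))
    write_newick(chronogram_phylo(sim$chronogram), f("chronogram.nwk"))
    writeLines(partition_charset_lines(attr(sim$alignment, "partition")),
               f("partitions.txt"))
    man <- c(vapply(seq_along(out$params), function(i)
      paste0(names(out$params)[i], "=",
             paste(format(out$params[[i]]), collapse = ",")), character(1)),
      paste0("n_columns=", ncol(sim$alignment)),
      paste0("n_indel_events=", sim$n_indel_events))
    writeLines(man, f("manifest.txt"))
    out$files <- vapply(c("alignment.fasta", "sequences.fasta", "true_tree.nwk",
                          "chronogram.nwk", "partitions.txt", "manifest.txt"),
                        f, character(1))
  }
  out
}

# Fixed-geometry chronogram for the aa_like profile: Yule ingroup rescaled to
# the crown age, then outgroup and two calibration taxa grafted at set ages.
# Ingroup node ages are kept >= min_gap apart (and off zero): the emulated
# study's printed divergence times are spaced ~0.1 Myr, so near-simultaneous
# splits (internal edges carrying ~1 expected substitution) would be
# unrealistically hard for every inference method.
aa_like_chronogram <- function(p, seed, min_gap = 0.05) {
  ing <- simulate_yule_chronogram(p$n_ingroup, 2, seed,
                                  labels = sprintf("AA%02d", seq_len(p$n_ingroup)))
  idx <- (ing$ntip + 1):(ing$ntip + ing$tree$Nnode)
  ages <- ing$ages[idx]
  # increasing remap that enforces the spacing, then rescale to the crown age
  ord <- order(ages)
  spaced <- ages[ord]
  spaced[1] <- max(spaced[1], min_gap)
  for (i in seq_along(spaced)[-1])
    spaced[i] <- max(spaced[i], spaced[i - 1] + min_gap)
  ages[ord] <- spaced
  ing <- chronogram(ing$tree, ages)
  scale <- p$crown_age / root_age(ing)
  ing_phy <- chronogram_phylo(ing)
  ing_phy$edge.length <- ing_phy$edge.length * scale
  ing_nwk <- sub(";$", "", ape::write.tree(ing_phy))
  txt <- sprintf("(CAL1:%g,(CAL2:%g,(OUT:%g,%s:%g):%g):%g);",
                 p$root_age, p$second_calib_age, p$outgroup_age,
                 ing_nwk, p$outgroup_age - p$crown_age,
                 p$second_calib_age - p$outgroup_age,
                 p$root_age - p$second_calib_age)
  as_chronogram(ape::read.tree(text = txt))
}

# charset lines (1-based inclusive) for a partition_set
partition_charset_lines <- function(ps) {
  unlist(lapply(names(ps$partitions), function(nm) {
    m <- ps$partitions[[nm]]
    iv <- paste(apply(m, 1, function(r) paste0(r[1] + 1L, "-", r[2])),
                collapse = " ")
    paste0("charset ", nm, " = ", iv, ";")
  }))
}
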