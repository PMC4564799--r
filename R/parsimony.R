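# IUPAC code -> 4-bit state mask (A=1, C=2, G=4, T=8); missing = all four
iupac_mask_table <- function() {
  p <- iupac_partial_table()
  stats::setNames(as.integer(colSums(p * c(1L, 2L, 4L, 8L))), colnames(p))
}
IUPAC_MASK <- iupac_mask_table()

# Pattern bitmask matrix (taxa x patterns) + weights for Fitch counting.
fitch_data <- function(alignment) {
  pd <- compress_patterns(alignment)
  masks <- matrix(IUPAC_MASK[pd$patterns], nrow = nrow(pd$patterns),
                  dimnames = list(rownames(pd$patterns), NULL))
  list(masks = masks, weights = pd$weights)
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of unordered state changes over all columns, with gaps,
#' `N` and ambiguity codes contributing their full compatible state set at
#' the tip (missing data). The score is independent of rooting and taxon
#' input order.
#'
#' @param tree `phylo` whose tips match the alignment taxa.
#' @param alignment A [as_alignment()] matrix, or a prebuilt structure from
#'   the internal `fitch_data()`.
#' @return Integer parsimony score.
#' @export
fitch_length <- function(tree, alignment) {
  fd <- if (is.list(alignment) && !is.null(alignment$masks)) alignment
        else fitch_data(alignment)
  phy <- ape::unroot(tree)
  miss <- setdiff(phy$tip.label, rownames(fd$masks))
  if (length(miss)) stop("tree tips not in alignment: ", paste(miss, collapse = ", "))
  adj <- tree_adjacency(phy)
  ntip <- length(phy$tip.label)
  P <- length(fd$weights)
  cost <- integer(P)
  # root on tip 1's pendant edge => binary recursion everywhere
  rec <- function(node, from) {
    if (node <= ntip) return(fd$masks[phy$tip.label[node], ])
    kids <- setdiff(adj[[node]], from)
    st <- rec(kids[1], node)
    for (k in kids[-1]) {
      st2 <- rec(k, node)
      inter <- bitwAnd(st, st2)
      zero <- inter == 0L
      cost[zero] <<- cost[zero] + 1L
      st <- ifelse(zero, bitwOr(st, st2), inter)
    }
    st
  }
  start <- adj[[1L]][1]
  st_in <- rec(start, 1L)
  inter <- bitwAnd(st_in, fd$masks[phy$tip.label[1L], ])
  cost[inter == 0L] <- cost[inter == 0L] + 1L
  as.integer(sum(cost * fd$weights))
}

# Insert tip `label` into every edge of an unrooted tree; returns newick
# strings (one per edge).
insertion_candidates <- function(phy, label) {
  if (length(phy$tip.label) == 1L)
    return(paste0("(", phy$tip.label, ",", label, ");"))
  if (length(phy$tip.label) == 2L)
    return(paste0("(", phy$tip.label[1], ",", phy$tip.label[2], ",", label, ");"))
  vapply(attachment_strings(ape::unroot(phy)), function(s)
    paste0("(", substr(s, 2, nchar(s) - 1), ",", label, ");"), character(1),
    USE.NAMES = FALSE)
}

# One random-addition stepwise build; returns phylo.
stepwise_addition <- function(fd, order_taxa) {
  cur <- ape::read.tree(text = paste0("(", paste(order_taxa[1:3], collapse = ","), ");"))
  for (tx in order_taxa[-(1:3)]) {
    cands <- insertion_candidates(cur, tx)
    trees <- lapply(cands, function(s) ape::read.tree(text = s))
    sub <- fd
    sub$masks <- fd$masks[c(trees[[1]]$tip.label), , drop = FALSE]
    scores <- vapply(trees, fitch_length, numeric(1), alignment = sub)
    best <- which(scores <= min(scores) + 1e-9)
    if (length(best) > 1) {
      keys <- vapply(trees[best], topology_key, character(1))
      best <- best[order(keys)[1]]
    }
    cur <- trees[[best]]
  }
  cur
}

#' Maximum-parsimony heuristic search
#'
#' For each replicate, a random-order stepwise addition builds a start tree
#' which is then improved by hill-climbing branch swapping (TBR by default:
#' bisect every edge, reconnect across all edge pairs; strict improvement
#' only). With `keep_all_optimal` all distinct equally best trees found
#' across replicates (plus equal-score swap neighbours of the optima) are
#' returned.
#'
#' @param alignment A [as_alignment()] matrix.
#' @param n_addition_replicates Number of random-addition starts.
#' @param swap `"TBR"`, `"NNI"`, or `"none"`.
#' @param keep_all_optimal Keep every equally parsimonious tree (MulTrees).
#' @param seed Integer seed; the search is deterministic given the seed.
#' @return List of class `parsimony_result`: `trees` (list of phylo),
#'   `score`, `n_replicates`.
#' @export
parsimony_search <- function(alignment, n_addition_replicates = 10L,
                             swap = c("TBR", "NNI", "none"),
                             keep_all_optimal = TRUE, seed = 1L) {
  swap <- match.arg(swap)
  if (nrow(alignment) < 4) stop("parsimony search needs >= 4 taxa")
  fd <- fitch_data(alignment)
  taxa <- sort(rownames(alignment))
  set.seed(seed)
  best_score <- Inf
  best <- list()    # topology_key -> phylo
  for (rep in seq_len(n_addition_replicates)) {
    ord <- sample(taxa)
    tr <- stepwise_addition(fd, ord)
    res <- swap_hill_climb(tr, fd, swap)
    sc <- res$score
    cands <- c(list(res$tree), if (keep_all_optimal) res$ties else NULL)
    if (sc < best_score - 1e-9) { best_score <- sc; best <- list() }
    if (sc <= best_score + 1e-9) {
      for (tt in cands) {
        k <- topology_key(tt)
        if (is.null(best[[k]])) best[[k]] <- tt
      }
    }
  }
  trees <- best[order(names(best))]
  names(trees) <- NULL
  structure(list(trees = trees, score = best_score,
                 n_replicates = n_addition_replicates),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> score ", x$score, ", ", length(x$trees),
      " optimal tree(s), ", x$n_replicates, " addition replicate(s)\n", sep = "")
  invisible(x)
}

# Hill climb from `tree` using the requested swap neighbourhood; strict
# improvement only; deterministic tie-breaking by topology key.
swap_hill_climb <- function(tree, fd, swap) {
  cur <- ape::unroot(tree)
  cur_score <- fitch_length(cur, fd)
  ties <- list()
  if (swap == "none") return(list(tree = cur, score = cur_score, ties = ties))
  repeat {
    nb <- if (swap == "TBR") {
      lapply(tbr_neighbors(cur), function(s) ape::read.tree(text = s))
    } else nni_neighbors(cur)
    if (length(nb) == 0) break
    scores <- vapply(nb, fitch_length, numeric(1), alignment = fd)
    ties <- nb[abs(scores - cur_score) < 1e-9]
    if (min(scores) >= cur_score - 1e-9) break
    best <- which(scores <= min(scores) + 1e-9)
    if (length(best) > 1) {
      keys <- vapply(nb[best], topology_key, character(1))
      best <- best[order(keys)[1]]
    }
    cur <- nb[[best]]
    cur_score <- scores[best]
  }
  list(tree = cur, score = cur_score, ties = ties)
}
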