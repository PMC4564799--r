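# --- low-level unrooted tree helpers -----------------------------------------
# Adjacency-list view of a phylo object: for node i, adj[[i]] is the vector of
# neighbouring node ids (edges in both directions).
tree_adjacency <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  adj <- vector("list", n)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Newick string of the subtree at `node`, looking away from `from`
subtree_string <- function(phy, adj, node, from) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- setdiff(adj[[node]], from)
  parts <- sort(vapply(kids, function(k) subtree_string(phy, adj, k, node),
                       character(1)))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Canonical topology key for an unrooted tree
#'
#' A string invariant under rooting, rotation and taxon input order; used for
#' deduplication and congruence checks.
#'
#' @param phy A `phylo` tree.
#' @return Character scalar.
#' @export
topology_key <- function(phy) {
  phy <- ape::unroot(phy)
  adj <- tree_adjacency(phy)
  anchor <- which(phy$tip.label == min(phy$tip.label))
  paste0("(", phy$tip.label[anchor], ",",
         subtree_string(phy, adj, adj[[anchor]][1], anchor), ");")
}

# Non-trivial bipartitions of an unrooted tree, each encoded as the sorted
# comma-joined tip set on the side NOT containing the alphabetically first
# taxon.
tree_splits <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  first <- min(phy$tip.label)
  phy2 <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy2$tip.label[i]
  out <- character(0)
  for (k in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[k, 1]; chi <- phy2$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
    s <- below[[chi]]
    if (length(s) >= 2 && length(s) <= ntip - 2) {
      if (first %in% s) s <- setdiff(phy2$tip.label, s)
      out <- c(out, paste(sort(s), collapse = ","))
    }
  }
  unique(out)
}

# Build a rooted tree from a set of mutually compatible clades (tip-label
# vectors); returns a phylo. Used by the consensus builder.
tree_from_clades <- function(taxa, clades) {
  clades <- clades[order(-lengths(clades))]
  build <- function(members, pool) {
    inner <- pool[vapply(pool, function(cl) all(cl %in% members) &&
                           length(cl) < length(members), logical(1))]
    taken <- character(0)
    parts <- character(0)
    while (length(inner)) {
      cl <- inner[[1]]
      inner <- inner[-1]
      if (any(cl %in% taken)) next
      taken <- c(taken, cl)
      parts <- c(parts, build(cl, inner))
    }
    singles <- setdiff(members, taken)
    all_parts <- sort(c(parts, singles))
    if (length(all_parts) == 1) return(all_parts)
    paste0("(", paste(all_parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(sort(taxa), clades), ";"))
}

#' Root a tree on the out-group's pendant edge
#'
#' The root is inserted at the midpoint of the edge leading to the out-group
#' tip (halving its branch length when lengths are present).
#'
#' @param tree A `phylo` tree.
#' @param outgroup Tip label to root on.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("out-group taxon not in tree: ", outgroup)
  tree <- ape::unroot(tree)
  tip <- which(tree$tip.label == outgroup)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
    rooted <- phytools::reroot(tree, tip, position = 0.5)
    rooted$edge.length <- NULL
    rooted
  } else {
    len <- tree$edge.length[tree$edge[, 2] == tip]
    phytools::reroot(tree, tip, position = len / 2)
  }
}

#' Majority-rule consensus of a set of trees
#'
#' Keeps every bipartition occurring in more than `threshold` of the trees
#' and assembles them into one (possibly multifurcating) tree; internal node
#' labels carry the split frequencies (percent).
#'
#' @param trees List (or `multiPhylo`) of trees over identical taxa.
#' @param threshold Frequency cut-off (default 0.5 = majority rule).
#' @return Unrooted consensus `phylo` with `node.label` frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), taxa))
      stop("trees must share an identical taxon set")
  tab <- table(unlist(lapply(trees, tree_splits)))
  freq <- as.numeric(tab) / length(trees)
  keep <- names(tab)[freq > threshold]
  keep_freq <- freq[freq > threshold]
  clades <- strsplit(keep, ",", fixed = TRUE)
  cons <- tree_from_clades(taxa, clades)
  cons <- ape::unroot(cons)
  # attach frequencies (percent) to matching internal edges
  sp <- tree_splits(cons)
  lab <- rep("", cons$Nnode)
  map <- stats::setNames(round(100 * keep_freq, 1), keep)
  ntip <- length(cons$tip.label)
  phy2 <- ape::reorder.phylo(cons, "postorder")
  below <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy2$tip.label[i]
  first <- min(taxa)
  for (k in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[k, 1]; chi <- phy2$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
    if (chi > ntip) {
      s <- below[[chi]]
      if (first %in% s) s <- setdiff(taxa, s)
      key <- paste(sort(s), collapse = ",")
      if (key %in% names(map)) lab[chi - ntip] <- as.character(map[[key]])
    }
  }
  phy2$node.label <- lab
  phy2
}

# --- topology move sets ------------------------------------------------------

# All nearest-neighbour-interchange neighbours of an unrooted binary tree.
nni_neighbors <- function(phy) {
  phy <- ape::reorder.phylo(ape::unroot(phy), "cladewise")
  ntip <- length(phy$tip.label)
  res <- list()
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    if (v <= ntip) next                      # internal edges only
    x_edges <- which(phy$edge[, 1] == u & phy$edge[, 2] != v)
    if (length(x_edges) == 0) next
    xk <- x_edges[1]                          # one swap partner suffices
    c_edges <- which(phy$edge[, 1] == v)
    for (ck in c_edges) {
      e2 <- phy$edge
      e2[xk, ] <- c(u, phy$edge[ck, 2])
      e2[ck, ] <- c(v, phy$edge[xk, 2])
      nb <- phy
      nb$edge <- e2
      nb <- ape::reorder.phylo(nb, "cladewise")
      res[[length(res) + 1L]] <- nb
    }
  }
  res
}

# Rooted-at-each-edge newick strings of an unrooted tree over >= 1 tips.
attachment_strings <- function(phy_or_label) {
  if (is.character(phy_or_label)) return(phy_or_label)
  phy <- phy_or_label
  if (length(phy$tip.label) == 1L) return(phy$tip.label)
  if (length(phy$tip.label) == 2L)
    return(paste0("(", paste(sort(phy$tip.label), collapse = ","), ")"))
  adj <- tree_adjacency(phy)
  vapply(seq_len(nrow(phy$edge)), function(k) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    paste0("(", subtree_string(phy, adj, a, b), ",",
           subtree_string(phy, adj, b, a), ")")
  }, character(1))
}

# Tree-bisection-reconnection neighbourhood of an unrooted binary tree,
# returned as unique newick strings (topology only, original excluded).
tbr_neighbors <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  own <- topology_key(phy)
  seen <- new.env(parent = emptyenv())
  out <- character(0)
  splits_done <- character(0)
  for (k in seq_len(nrow(phy$edge))) {
    chi <- phy$edge[k, 2]
    tipsA <- unrooted_tips_below(phy, chi)
    tipsB <- setdiff(phy$tip.label, tipsA)
    if (length(tipsA) < 1 || length(tipsB) < 1) next
    skey <- paste(sort(tipsA), collapse = ",")
    if (length(tipsB) < length(tipsA) ||
        (length(tipsB) == length(tipsA) && min(tipsB) < min(tipsA)))
      skey <- paste(sort(tipsB), collapse = ",")
    if (skey %in% splits_done) next
    splits_done <- c(splits_done, skey)
    TA <- if (length(tipsA) <= 2) NULL else ape::keep.tip(phy, tipsA)
    TB <- if (length(tipsB) <= 2) NULL else ape::keep.tip(phy, tipsB)
    sa <- if (is.null(TA)) {
      if (length(tipsA) == 1) tipsA else paste0("(", paste(sort(tipsA), collapse = ","), ")")
    } else attachment_strings(ape::unroot(TA))
    sb <- if (is.null(TB)) {
      if (length(tipsB) == 1) tipsB else paste0("(", paste(sort(tipsB), collapse = ","), ")")
    } else attachment_strings(ape::unroot(TB))
    for (s1 in sa) for (s2 in sb) {
      txt <- paste0("(", s1, ",", s2, ");")
      tr <- ape::read.tree(text = txt)
      key <- topology_key(tr)
      if (key == own || !is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      out <- c(out, txt)
    }
  }
  out
}

# Tip labels below a node of an (arbitrarily rooted) phylo.
unrooted_tips_below <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  phy2 <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy2$tip.label[i]
  for (k in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[k, 1]; chi <- phy2$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  below[[node]]
}
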