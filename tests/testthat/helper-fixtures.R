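# Shared helpers: small random alignments, trees and a toy GenBank record.

random_alignment <- function(n_taxa, n_cols, seed = 1,
                             chars = c("A", "C", "G", "T"),
                             gap_frac = 0, taxa = paste0("t", seq_len(n_taxa))) {
  set.seed(seed)
  m <- matrix(sample(chars, n_taxa * n_cols, replace = TRUE), n_taxa,
              dimnames = list(taxa, NULL))
  if (gap_frac > 0) m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  as_alignment(m)
}

random_bl_tree <- function(n, seed = 1, min_bl = 0.05, max_bl = 0.5) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

toy_genbank_path <- function() {
  path <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TOY0001                 60 bp    DNA     circular PLN 01-JAN-2015",
    "ACCESSION   TOY0001",
    "FEATURES             Location/Qualifiers",
    "     gene            5..28",
    "                     /gene=\"psbA\"",
    "     CDS             join(5..16,21..28)",
    "                     /gene=\"psbA\"",
    "     tRNA            complement(35..44)",
    "                     /gene=\"trnH\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), path)
  path
}

# Stretch pendant edges of a rooted tree so all tips reach the same depth.
force_ultrametric <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  h <- max(depth[seq_len(ntip)])
  for (i in seq_len(ntip)) {
    k <- which(phy$edge[, 2] == i)
    phy$edge.length[k] <- phy$edge.length[k] + (h - depth[i])
  }
  phy
}

# Map each edge of an unrooted tree to its branch length, keyed by the sorted
# tip set below the edge (pendant edges keyed by the tip name).
edge_lengths_by_split <- function(phy) {
  phy <- ape::reorder.phylo(ape::unroot(phy), "postorder")
  ntip <- length(phy$tip.label)
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  first <- min(phy$tip.label)
  out <- numeric(0)
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; chi <- phy$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
    s <- below[[chi]]
    if (first %in% s) s <- setdiff(phy$tip.label, s)
    out[paste(sort(s), collapse = ",")] <- phy$edge.length[k]
  }
  out
}

# cache the aa_like fixture across test files (expensive to regenerate)
aa_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("aa_like", seed = 42)
    cache
  }
})
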