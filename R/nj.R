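#' Neighbour-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration on the Q criterion. Ties in Q are
#' broken by the lexicographically smallest (label, label) pair so the
#' result is bit-reproducible. Negative branch lengths are clamped to zero
#' and the clamped total is recorded in `attr(tree, "negative_deficit")`.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return Unrooted `phylo` with branch lengths.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs >= 3 taxa")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries (saturation?)")

  # working copies; each cluster holds a newick fragment and its sort key
  D <- d
  frag <- stats::setNames(taxa, taxa)
  key <- stats::setNames(taxa, taxa)
  deficit <- 0
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[rownames(D)[ij[1]]], key[rownames(D)[ij[2]]]))
      paste(ks, collapse = "|")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { deficit <- deficit + abs(vi); vj <- vj + vi; vi <- 0 }
    if (vj < 0) { deficit <- deficit + abs(vj); vi <- vi + vj; vj <- 0 }
    new_lab <- paste0("{", li, "+", lj, "}")
    frag[new_lab] <- paste0("(", frag[li], ":", format(vi, digits = 12),
                            ",", frag[lj], ":", format(vj, digits = 12), ")")
    key[new_lab] <- min(key[li], key[lj])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    D <- D2
  }
  # final three-cluster star: closed-form edge lengths
  labs <- rownames(D)
  v <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  neg <- v < 0
  deficit <- deficit + sum(abs(v[neg]))
  v[neg] <- 0
  txt <- paste0("(", frag[labs[1]], ":", format(v[1], digits = 12), ",",
                frag[labs[2]], ":", format(v[2], digits = 12), ",",
                frag[labs[3]], ":", format(v[3], digits = 12), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "negative_deficit") <- deficit
  tr
}

#' Neighbour joining straight from an alignment
#'
#' Convenience wrapper: model-based distances then [neighbor_joining()].
#'
#' @inheritParams distance_matrix
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(alignment, model = substitution_model("JC"),
                    gap_mode = "missing") {
  neighbor_joining(distance_matrix(alignment, model, gap_mode))
}
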