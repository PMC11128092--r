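# Trees from core SNP distances, and Robinson-Foulds comparison.

#' Pairwise SNP distance matrix from a core alignment
#'
#' d[i, j] is the proportion of mismatching columns among the columns where
#' both genomes carry a base in \{A,C,G,T\} (gaps and Ns excluded), summed
#' over all LCBs.  The reference is included as a taxon.
#'
#' @param aln a \code{\link{core_alignment}} over at least 3 genomes.
#' @return symmetric numeric matrix with genome ids as dimnames.
#' @export
snp_distance_matrix <- function(aln) {
  G <- length(aln$roster)
  if (G < 3L) stop("need at least 3 genomes for a distance matrix")
  diffs <- comps <- matrix(0, G, G)
  for (b in aln$lcbs) {
    cnt <- .pair_counts_cpp(unname(b$rows))
    diffs <- diffs + cnt$diff
    comps <- comps + cnt$comp
  }
  bad <- which(comps == 0 & upper.tri(comps), arr.ind = TRUE)
  if (nrow(bad))
    stop("no comparable core columns between ", aln$roster[bad[1L, 1L]],
         " and ", aln$roster[bad[1L, 2L]])
  d <- diffs / comps
  diag(d) <- 0
  dimnames(d) <- list(aln$roster, aln$roster)
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration (via \code{ape::nj});
#' negative branch lengths are clamped to zero.
#'
#' @param dm symmetric distance matrix with labels as dimnames.
#' @return unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Polytomies are taken as-is (no resolution).  Returns a named numeric
# vector: key -> branch length of the corresponding internal edge.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  desc <- function(node, edges, tips) {
    kids <- edges[edges[, 1L] == node, 2L]
    unlist(lapply(kids, function(k)
      if (k <= ntip) tips[k] else desc(k, edges, tips)))
  }
  internal <- which(tree$edge[, 2L] > ntip)
  keys <- character(0)
  wts <- numeric(0)
  for (e in internal) {
    side <- desc(tree$edge[e, 2L], tree$edge, tree$tip.label)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (labs[1L] %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    keys <- c(keys, key)
    wts <- c(wts, if (is.null(tree$edge.length)) 1
             else tree$edge.length[e])
  }
  setNames(wts, keys)
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
}

#' Normalized Robinson-Foulds distance
#'
#' The number of non-trivial bipartitions differing between the two trees,
#' normalized by the total number of internal branches across both trees:
#' |B1 delta B2| / (|B1| + |B2|).  Zero when both trees have no internal
#' edges.
#'
#' @param t1,t2 \code{phylo} trees over the same leaf set.
#' @return value in [0, 1].
#' @export
normalized_rf <- function(t1, t2) {
  check_same_leaves(t1, t2)
  b1 <- names(tree_bipartitions(t1))
  b2 <- names(tree_bipartitions(t2))
  tot <- length(b1) + length(b2)
  if (tot == 0L) return(0)
  (sum(!b1 %in% b2) + sum(!b2 %in% b1)) / tot
}

#' Normalized weighted Robinson-Foulds distance
#'
#' Branch-length-weighted symmetric difference over all non-trivial
#' bipartitions: sum over bipartitions of |w1(b) - w2(b)| (weight 0 where a
#' bipartition is absent), normalized by the total internal branch length of
#' both trees.
#'
#' @param t1,t2 \code{phylo} trees with branch lengths over the same leaf
#'   set.
#' @return value in [0, 1].
#' @export
normalized_weighted_rf <- function(t1, t2) {
  check_same_leaves(t1, t2)
  w1 <- tree_bipartitions(t1)
  w2 <- tree_bipartitions(t2)
  keys <- union(names(w1), names(w2))
  a <- ifelse(keys %in% names(w1), w1[keys], 0)
  b <- ifelse(keys %in% names(w2), w2[keys], 0)
  denom <- sum(w1) + sum(w2)
  if (denom == 0) return(0)
  sum(abs(a - b)) / denom
}

#' Infer a core-genome tree from an alignment
#'
#' Convenience wrapper: SNP distance matrix then neighbour joining.
#'
#' @param aln a \code{\link{core_alignment}}.
#' @return unrooted \code{phylo} tree.
#' @export
core_tree <- function(aln) neighbor_joining(snp_distance_matrix(aln))
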