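#' Effective number of strains
#'
#' The exponential of the Shannon entropy (natural log) of a sample's strain
#' abundance distribution: the number of equally abundant strains that would
#' give the same entropy. Entropy is computed with [vegan::diversity()].
#'
#' @param composition Named or plain fraction vector (non-negative, at least
#'   one positive entry). Zero entries are ignored.
#' @return A value in \[1, number of strains with positive abundance\].
#' @examples
#' effective_number_of_strains(c(0.5, 0.5)) # 2
#' @export
effective_number_of_strains <- function(composition) {
  if (!is.numeric(composition) || all(composition <= 0) ||
      any(composition < 0)) {
    stop_invalid("composition must be non-negative with a positive entry")
  }
  p <- composition / sum(composition)
  exp(vegan::diversity(p, index = "shannon"))
}

#' Build a strain tree from genotype Jaccard distances
#'
#' Average-linkage (UPGMA) hierarchical clustering on pairwise distances
#' d = 1 - Jaccard similarity between discretized genotypes, returned as a
#' rooted ultrametric `ape` phylo tree whose branch lengths are in
#' Jaccard-distance units. Identical genotypes coalesce at height 0.
#'
#' @param genotypes Genotype matrix (strains x sites) with unique row names;
#'   fractional entries are discretized at 0.5.
#' @return An object of class `phylo`.
#' @export
build_strain_tree <- function(genotypes) {
  if (nrow(genotypes) < 2) stop_invalid("need at least 2 genotypes")
  if (is.null(rownames(genotypes)) || anyDuplicated(rownames(genotypes))) {
    stop_invalid("genotypes must have unique row names")
  }
  J <- jaccard_cross(genotypes, genotypes)
  d <- stats::as.dist(1 - J)
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)  # node heights halved: leaves at distance d sit d/2 deep
}

#' Weighted UniFrac dissimilarity between two strain compositions
#'
#' Sum over branches of branch length times the absolute difference in the
#' fraction of each community's total abundance descending through the
#' branch. Unnormalized ("raw") by default; with `normalized = TRUE` the sum
#' is divided by its maximum attainable value on the tree (the abundance-
#' weighted mean root-to-leaf distance of the two communities).
#'
#' @param comp_a,comp_b Named abundance vectors; every named strain must be a
#'   tree leaf. Abundances are normalized to sum to 1.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param normalized Return the normalized variant (default FALSE).
#' @return Non-negative dissimilarity; 0 iff the two compositions place
#'   identical mass identically.
#' @export
weighted_unifrac <- function(comp_a, comp_b, tree, normalized = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  pa <- unifrac_leaf_weights(comp_a, tree)
  pb <- unifrac_leaf_weights(comp_b, tree)
  # per-edge descendant mass by postorder accumulation
  nt <- length(tree$tip.label)
  wa <- edge_mass(tree, pa)
  wb <- edge_mass(tree, pb)
  raw <- sum(tree$edge.length * abs(wa - wb))
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  denom <- sum(depth * (pa + pb))
  if (denom == 0) return(0)
  raw / denom
}

unifrac_leaf_weights <- function(comp, tree) {
  comp <- comp[comp > 0]
  if (length(comp) == 0) stop_invalid("composition has no positive abundance")
  miss <- setdiff(names(comp), tree$tip.label)
  if (length(miss)) {
    stop_invalid("strains not in tree: ", paste(miss, collapse = ", "))
  }
  p <- numeric(length(tree$tip.label))
  p[match(names(comp), tree$tip.label)] <- comp / sum(comp)
  p
}

edge_mass <- function(tree, tipw) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  mass <- numeric(nn)
  mass[seq_len(nt)] <- tipw
  # accumulate child mass into parents in postorder
  for (e in ape::postorder(tree)) {
    mass[tree$edge[e, 1]] <- mass[tree$edge[e, 1]] + mass[tree$edge[e, 2]]
  }
  mass[tree$edge[, 2]]
}

#' Self- versus other-sample UniFrac dissimilarity
#'
#' For every sample, the weighted UniFrac dissimilarity between its inferred
#' and its true strain composition ("self"), and the dissimilarities between
#' its inferred composition and the true compositions of all other samples
#' ("other"), stratified by the sample's spike-in level. All comparisons
#' share one tree over the union of true and inferred strains.
#'
#' @param true_composition,inferred_composition Samples x strains abundance
#'   matrices with identical row order (sample ids).
#' @param tree `phylo` tree containing every strain of both matrices.
#' @param lbp_level Per-sample spike-in level vector.
#' @return Data frame: `sample_id`, `lbp_level`, `self_unifrac`,
#'   `median_other_unifrac`, `min_other_unifrac`.
#' @export
self_vs_other_dissimilarity <- function(true_composition,
                                        inferred_composition, tree,
                                        lbp_level) {
  stopifnot(nrow(true_composition) == nrow(inferred_composition),
            nrow(true_composition) == length(lbp_level))
  n <- nrow(true_composition)
  nt <- length(tree$tip.label)
  Wt <- sapply(seq_len(n), function(i) {
    edge_mass(tree, unifrac_leaf_weights(true_composition[i, ], tree))
  })
  Wi <- sapply(seq_len(n), function(i) {
    edge_mass(tree, unifrac_leaf_weights(inferred_composition[i, ], tree))
  })
  len <- tree$edge.length
  self <- numeric(n); med_other <- numeric(n); min_other <- numeric(n)
  for (i in seq_len(n)) {
    d <- colSums(len * abs(Wt - Wi[, i]))
    self[i] <- d[i]
    min_other[i] <- min(d[-i])
    med_other[i] <- stats::median(d[-i])
  }
  data.frame(sample_id = rownames(true_composition) %||% seq_len(n),
             lbp_level = lbp_level,
             self_unifrac = self,
             median_other_unifrac = med_other,
             min_other_unifrac = min_other)
}
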