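#' Discretize a fractional genotype
#'
#' Entries at or above the threshold become the alternate allele (1); ties map
#' to alternate. Binary inputs are unchanged.
#'
#' @param genotype Numeric vector or matrix with entries in \[0, 1\].
#' @param threshold Discretization threshold, default 0.5.
#' @return Integer 0/1 object of the same shape.
#' @export
discretize_genotype <- function(genotype, threshold = 0.5) {
  assert_fraction(genotype, "genotype")
  out <- (genotype >= threshold) * 1L
  if (is.matrix(genotype)) dimnames(out) <- dimnames(genotype)
  else names(out) <- names(genotype)
  out
}

#' Jaccard similarity of two binary genotypes
#'
#' Computed over the strains' alternate-allele site sets:
#' \eqn{|A \cap B| / |A \cup B|}. Two all-reference genotypes (both sets
#' empty) have similarity 1.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard_similarity(c(1, 1, 0), c(0, 1, 1)) # 1/3
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("genotype lengths differ")
  a <- a >= 0.5; b <- b >= 0.5
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Pairwise Jaccard between rows of two binary matrices.
jaccard_cross <- function(Ga, Gb) {
  Ga <- (Ga >= 0.5) * 1; Gb <- (Gb >= 0.5) * 1
  inter <- Ga %*% t(Gb)
  un <- outer(rowSums(Ga), rowSums(Gb), "+") - inter
  J <- inter / un
  J[un == 0] <- 1
  dimnames(J) <- list(rownames(Ga), rownames(Gb))
  J
}

#' Match counts between true and inferred strains across thresholds
#'
#' For each Jaccard-similarity threshold, counts for every true strain the
#' number of inferred strains whose (discretized) genotype is at least that
#' similar.
#'
#' @param true_genotypes,inferred_genotypes Genotype matrices (strains x
#'   sites); inferred genotypes may be fractional and are discretized at 0.5.
#' @param thresholds Numeric vector of thresholds in (0, 1\].
#' @return Data frame: `threshold`, `strain_id`, `n_matches`.
#' @export
match_table <- function(true_genotypes, inferred_genotypes,
                        thresholds = c(0.3, 0.5, 0.7, 0.9, 0.95, 1.0)) {
  if (nrow(true_genotypes) == 0 || nrow(inferred_genotypes) == 0) {
    stop_invalid("genotype sets must be non-empty")
  }
  J <- jaccard_cross(true_genotypes, inferred_genotypes)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    data.frame(threshold = th,
               strain_id = rownames(true_genotypes) %||%
                 seq_len(nrow(true_genotypes)),
               n_matches = as.integer(rowSums(J >= th)))
  }))
  rownames(out) <- NULL
  out
}

#' Collapse near-identical inferred strains
#'
#' Greedily merges pairs of inferred strains whose discretized genotypes
#' exceed the similarity threshold, in descending order of total (cohort-wide)
#' abundance: the more abundant strain survives, carries its own genotype, and
#' absorbs the pair's per-sample abundances. Iterates to a fixed point.
#' Per-sample abundance totals are conserved.
#'
#' @param result A `strain_inference` (see [fit_mixture()]).
#' @param threshold Jaccard similarity above which strains merge
#'   (default 0.99).
#' @param inclusive If TRUE merge at `>= threshold` rather than
#'   `> threshold` (used for product-strain merging at 0.95).
#' @return A `strain_inference` with possibly fewer strains.
#' @export
collapse_duplicates <- function(result, threshold = 0.99, inclusive = FALSE) {
  stopifnot(inherits(result, "strain_inference"))
  G <- result$genotypes
  Ab <- result$abundances
  Gd <- (G >= 0.5) * 1
  repeat {
    K <- nrow(G)
    if (K < 2) break
    J <- jaccard_cross(Gd, Gd)
    diag(J) <- 0
    hit <- if (inclusive) J >= threshold else J > threshold
    if (!any(hit)) break
    tot <- colSums(Ab)
    # survivor: largest total abundance, ties by lexicographic strain id
    ord <- order(-tot, rownames(G))
    merged <- FALSE
    for (a in ord) {
      partners <- which(hit[a, ])
      partners <- partners[tot[partners] <= tot[a] | seq_len(K)[partners] > a]
      if (length(partners) == 0) next
      b <- partners[order(-tot[partners])][1]
      Ab[, a] <- Ab[, a] + Ab[, b]
      Ab <- Ab[, -b, drop = FALSE]
      G <- G[-b, , drop = FALSE]
      Gd <- Gd[-b, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  out <- result
  out$genotypes <- G
  out$abundances <- Ab
  out
}

#' Identify the inferred product (LBP) strain
#'
#' Merges inferred strains that are mutually similar at or above
#' `merge_threshold` (survivor rule as in [collapse_duplicates()]), then
#' returns the merged strain with maximal Jaccard similarity to the known
#' product genotype.
#'
#' @param result A `strain_inference`.
#' @param lbp_genotype Binary genotype vector of the product strain.
#' @param merge_threshold Merge threshold (default 0.95, inclusive).
#' @return List: `strain_id`, `similarity`, `abundance` (per-sample vector of
#'   the merged strain), and the `merged` result.
#' @export
identify_lbp_strain <- function(result, lbp_genotype, merge_threshold = 0.95) {
  stopifnot(inherits(result, "strain_inference"))
  if (nrow(result$genotypes) == 0) stop_invalid("empty inference result")
  merged <- collapse_duplicates(result, merge_threshold, inclusive = TRUE)
  J <- apply(merged$genotypes, 1, jaccard_similarity, b = lbp_genotype)
  best <- which.max(J)
  list(strain_id = rownames(merged$genotypes)[best],
       similarity = unname(J[best]),
       abundance = merged$abundances[, best],
       merged = merged)
}

#' Classify spike-in detection per sample
#'
#' Applies the study's detection rules given true and inferred product-strain
#' abundances: a false positive is a sample with true abundance 0 and
#' inferred abundance above 1%; a false negative has true abundance 10% and
#' inferred below 5%; presence is called at inferred abundance of at least
#' 10%. True-0 samples at or below 1% are true negatives; spiked samples
#' called present are true positives. Combinations the rules do not probe
#' (e.g. true 0 with inferred between 1% and 10%) are labeled
#' `indeterminate`.
#'
#' @param true_ab,inferred_ab Vectors of fractions in \[0, 1\].
#' @param fp_threshold,fn_threshold,presence_threshold The 1%, 5% and 10%
#'   rule constants.
#' @return Data frame: `true_lbp_abundance`, `inferred_lbp_abundance`,
#'   `label` in {TP, TN, FP, FN, indeterminate}.
#' @export
classify_detection <- function(true_ab, inferred_ab,
                               fp_threshold = 0.01, fn_threshold = 0.05,
                               presence_threshold = 0.10) {
  assert_fraction(true_ab, "true_ab")
  assert_fraction(inferred_ab, "inferred_ab")
  stopifnot(length(true_ab) == length(inferred_ab))
  eq <- function(x, v) abs(x - v) < 1e-9
  label <- rep("indeterminate", length(true_ab))
  label[eq(true_ab, 0) & inferred_ab > fp_threshold] <- "FP"
  label[eq(true_ab, 0.10) & inferred_ab < fn_threshold] <- "FN"
  label[eq(true_ab, 0) & inferred_ab <= fp_threshold] <- "TN"
  tp <- true_ab > 0 & !eq(true_ab, 0) & inferred_ab >= presence_threshold &
    !(eq(true_ab, 0.10) & inferred_ab < fn_threshold)
  label[tp] <- "TP"
  data.frame(true_lbp_abundance = true_ab,
             inferred_lbp_abundance = inferred_ab,
             label = label)
}

#' Product-strain abundance RMSE by sequencing depth
#'
#' Root mean squared error between true spike-in levels and inferred
#' product-strain abundances, computed within each depth group.
#'
#' @param true_ab,inferred_ab Aligned per-sample fraction vectors.
#' @param depth Per-sample depth vector.
#' @return Named numeric vector, one RMSE per depth (named by depth).
#' @export
lbp_abundance_rmse <- function(true_ab, inferred_ab, depth) {
  stopifnot(length(true_ab) == length(inferred_ab),
            length(true_ab) == length(depth))
  groups <- split(seq_along(depth), depth)
  empty <- lengths(groups) == 0
  if (any(empty)) warning("empty depth group(s) omitted")
  vapply(groups[!empty], function(ix) {
    sqrt(mean((inferred_ab[ix] - true_ab[ix])^2))
  }, numeric(1))
}

#' Cumulative-abundance agreement of matched strains
#'
#' For each true endogenous strain with at least one genotypically matching
#' inferred strain (Jaccard above `match_threshold`, computed on discretized
#' genotypes), compares the true cumulative abundance (summed over samples)
#' with the matched inferred strains' summed cumulative abundance, and
#' reports the Pearson correlation over strain pairs. The product strain is
#' excluded (its cumulative abundance dwarfs the endogenous strains).
#'
#' @param true_genotypes Binary matrix of true strains (rows named).
#' @param true_composition Samples x true-strain abundance matrix.
#' @param result A (collapsed) `strain_inference`.
#' @param match_threshold Match cutoff (default 0.9, strict `>`).
#' @param exclude Strain ids to drop from the true set (default `"sLBP"`).
#' @return List: `pairs` (data frame `strain_id`, `true_cumulative`,
#'   `inferred_cumulative`), `r` (Pearson correlation, `NA` with a warning if
#'   fewer than 2 matched pairs), `unmatched` (ids of true strains without a
#'   match).
#' @export
cumulative_abundance_correlation <- function(true_genotypes, true_composition,
                                             result, match_threshold = 0.9,
                                             exclude = "sLBP") {
  stopifnot(inherits(result, "strain_inference"))
  keep <- setdiff(rownames(true_genotypes), exclude)
  Gt <- true_genotypes[keep, , drop = FALSE]
  J <- jaccard_cross(Gt, result$genotypes)
  true_cum <- colSums(true_composition)[keep]
  inf_cum <- colSums(result$abundances)
  pairs <- NULL
  unmatched <- character(0)
  for (i in seq_len(nrow(Gt))) {
    hits <- which(J[i, ] > match_threshold)
    if (length(hits) == 0) {
      unmatched <- c(unmatched, keep[i])
    } else {
      pairs <- rbind(pairs, data.frame(
        strain_id = keep[i],
        true_cumulative = unname(true_cum[i]),
        inferred_cumulative = sum(inf_cum[hits])))
    }
  }
  r <- NA_real_
  if (!is.null(pairs) && nrow(pairs) >= 2) {
    r <- stats::cor(pairs$true_cumulative, pairs$inferred_cumulative)
  } else {
    warning("fewer than 2 matched pairs; correlation undefined")
  }
  list(pairs = pairs, r = r, unmatched = unmatched)
}
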