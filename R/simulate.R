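#' Simulate binary strain genotypes
#'
#' Draws pairwise-distinct binary allele vectors over a shared catalog of
#' biallelic SNV sites. Each site is an independent Bernoulli(0.5) draw of the
#' alternate allele; duplicate genotypes are rejected and redrawn so that every
#' strain in a cohort carries a unique SNV pattern.
#'
#' @param n_strains Number of strains to draw (>= 1).
#' @param n_sites Number of biallelic SNV sites (>= 1).
#' @param seed Integer seed; the same seed reproduces the same genotypes.
#' @param strain_ids Optional character vector of row names
#'   (default `strain_001`, ...).
#' @return Integer matrix of 0/1 alleles, strains in rows, sites in columns.
#' @examples
#' g <- simulate_strain_genotypes(3, 50, seed = 1)
#' @export
simulate_strain_genotypes <- function(n_strains, n_sites, seed,
                                      strain_ids = NULL) {
  n_strains <- assert_count(n_strains, "n_strains")
  n_sites <- assert_count(n_sites, "n_sites")
  if (n_strains > 2^min(n_sites, 30)) {
    stop_invalid("cannot draw ", n_strains, " distinct genotypes over ",
                 n_sites, " sites")
  }
  set.seed(seed)
  G <- matrix(rbinom(n_strains * n_sites, 1L, 0.5), n_strains, n_sites)
  repeat {
    key <- apply(G, 1, paste, collapse = "")
    dup <- which(duplicated(key))
    if (length(dup) == 0) break
    G[dup, ] <- rbinom(length(dup) * n_sites, 1L, 0.5)
  }
  rownames(G) <- strain_ids %||% sprintf("strain_%03d", seq_len(n_strains))
  storage.mode(G) <- "integer"
  G
}

#' Cohort configuration for a simulated single-strain LBP trial
#'
#' Bundles the design parameters of one simulated cohort. The defaults are the
#' study conditions: 100 participants with 4 samples each, 1 to 4
#' participant-private endogenous strains over 10,000 biallelic sites,
#' per-site coverage of 5x/10x/20x/30x, and one shared LBP strain spiked in at
#' a level drawn uniformly from 0 to 100% in 10% increments.
#'
#' @param n_participants Number of participants.
#' @param samples_per_participant Samples collected per participant.
#' @param n_sites Number of biallelic SNV sites.
#' @param strains_range Integer range (min, max) of endogenous strains per
#'   participant; each participant's count is drawn uniformly from it.
#' @param depths Set of nominal sequencing depths (reads per site); samples of
#'   a participant cycle through this set so depths are balanced.
#' @param lbp_levels Possible spike-in fractions of the LBP strain; drawn
#'   uniformly and independently per sample.
#' @param alpha Symmetric Dirichlet concentration for endogenous abundances.
#' @param depth_mode `"fixed"` (every site covered at exactly the nominal
#'   depth) or `"poisson"` (per-site depth is Poisson with the nominal mean).
#' @param seed Master seed for the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 100,
                          samples_per_participant = 4,
                          n_sites = 10000,
                          strains_range = c(1L, 4L),
                          depths = c(5, 10, 20, 30),
                          lbp_levels = seq(0, 1, by = 0.1),
                          alpha = 1,
                          depth_mode = c("fixed", "poisson"),
                          seed = 1) {
  assert_count(n_participants, "n_participants")
  assert_count(samples_per_participant, "samples_per_participant")
  assert_count(n_sites, "n_sites")
  if (length(depths) == 0) stop_invalid("depths must be non-empty")
  if (length(lbp_levels) == 0) stop_invalid("lbp_levels must be non-empty")
  if (any(depths < 1)) stop_invalid("depths must be >= 1")
  assert_fraction(lbp_levels, "lbp_levels")
  if (length(strains_range) != 2 || strains_range[1] < 1 ||
      strains_range[2] < strains_range[1]) {
    stop_invalid("strains_range must be (min, max) with 1 <= min <= max")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    samples_per_participant = as.integer(samples_per_participant),
    n_sites = as.integer(n_sites),
    strains_range = as.integer(strains_range),
    depths = depths,
    lbp_levels = lbp_levels,
    alpha = alpha,
    depth_mode = match.arg(depth_mode),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Build the per-sample design of a simulated cohort
#'
#' Assigns endogenous strains to participants (disjoint sets, counts drawn
#' from `strains_range`), and to every sample one sequencing depth (cycled so
#' each participant's samples are balanced across the depth grid) and one
#' spike-in level (uniform over `lbp_levels`, via a per-sample child seed so
#' any sample is reproducible in isolation).
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_design`: a list with `samples` (one row
#'   per sample: `sample_id`, `participant`, `sample_idx`, `depth`,
#'   `lbp_level`), `strain_owner` (named integer vector mapping endogenous
#'   strain id to participant), and the `config`.
#' @export
build_cohort_design <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  np <- config$n_participants
  ns <- config$samples_per_participant
  set.seed(child_seed(config$seed, 0L))
  n_per <- sample(seq(config$strains_range[1], config$strains_range[2]),
                  np, replace = TRUE)
  owner <- rep(seq_len(np), n_per)
  names(owner) <- sprintf("endo_%04d", seq_along(owner))
  samples <- expand.grid(sample_idx = seq_len(ns), participant = seq_len(np),
                         KEEP.OUT.ATTRS = FALSE)[, 2:1]
  samples$sample_id <- sprintf("P%03d_S%d", samples$participant,
                               samples$sample_idx)
  samples$depth <- config$depths[((samples$sample_idx - 1) %%
                                    length(config$depths)) + 1]
  samples$lbp_level <- vapply(seq_len(nrow(samples)), function(r) {
    set.seed(child_seed(config$seed, samples$participant[r],
                        samples$sample_idx[r]))
    sample(config$lbp_levels, 1)
  }, numeric(1))
  rownames(samples) <- NULL
  structure(list(samples = samples, strain_owner = owner, config = config),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("cohort_design:", x$config$n_participants, "participants x",
      x$config$samples_per_participant, "samples,",
      length(x$strain_owner), "endogenous strains,",
      x$config$n_sites, "sites\n")
  invisible(x)
}

#' Draw one sample's endogenous strain composition
#'
#' Relative abundances of a participant's endogenous strains are drawn from a
#' symmetric Dirichlet distribution, independently for each sample, so that
#' strain proportions vary from sample to sample.
#'
#' @param strain_ids Character vector of the participant's strain ids.
#' @param seed Integer seed.
#' @param alpha Symmetric Dirichlet concentration (default 1, i.e. uniform on
#'   the simplex).
#' @return Named numeric vector of fractions summing to 1.
#' @export
draw_sample_composition <- function(strain_ids, seed, alpha = 1) {
  if (length(strain_ids) == 0) stop_invalid("at least one strain is required")
  set.seed(seed)
  w <- rgamma(length(strain_ids), shape = alpha)
  if (sum(w) == 0) w <- rep(1, length(w))
  stats::setNames(w / sum(w), strain_ids)
}

#' Spike an LBP strain into a composition
#'
#' Rescales the endogenous fractions by `1 - lbp_level` and adds the LBP
#' strain at `lbp_level`, mirroring a proportional spike-in of product DNA.
#'
#' @param composition Named fraction vector summing to 1.
#' @param lbp_level Spike-in fraction in \[0, 1\].
#' @param lbp_id Strain id of the spiked product strain.
#' @return Named fraction vector summing to 1, with `lbp_id` appended.
#' @examples
#' spike_lbp(c(A = 1), 0.3)
#' @export
spike_lbp <- function(composition, lbp_level, lbp_id = "sLBP") {
  if (length(lbp_level) != 1) stop_invalid("lbp_level must be a single value")
  assert_fraction(lbp_level, "lbp_level")
  assert_fraction(composition, "composition")
  if (lbp_id %in% names(composition)) {
    stop_invalid("lbp_id '", lbp_id, "' collides with an endogenous strain")
  }
  out <- c(composition * (1 - lbp_level), stats::setNames(lbp_level, lbp_id))
  out
}

#' Render a metagenotype from a strain composition
#'
#' Generates the observed reference/alternate allele counts of one sample. At
#' each site the expected alternate-allele fraction is the abundance-weighted
#' mean of the strains' alleles, and the alternate count is drawn
#' binomially at the sample's depth.
#'
#' @param composition Named fraction vector (strain id -> abundance).
#' @param genotypes Binary genotype matrix (strains x sites) containing every
#'   strain of `composition` as a row.
#' @param depth Nominal reads per site (>= 1).
#' @param seed Integer seed.
#' @param sample_id Optional sample identifier.
#' @param depth_mode `"fixed"` or `"poisson"` per-site depth.
#' @return A `metagenotype`: list with `sample_id` and integer vectors `ref`
#'   and `alt` of per-site allele counts.
#' @export
render_metagenotype <- function(composition, genotypes, depth, seed,
                                sample_id = NULL,
                                depth_mode = c("fixed", "poisson")) {
  depth_mode <- match.arg(depth_mode)
  if (depth < 1) stop_invalid("depth must be >= 1")
  missing <- setdiff(names(composition), rownames(genotypes))
  if (length(missing)) {
    stop_invalid("no genotype for strain(s): ", paste(missing, collapse = ", "))
  }
  G <- genotypes[names(composition), , drop = FALSE]
  p <- clip(as.vector(composition %*% G), 0, 1)
  set.seed(seed)
  d <- if (depth_mode == "fixed") rep(as.integer(depth), length(p)) else
    stats::rpois(length(p), depth)
  alt <- stats::rbinom(length(p), d, p)
  structure(list(sample_id = sample_id, ref = as.integer(d - alt),
                 alt = as.integer(alt)),
            class = "metagenotype")
}

#' @export
print.metagenotype <- function(x, ...) {
  cat("metagenotype", if (!is.null(x$sample_id)) x$sample_id else "",
      "-", length(x$alt), "sites, mean depth",
      round(mean(x$ref + x$alt), 2), "\n")
  invisible(x)
}

#' Simulate a full LBP-trial cohort
#'
#' Draws endogenous genotypes per the design, spikes one shared LBP strain
#' into every sample at the design's per-sample level, and renders the
#' metagenotype count matrices. All randomness descends from the design's
#' master seed through documented per-sample child seeds.
#'
#' @param design A [build_cohort_design()] result.
#' @param lbp_genotype Optional binary vector for the LBP strain; by default a
#'   genotype is drawn with `simulate_strain_genotypes` under the design seed.
#'   Pass the same vector across cohorts to share one product strain.
#' @param lbp_id Strain id for the spiked product strain.
#' @return An object of class `lbp_cohort`: `genotypes` (strains x sites 0/1
#'   matrix including the LBP strain), `composition` (samples x strains
#'   abundance matrix, rows summing to 1), `metagenotypes` (a
#'   [metagenotype_set()]), and the design's `samples` table.
#' @export
simulate_cohort <- function(design, lbp_genotype = NULL, lbp_id = "sLBP") {
  stopifnot(inherits(design, "cohort_design"))
  cfg <- design$config
  owner <- design$strain_owner
  n_endo <- length(owner)
  G <- simulate_strain_genotypes(n_endo + 1L, cfg$n_sites,
                                 seed = child_seed(cfg$seed, 1L),
                                 strain_ids = c(names(owner), lbp_id))
  if (!is.null(lbp_genotype)) {
    stopifnot(length(lbp_genotype) == cfg$n_sites,
              all(lbp_genotype %in% c(0, 1)))
    G[lbp_id, ] <- as.integer(lbp_genotype)
  }
  smp <- design$samples
  n <- nrow(smp)
  comp <- matrix(0, n, n_endo + 1L,
                 dimnames = list(smp$sample_id, rownames(G)))
  ref <- matrix(0L, n, cfg$n_sites)
  alt <- matrix(0L, n, cfg$n_sites)
  for (r in seq_len(n)) {
    cs <- child_seed(cfg$seed, smp$participant[r], smp$sample_idx[r])
    ids <- names(owner)[owner == smp$participant[r]]
    endo <- draw_sample_composition(ids, seed = cs, alpha = cfg$alpha)
    full <- spike_lbp(endo, smp$lbp_level[r], lbp_id = lbp_id)
    comp[r, names(full)] <- full
    mg <- render_metagenotype(full, G, smp$depth[r], seed = cs + 1L,
                              sample_id = smp$sample_id[r],
                              depth_mode = cfg$depth_mode)
    ref[r, ] <- mg$ref
    alt[r, ] <- mg$alt
  }
  rownames(ref) <- rownames(alt) <- smp$sample_id
  structure(list(
    genotypes = G,
    composition = comp,
    metagenotypes = metagenotype_set(ref, alt),
    samples = smp,
    lbp_id = lbp_id
  ), class = "lbp_cohort")
}

#' @export
print.lbp_cohort <- function(x, ...) {
  cat("lbp_cohort:", nrow(x$composition), "samples,",
      nrow(x$genotypes), "true strains (incl.", x$lbp_id, "),",
      ncol(x$genotypes), "sites\n")
  invisible(x)
}
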