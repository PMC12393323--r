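#' Study configuration: replicate cohorts plus evaluation thresholds
#'
#' Bundles the cohort design, the fit configuration and the evaluation
#' thresholds used across a multi-cohort simulation study. Defaults are the
#' study conditions: 10 cohorts, the default [cohort_config()], K = 300
#' inferred strains, product-strain merge at 0.95, genotype match at 0.9,
#' duplicate collapse at 0.99, presence at 10%, false-positive bound 1%,
#' false-negative bound 5%.
#'
#' @param n_cohorts Number of independent cohorts.
#' @param cohort A [cohort_config()] template (its seed is replaced by a
#'   per-cohort child of `seed`).
#' @param fit A [fit_config()].
#' @param merge_threshold,match_threshold,collapse_threshold Jaccard
#'   thresholds for product-strain merging, genotype matching, and duplicate
#'   collapsing.
#' @param presence_threshold,fp_threshold,fn_threshold Detection rule
#'   constants.
#' @param seed Master seed; cohort c uses `child_seed(seed, c)`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_cohorts = 10, cohort = cohort_config(),
                         fit = fit_config(),
                         merge_threshold = 0.95, match_threshold = 0.9,
                         collapse_threshold = 0.99,
                         presence_threshold = 0.10, fp_threshold = 0.01,
                         fn_threshold = 0.05, seed = 1) {
  assert_count(n_cohorts, "n_cohorts")
  for (th in c(merge_threshold, match_threshold, collapse_threshold,
               presence_threshold, fp_threshold, fn_threshold)) {
    if (th <= 0 || th > 1) stop_invalid("thresholds must be in (0, 1]")
  }
  structure(list(n_cohorts = as.integer(n_cohorts), cohort = cohort,
                 fit = fit, merge_threshold = merge_threshold,
                 match_threshold = match_threshold,
                 collapse_threshold = collapse_threshold,
                 presence_threshold = presence_threshold,
                 fp_threshold = fp_threshold, fn_threshold = fn_threshold,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Evaluate an inference result against cohort truth
#'
#' Runs the full evaluation battery of one cohort: product-strain
#' identification (after >= merge-threshold merging), per-sample detection
#' calls and abundance RMSE by depth, duplicate collapsing, true-vs-inferred
#' match tables, cumulative-abundance correlation of matched endogenous
#' strains, effective number of strains, and self-versus-other weighted
#' UniFrac dissimilarity on a shared genotype-distance tree.
#'
#' @param cohort An [simulate_cohort()] truth object.
#' @param result A `strain_inference` for the cohort's samples.
#' @param config A [study_config()] supplying thresholds.
#' @return List of class `cohort_evaluation`: `lbp` (id, similarity,
#'   per-sample abundance), `detection` (per-sample calls), `rmse_by_depth`,
#'   `match_table`, `cumulative` (pairs + Pearson r), `diversity` (per-sample
#'   true/inferred ENS), `unifrac` (self-vs-other table), `collapsed`
#'   (the collapsed inference).
#' @export
evaluate_cohort <- function(cohort, result, config = study_config()) {
  stopifnot(inherits(cohort, "lbp_cohort"),
            inherits(result, "strain_inference"))
  lbp_geno <- cohort$genotypes[cohort$lbp_id, ]
  lbp <- identify_lbp_strain(result, lbp_geno,
                             merge_threshold = config$merge_threshold)
  true_lbp <- cohort$composition[, cohort$lbp_id]
  detection <- classify_detection(true_lbp, lbp$abundance,
                                  fp_threshold = config$fp_threshold,
                                  fn_threshold = config$fn_threshold,
                                  presence_threshold =
                                    config$presence_threshold)
  detection <- cbind(sample_id = rownames(cohort$composition), detection,
                     depth = cohort$samples$depth)
  rmse <- lbp_abundance_rmse(true_lbp, lbp$abundance, cohort$samples$depth)

  collapsed <- collapse_duplicates(result, config$collapse_threshold)
  mt <- match_table(cohort$genotypes, collapsed$genotypes)
  cum <- cumulative_abundance_correlation(
    cohort$genotypes, cohort$composition, collapsed,
    match_threshold = config$match_threshold, exclude = cohort$lbp_id)

  ens <- data.frame(
    sample_id = rownames(cohort$composition),
    depth = cohort$samples$depth,
    ens_true = apply(cohort$composition, 1, effective_number_of_strains),
    ens_inferred = apply(collapsed$abundances, 1,
                         effective_number_of_strains))

  # one tree over the union of true and collapsed inferred strains
  Gi <- discretize_genotype(collapsed$genotypes)
  rownames(Gi) <- paste0("inf_", rownames(Gi))
  union_G <- rbind(cohort$genotypes, Gi)
  tree <- build_strain_tree(union_G)
  inf_comp <- collapsed$abundances
  colnames(inf_comp) <- paste0("inf_", colnames(collapsed$abundances))
  uf <- self_vs_other_dissimilarity(cohort$composition, inf_comp, tree,
                                    cohort$samples$lbp_level)

  structure(list(lbp = lbp[c("strain_id", "similarity", "abundance")],
                 detection = detection, rmse_by_depth = rmse,
                 match_table = mt, cumulative = cum, diversity = ens,
                 unifrac = uf, collapsed = collapsed),
            class = "cohort_evaluation")
}

#' Pooled false-positive / false-negative rates from detection tables
#'
#' FP rate: among samples with true spike-in 0, the fraction with inferred
#' abundance above the FP bound. FN rate: among samples with true spike-in
#' 10%, the fraction inferred below the FN bound.
#'
#' @param detection A detection table or rbind of several (`label`,
#'   `true_lbp_abundance` columns).
#' @return Named vector: `fp_rate`, `fn_rate`, `n_true_zero`, `n_true_ten`.
#' @export
detection_rates <- function(detection) {
  eq <- function(x, v) abs(x - v) < 1e-9
  zero <- detection[eq(detection$true_lbp_abundance, 0), ]
  ten <- detection[eq(detection$true_lbp_abundance, 0.10), ]
  c(fp_rate = if (nrow(zero)) mean(zero$label == "FP") else NA_real_,
    fn_rate = if (nrow(ten)) mean(ten$label == "FN") else NA_real_,
    n_true_zero = nrow(zero), n_true_ten = nrow(ten))
}

#' Run the full simulation study
#'
#' For each of `config$n_cohorts` cohorts: simulate truth (genotypes,
#' compositions, metagenotypes) under a per-cohort child seed with one shared
#' product-strain genotype, deconvolve with the mixture engine at K = 3x the
#' number of true strains (capped by `config$fit$K`), evaluate, and
#' optionally write all truth/inference/evaluation tables under
#' `out_dir/cohort_<c>/`. A failing cohort is reported and skipped.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory for TSV/Newick artifacts.
#' @return List of class `study_report`: `cohorts` (per-cohort evaluations),
#'   `summary` (per-cohort product-strain similarity, max RMSE, Pearson r),
#'   `pooled_detection` (rates pooled over cohorts), `failures`.
#' @export
run_simulation_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  lbp_geno <- simulate_strain_genotypes(
    1, config$cohort$n_sites, seed = child_seed(config$seed, 0L, 99L))[1, ]
  evals <- vector("list", config$n_cohorts)
  failures <- character(0)
  all_detection <- NULL
  rows <- NULL
  for (c in seq_len(config$n_cohorts)) {
    res <- tryCatch({
      ccfg <- config$cohort
      ccfg$seed <- child_seed(config$seed, c)
      design <- build_cohort_design(ccfg)
      cohort <- simulate_cohort(design, lbp_genotype = lbp_geno)
      fcfg <- config$fit
      fcfg$K <- min(fcfg$K, 3L * nrow(cohort$genotypes))
      fcfg$seed <- child_seed(config$seed, c, 1L)
      fit <- fit_mixture(cohort$metagenotypes, fcfg)
      ev <- evaluate_cohort(cohort, fit, config)
      if (!is.null(out_dir)) {
        cdir <- file.path(out_dir, sprintf("cohort_%02d", c))
        write_cohort_tables(cohort, fit, ev, cdir)
      }
      list(cohort = c, eval = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("cohort ", c, " failed: ", conditionMessage(res))
      failures <- c(failures, sprintf("cohort_%02d: %s", c,
                                      conditionMessage(res)))
      next
    }
    ev <- res$eval
    evals[[c]] <- ev
    all_detection <- rbind(all_detection, ev$detection)
    rows <- rbind(rows, data.frame(
      cohort = c,
      lbp_similarity = ev$lbp$similarity,
      max_rmse = max(ev$rmse_by_depth),
      pearson_r = ev$cumulative$r,
      n_matched = if (is.null(ev$cumulative$pairs)) 0L else
        nrow(ev$cumulative$pairs)))
  }
  pooled <- if (is.null(all_detection)) NULL else
    detection_rates(all_detection)
  rep <- structure(list(cohorts = evals, summary = rows,
                        pooled_detection = pooled, failures = failures,
                        config = config),
                   class = "study_report")
  if (!is.null(out_dir)) {
    utils::write.table(rows, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(pooled)) {
      utils::write.table(data.frame(metric = names(pooled),
                                    value = unname(pooled)),
                         file.path(out_dir, "pooled_detection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  rep
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", length(Filter(Negate(is.null), x$cohorts)),
      "cohort(s) evaluated\n")
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$pooled_detection)) {
    cat("pooled FP rate:", signif(x$pooled_detection["fp_rate"], 4),
        " FN rate:", signif(x$pooled_detection["fn_rate"], 4), "\n")
  }
  invisible(x)
}

write_cohort_tables <- function(cohort, fit, ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(cohort$genotypes, file.path(dir, "true_genotypes.tsv"))
  write_composition_tsv(cohort$composition,
                        file.path(dir, "true_composition.tsv"))
  write_metagenotype_tsv(cohort$metagenotypes,
                         file.path(dir, "metagenotype.tsv"))
  write_inference(fit, dir)
  utils::write.table(ev$detection, file.path(dir, "detection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$match_table, file.path(dir, "match_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(depth = names(ev$rmse_by_depth),
                                rmse = unname(ev$rmse_by_depth)),
                     file.path(dir, "rmse_by_depth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ev$cumulative$pairs)) {
    utils::write.table(ev$cumulative$pairs,
                       file.path(dir, "cumulative_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(ev$diversity, file.path(dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$unifrac, file.path(dir, "unifrac.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Gi <- discretize_genotype(ev$collapsed$genotypes)
  rownames(Gi) <- paste0("inf_", rownames(Gi))
  tree <- build_strain_tree(rbind(cohort$genotypes, Gi))
  ape::write.tree(tree, file.path(dir, "strain_tree.nwk"))
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror [study_config()]; `cohort:` and `fit:` sub-maps
#' mirror [cohort_config()] and [fit_config()].
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  fit <- do.call(fit_config, y$fit %||% list())
  args <- y[setdiff(names(y), c("cohort", "fit"))]
  do.call(study_config, c(list(cohort = cohort, fit = fit), args))
}
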