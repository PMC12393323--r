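test_that("a pure noiseless sample is recovered exactly", {
  G <- simulate_strain_genotypes(1, 120, seed = 5, strain_ids = "S")
  mg <- render_metagenotype(c(S = 1), G, depth = 30, seed = 6, sample_id = "x")
  fit <- fit_mixture(list(mg), fit_config(K = 3, seed = 1))
  disc <- discretize_genotype(fit$genotypes)
  hits <- apply(disc, 1, function(g) jaccard_similarity(g, G[1, ]))
  best <- which.max(hits)
  expect_equal(unname(hits[best]), 1)
  expect_gte(fit$abundances[1, best], 0.999)
})

test_that("two pure samples yield both strains at similarity 1", {
  G <- simulate_strain_genotypes(2, 150, seed = 8)
  mg1 <- render_metagenotype(c(strain_001 = 1), G, 30, seed = 1, sample_id = "a")
  mg2 <- render_metagenotype(c(strain_002 = 1), G, 30, seed = 2, sample_id = "b")
  fit <- fit_mixture(list(mg1, mg2), fit_config(K = 3, seed = 1))
  disc <- discretize_genotype(fit$genotypes)
  j1 <- max(apply(disc, 1, jaccard_similarity, b = G[1, ]))
  j2 <- max(apply(disc, 1, jaccard_similarity, b = G[2, ]))
  expect_equal(j1, 1)
  expect_equal(j2, 1)
})

test_that("abundance rows are a simplex and the fit is deterministic", {
  co <- tiny_cohort(n_participants = 3, n_sites = 200, seed = 4)
  cfg <- fit_config(K = 3 * nrow(co$genotypes), seed = 9)
  fit <- fit_mixture(co$metagenotypes, cfg)
  expect_true(all(abs(rowSums(fit$abundances) - 1) < 1e-6))
  expect_true(all(fit$genotypes >= 0 & fit$genotypes <= 1))
  fit2 <- fit_mixture(co$metagenotypes, cfg)
  expect_identical(fit$genotypes, fit2$genotypes)
  expect_identical(fit$abundances, fit2$abundances)
})

test_that("the polish-phase penalized objective never increases", {
  co <- tiny_cohort(n_participants = 3, n_sites = 150, seed = 12)
  fit <- fit_mixture(co$metagenotypes,
                     fit_config(K = 3 * nrow(co$genotypes), seed = 2))
  tr <- fit$objective
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
})

test_that("strains recovered on a depth-30 cohort cover abundant truth", {
  co <- tiny_cohort(n_participants = 5, n_sites = 300, depths = 30, seed = 21)
  fit <- fit_mixture(co$metagenotypes,
                     fit_config(K = 3 * nrow(co$genotypes), seed = 21))
  coll <- collapse_duplicates(fit, 0.99)
  disc <- discretize_genotype(coll$genotypes)
  cum <- colSums(co$composition)
  best <- vapply(rownames(co$genotypes), function(s) {
    max(apply(disc, 1, jaccard_similarity, b = co$genotypes[s, ]))
  }, numeric(1))
  # almost all strains with cumulative abundance above 1 have a close match,
  # and the clearly dominant ones always do
  abundant <- cum > 1
  expect_gte(mean(best[abundant] > 0.9), 0.75)
  expect_true(all(best[cum > 1.5] > 0.9))
  # matched strains are the abundant ones overall
  expect_gt(median(cum[best > 0.9]), median(cum[best <= 0.9]))
})

test_that("label permutation leaves evaluation metrics unchanged", {
  co <- tiny_cohort(n_participants = 3, n_sites = 120, seed = 5)
  res <- oracle_inference(co)
  perm <- rev(seq_len(nrow(res$genotypes)))
  res_p <- make_inference(res$genotypes[perm, ], res$abundances[, perm])
  l1 <- identify_lbp_strain(res, co$genotypes[co$lbp_id, ])
  l2 <- identify_lbp_strain(res_p, co$genotypes[co$lbp_id, ])
  expect_equal(l1$similarity, l2$similarity)
  expect_equal(unname(l1$abundance), unname(l2$abundance))
  c1 <- cumulative_abundance_correlation(co$genotypes, co$composition, res)
  c2 <- cumulative_abundance_correlation(co$genotypes, co$composition, res_p)
  expect_equal(c1$r, c2$r)
})

test_that("reconstruction error measures mean absolute residual", {
  G <- rbind(s1 = c(1, 0, 1, 0), s2 = c(0, 1, 0, 1))
  mg <- metagenotype_set(ref = matrix(c(0L, 4L, 0L, 4L), 1),
                         alt = matrix(c(4L, 0L, 4L, 0L), 1))
  perfect <- make_inference(G, matrix(c(1, 0), 1,
                                      dimnames = list(NULL, rownames(G))))
  expect_equal(unname(reconstruction_error(mg, perfect)), 0)
  flipped <- make_inference(G, matrix(c(0, 1), 1,
                                      dimnames = list(NULL, rownames(G))))
  expect_equal(unname(reconstruction_error(mg, flipped)), 1)
  # hand arithmetic: observed (0.5, 0), reconstructed (0.25, 0)
  mg2 <- metagenotype_set(ref = matrix(c(2L, 4L), 1),
                          alt = matrix(c(2L, 0L), 1))
  half <- make_inference(rbind(a = c(1, 0), b = c(0, 0)),
                         matrix(c(0.25, 0.75), 1,
                                dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(reconstruction_error(mg2, half)), 0.125)
})

test_that("reconstruction error of the truth vanishes at high depth", {
  cfg <- cohort_config(n_participants = 2, n_sites = 150, depths = 1000,
                       seed = 3)
  co <- simulate_cohort(build_cohort_design(cfg))
  err <- reconstruction_error(co$metagenotypes, oracle_inference(co))
  expect_lt(max(err), 0.02)
})

test_that("depth dispersion summarizes per-site coverage", {
  co <- tiny_cohort(n_participants = 2, n_sites = 50, depths = 20)
  dd <- depth_dispersion(co$metagenotypes, sample = 1)
  expect_equal(unname(dd["median"]), 20)
  expect_equal(unname(dd["iqr"]), 0)
  mg <- structure(list(sample_id = "m", ref = c(0L, 1L, 2L, 3L, 4L),
                       alt = c(1L, 1L, 1L, 1L, 1L)), class = "metagenotype")
  expect_equal(unname(depth_dispersion(mg)["median"]), 3)
  # Poisson coverage: median near the nominal mean
  cfgp <- cohort_config(n_participants = 1, samples_per_participant = 1,
                        n_sites = 10000, depths = 10, depth_mode = "poisson",
                        seed = 8)
  cop <- simulate_cohort(build_cohort_design(cfgp))
  ddp <- depth_dispersion(cop$metagenotypes, sample = 1)
  expect_gte(unname(ddp["median"]), 9)
  expect_lte(unname(ddp["median"]), 11)
  expect_gt(unname(ddp["iqr"]), 0)
})

test_that("inference tables round-trip and invalid tables are rejected", {
  co <- tiny_cohort(n_participants = 2, n_sites = 60)
  res <- oracle_inference(co)
  res$per_sample_error <- reconstruction_error(co$metagenotypes, res)
  dir <- withr::local_tempdir()
  write_inference(res, dir)
  back <- load_external_inference(file.path(dir, "inferred_genotypes.tsv"),
                                  file.path(dir, "inferred_abundances.tsv"))
  expect_equal(back$genotypes, res$genotypes, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(unname(back$abundances), unname(res$abundances),
               tolerance = 1e-9)

  # abundance row far from 1 -> error naming the sample
  ab_bad <- res$abundances
  ab_bad[2, ] <- ab_bad[2, ] * 0.9
  abf <- file.path(dir, "bad_ab.tsv")
  utils::write.table(data.frame(sample_id = rownames(ab_bad), ab_bad,
                                check.names = FALSE),
                     abf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_external_inference(
    file.path(dir, "inferred_genotypes.tsv"), abf), "sums to")

  # genotype entry outside [0, 1] -> error
  g_bad <- res$genotypes
  g_bad[1, 1] <- 1.2
  gbf <- file.path(dir, "bad_g.tsv")
  write_genotypes_tsv(g_bad, gbf)
  expect_error(load_external_inference(
    gbf, file.path(dir, "inferred_abundances.tsv")), "outside")
})

test_that("inconsistent site counts are rejected", {
  m1 <- structure(list(sample_id = "a", ref = c(1L, 1L), alt = c(0L, 1L)),
                  class = "metagenotype")
  m2 <- structure(list(sample_id = "b", ref = c(1L, 1L, 1L),
                       alt = c(0L, 1L, 0L)), class = "metagenotype")
  expect_error(as_metagenotype_set(list(m1, m2)), "site count")
})
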