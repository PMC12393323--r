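test_that("simulated genotypes are distinct binary vectors and seed-stable", {
  g <- simulate_strain_genotypes(5, 200, seed = 7)
  expect_equal(dim(g), c(5, 200))
  expect_true(all(g %in% c(0L, 1L)))
  expect_equal(anyDuplicated(apply(g, 1, paste, collapse = "")), 0L)
  expect_identical(g, simulate_strain_genotypes(5, 200, seed = 7))
  expect_false(identical(g, simulate_strain_genotypes(5, 200, seed = 8)))

  # with one site only two distinct genotypes exist
  g2 <- simulate_strain_genotypes(2, 1, seed = 3)
  expect_setequal(as.vector(g2), c(0L, 1L))

  expect_error(simulate_strain_genotypes(0, 10, seed = 1), "n_strains")
  expect_error(simulate_strain_genotypes(3, 0, seed = 1), "n_sites")
  expect_error(simulate_strain_genotypes(3, 1, seed = 1), "distinct")
})

test_that("default cohort design matches the trial layout", {
  design <- build_cohort_design(cohort_config(seed = 5))
  expect_equal(nrow(design$samples), 400)
  expect_equal(length(unique(design$samples$participant)), 100)
  expect_true(all(table(design$samples$participant) == 4))
  expect_true(all(design$samples$depth %in% c(5, 10, 20, 30)))
  expect_true(all(design$samples$lbp_level %in% seq(0, 1, 0.1)))
  # depths balanced within every participant
  bydep <- table(design$samples$participant, design$samples$depth)
  expect_true(all(bydep == 1))
  # endogenous strains partition across participants (no sharing)
  expect_equal(anyDuplicated(names(design$strain_owner)), 0L)
  counts <- table(design$strain_owner)
  expect_true(all(counts >= 1 & counts <= 4))
  expect_equal(length(design$strain_owner), sum(counts))
})

test_that("minimal design and invalid configs behave as specified", {
  d <- build_cohort_design(cohort_config(n_participants = 1,
                                         samples_per_participant = 1,
                                         n_sites = 10, depths = 5,
                                         lbp_levels = 0, seed = 1))
  expect_equal(nrow(d$samples), 1)
  expect_equal(d$samples$lbp_level, 0)
  expect_error(cohort_config(depths = numeric(0)), "depths")
  expect_error(cohort_config(lbp_levels = numeric(0)), "lbp_levels")
})

test_that("sample compositions are seeded simplex draws", {
  one <- draw_sample_composition("A", seed = 1)
  expect_equal(unname(one), 1)
  four <- draw_sample_composition(LETTERS[1:4], seed = 9)
  expect_equal(sum(four), 1, tolerance = 1e-9)
  expect_true(all(four >= 0))
  expect_identical(four, draw_sample_composition(LETTERS[1:4], seed = 9))
  expect_false(identical(four, draw_sample_composition(LETTERS[1:4], seed = 10)))
  expect_error(draw_sample_composition(character(0), seed = 1), "strain")
})

test_that("spiking rescales endogenous mass proportionally", {
  expect_equal(spike_lbp(c(A = 1), 0.3),
               c(A = 0.7, sLBP = 0.3))
  expect_equal(spike_lbp(c(A = 0.6, B = 0.4), 0),
               c(A = 0.6, B = 0.4, sLBP = 0))
  full <- spike_lbp(c(A = 1), 1)
  expect_equal(unname(full["sLBP"]), 1)
  expect_equal(unname(full["A"]), 0)
  expect_equal(sum(spike_lbp(c(A = 0.25, B = 0.75), 0.45)), 1)
  expect_error(spike_lbp(c(A = 1), 1.2), "lbp_level")
  expect_error(spike_lbp(c(sLBP = 1), 0.5), "collides")
})

test_that("rendered metagenotypes follow the binomial read model", {
  G <- rbind(all1 = rep(1L, 50), all0 = rep(0L, 50))
  mg <- render_metagenotype(c(all1 = 1), G, depth = 30, seed = 1)
  expect_true(all(mg$alt == 30L))
  expect_true(all(mg$ref == 0L))
  mg2 <- render_metagenotype(c(all1 = 0.5, all0 = 0.5), G, depth = 20, seed = 2)
  expect_true(all(mg2$ref + mg2$alt == 20L))

  # Monte-Carlo: mean alt fraction at a 50/50 site ~ Binomial(20, 0.5)
  draws <- vapply(1:2000, function(s) {
    render_metagenotype(c(all1 = 0.5, all0 = 0.5), G[, 1:2], 20, seed = s)$alt[1]
  }, numeric(1))
  se <- sqrt(0.25 / (2000 * 20))
  expect_lt(abs(mean(draws / 20) - 0.5), 3 * se)

  expect_error(render_metagenotype(c(X = 1), G, 30, seed = 1), "genotype")
})

test_that("alt fraction converges to the allele at extreme depth", {
  G <- rbind(s = as.integer(runif(100) > 0.5))
  mg <- render_metagenotype(c(s = 1), G, depth = 10000, seed = 4)
  expect_lt(max(abs(mg$alt / 10000 - G[1, ])), 0.02)
})

test_that("full cohort simulation is reproducible and consistent", {
  co <- tiny_cohort(n_participants = 4, n_sites = 60)
  co2 <- tiny_cohort(n_participants = 4, n_sites = 60)
  expect_identical(co$metagenotypes$alt, co2$metagenotypes$alt)
  expect_identical(co$genotypes, co2$genotypes)
  # compositions on the simplex; counts conserve depth
  expect_true(all(abs(rowSums(co$composition) - 1) < 1e-9))
  d <- co$metagenotypes$ref + co$metagenotypes$alt
  expect_true(all(d == co$samples$depth))
  # spike level matches the design
  expect_equal(unname(co$composition[, co$lbp_id]), co$samples$lbp_level)
  # a participant's samples use only that participant's strains
  endo <- co$composition[, setdiff(colnames(co$composition), co$lbp_id)]
  design_cfg <- attr(co, "config")
  for (p in unique(co$samples$participant)) {
    rows <- co$samples$participant == p
    used <- colnames(endo)[colSums(endo[rows, , drop = FALSE]) > 0]
    other <- colnames(endo)[colSums(endo[!rows, , drop = FALSE]) > 0]
    expect_length(intersect(used, other), 0)
  }
})

test_that("a shared product genotype can be injected across cohorts", {
  lbp <- simulate_strain_genotypes(1, 60, seed = 99)[1, ]
  co1 <- simulate_cohort(build_cohort_design(
    cohort_config(n_participants = 2, n_sites = 60, seed = 1)), lbp_genotype = lbp)
  co2 <- simulate_cohort(build_cohort_design(
    cohort_config(n_participants = 2, n_sites = 60, seed = 2)), lbp_genotype = lbp)
  expect_equal(co1$genotypes["sLBP", ], co2$genotypes["sLBP", ])
  expect_false(identical(co1$genotypes, co2$genotypes))
})

test_that("metagenotype TSV round-trips", {
  co <- tiny_cohort(n_participants = 2, n_sites = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metagenotype_tsv(co$metagenotypes, path)
  back <- read_metagenotype_tsv(path)
  expect_equal(back$alt, co$metagenotypes$alt)
  expect_equal(back$ref, co$metagenotypes$ref)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(co$genotypes, gpath)
  expect_equal(read_genotypes_tsv(gpath), co$genotypes,
               ignore_attr = TRUE)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_composition_tsv(co$composition, cpath)
  back_c <- read_composition_tsv(cpath)
  expect_equal(back_c[rownames(co$composition),
                      colnames(co$composition)[colSums(co$composition) > 0]],
               co$composition[, colSums(co$composition) > 0])
})
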