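# Small cohorts and handmade objects shared across test files.

tiny_cohort <- function(n_participants = 6, n_sites = 400,
                        depths = c(5, 10, 20, 30), seed = 11) {
  cfg <- cohort_config(n_participants = n_participants,
                       n_sites = n_sites, depths = depths, seed = seed)
  simulate_cohort(build_cohort_design(cfg))
}

# An inference object built directly from a truth cohort (oracle inference).
oracle_inference <- function(cohort) {
  strain_inference(genotypes = cohort$genotypes,
                   abundances = cohort$composition)
}

make_inference <- function(genotypes, abundances) {
  strain_inference(genotypes = genotypes, abundances = abundances)
}

# Brute-force weighted UniFrac: enumerate every branch's descendant tips via
# phangorn, independently of the package's postorder accumulation.
brute_unifrac <- function(comp_a, comp_b, tree) {
  pa <- comp_a[tree$tip.label]; pa[is.na(pa)] <- 0; pa <- pa / sum(pa)
  pb <- comp_b[tree$tip.label]; pb[is.na(pb)] <- 0; pb <- pb / sum(pb)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    tips <- unlist(phangorn::Descendants(tree, node, type = "tips"))
    total <- total + tree$edge.length[e] * abs(sum(pa[tips]) - sum(pb[tips]))
  }
  total
}
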