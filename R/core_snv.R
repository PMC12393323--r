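#' Select core biallelic SNV sites from a genome panel
#'
#' Applies the database-construction filters to a genomes x sites allele
#' matrix: a site is retained when it is callable (non-missing) in at least
#' `ceil(core_fraction * n_genomes)` genomes ("core") and each of its two
#' alleles is observed in at least `min_allele_genomes` genomes (a genome
#' count, not a rounded percentage). With the default 95% core presence a
#' panel of 137 genomes yields a cutoff of 131 genomes, and the default
#' minor-allele cutoff is 2 genomes. Sites with more than two observed
#' alleles are excluded as non-biallelic.
#'
#' @param matrix Genomes x sites matrix of allele codes: 0 (reference),
#'   1 (alternate), NA (missing). Values other than 0/1/NA mark additional
#'   alleles and disqualify the site.
#' @param core_fraction Minimum fraction of genomes with a non-missing call.
#' @param min_allele_genomes Minimum genomes carrying each allele.
#' @return Integer vector of retained site indices (1-based).
#' @export
select_core_biallelic_sites <- function(matrix, core_fraction = 0.95,
                                        min_allele_genomes = 2) {
  m <- as.matrix(matrix)
  if (nrow(m) < 1 || ncol(m) < 1) stop_invalid("empty allele matrix")
  if (core_fraction <= 0 || core_fraction > 1) {
    stop_invalid("core_fraction must be in (0, 1]")
  }
  assert_count(min_allele_genomes, "min_allele_genomes")
  cutoff <- core_presence_cutoff(nrow(m), core_fraction)
  present <- colSums(!is.na(m))
  n_ref <- colSums(m == 0, na.rm = TRUE)
  n_alt <- colSums(m == 1, na.rm = TRUE)
  n_other <- present - n_ref - n_alt
  keep <- present >= cutoff &
    n_other == 0 &
    n_ref >= min_allele_genomes &
    n_alt >= min_allele_genomes
  which(keep)
}

#' @rdname select_core_biallelic_sites
#' @param n_genomes Panel size.
#' @export
core_presence_cutoff <- function(n_genomes, core_fraction = 0.95) {
  as.integer(ceiling(core_fraction * n_genomes))
}

#' Read / write allele matrices and site lists as TSV
#'
#' The allele matrix TSV has genomes in rows (first column `genome_id`) and
#' sites in columns, values 0/1/NA.
#'
#' @param path File path.
#' @export
read_allele_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "genome_id") stop_invalid("first column must be genome_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  m
}

#' @rdname read_allele_matrix_tsv
#' @param sites Integer vector of selected site indices.
#' @export
write_site_list_tsv <- function(sites, path) {
  utils::write.table(data.frame(site_index = sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
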