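#' Metagenotype count matrices for a set of samples
#'
#' Container for per-sample, per-site reference and alternate allele counts.
#'
#' @param ref,alt Integer matrices (samples x sites) of allele counts, with
#'   matching dimensions and sample ids as row names.
#' @return An object of class `metagenotype_set`.
#' @export
metagenotype_set <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt))) {
    stop_invalid("ref and alt must have identical dimensions")
  }
  if (any(ref < 0) || any(alt < 0)) stop_invalid("counts must be >= 0")
  structure(list(ref = ref, alt = alt,
                 sample_ids = rownames(ref) %||%
                   sprintf("sample_%03d", seq_len(nrow(ref)))),
            class = "metagenotype_set")
}

#' @export
print.metagenotype_set <- function(x, ...) {
  cat("metagenotype_set:", nrow(x$alt), "samples x", ncol(x$alt), "sites\n")
  invisible(x)
}

#' Coerce metagenotypes to a metagenotype_set
#'
#' @param x A `metagenotype_set`, a single `metagenotype`, or a list of
#'   `metagenotype` objects with equal site counts.
#' @return A `metagenotype_set`.
#' @export
as_metagenotype_set <- function(x) {
  if (inherits(x, "metagenotype_set")) return(x)
  if (inherits(x, "metagenotype")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "metagenotype"))) {
    stop_invalid("expected a metagenotype_set or list of metagenotype objects")
  }
  ns <- vapply(x, function(m) length(m$alt), integer(1))
  if (length(unique(ns)) != 1) {
    stop_invalid("samples disagree on site count: ",
                 paste(unique(ns), collapse = ", "))
  }
  ref <- do.call(rbind, lapply(x, `[[`, "ref"))
  alt <- do.call(rbind, lapply(x, `[[`, "alt"))
  ids <- vapply(seq_along(x), function(i) {
    x[[i]]$sample_id %||% sprintf("sample_%03d", i)
  }, character(1))
  rownames(ref) <- rownames(alt) <- ids
  metagenotype_set(ref, alt)
}

#' Per-site depth spread of a sample
#'
#' Order statistics of the per-site total counts (ref + alt) of one sample;
#' used to diagnose whether high metagenotype error tracks uneven or low
#' coverage.
#'
#' @param metagenotype A `metagenotype` (or a `metagenotype_set` plus
#'   `sample`).
#' @param sample Sample id or index when a set is given.
#' @return Named numeric vector: `median`, `iqr`, `q25`, `q75`, `mean`.
#' @export
depth_dispersion <- function(metagenotype, sample = NULL) {
  if (inherits(metagenotype, "metagenotype_set")) {
    if (is.null(sample)) stop_invalid("give a sample id/index for a set")
    d <- metagenotype$ref[sample, ] + metagenotype$alt[sample, ]
  } else if (inherits(metagenotype, "metagenotype")) {
    d <- metagenotype$ref + metagenotype$alt
  } else {
    stop_invalid("expected a metagenotype")
  }
  if (length(d) == 0) stop_invalid("no sites")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1], q25 = q[1], q75 = q[3], mean = mean(d))
}

#' Write / read metagenotype counts as TSV
#'
#' Long format: `sample_id`, `site_index` (0-based), `ref_count`, `alt_count`.
#'
#' @param x A `metagenotype_set` (or coercible).
#' @param path Output file.
#' @return `write_metagenotype_tsv` returns `path` invisibly;
#'   `read_metagenotype_tsv` returns a `metagenotype_set`.
#' @export
write_metagenotype_tsv <- function(x, path) {
  x <- as_metagenotype_set(x)
  n <- nrow(x$alt); S <- ncol(x$alt)
  df <- data.frame(
    sample_id = rep(x$sample_ids, each = S),
    site_index = rep(0:(S - 1), n),
    ref_count = as.vector(t(x$ref)),
    alt_count = as.vector(t(x$alt))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metagenotype_tsv
#' @export
read_metagenotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_index", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop_invalid("metagenotype TSV must have columns: ",
                 paste(need, collapse = ", "))
  }
  ids <- unique(df$sample_id)
  sites <- sort(unique(df$site_index))
  S <- length(sites)
  ref <- matrix(0L, length(ids), S, dimnames = list(ids, NULL))
  alt <- ref
  idx <- cbind(match(df$sample_id, ids), match(df$site_index, sites))
  ref[idx] <- as.integer(df$ref_count)
  alt[idx] <- as.integer(df$alt_count)
  metagenotype_set(ref, alt)
}

#' Write / read binary genotype matrices as TSV
#'
#' Rows are strains (first column `strain_id`), remaining columns are sites
#' with 0/1 (or fractional, for inferred genotypes) values.
#'
#' @param genotypes Matrix with strain row names.
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(strain_id = rownames(genotypes),
                   genotypes, check.names = FALSE)
  colnames(df) <- c("strain_id", sprintf("site_%d", seq_len(ncol(genotypes)) - 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "strain_id") stop_invalid("first column must be strain_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$strain_id
  colnames(m) <- NULL
  m
}

#' Write / read per-sample strain compositions as TSV
#'
#' Long format: `sample_id`, `strain_id`, `abundance`.
#'
#' @param composition Samples x strains abundance matrix with dimnames.
#' @param path File path.
#' @param drop_zero Omit zero-abundance entries (default TRUE).
#' @export
write_composition_tsv <- function(composition, path, drop_zero = TRUE) {
  df <- data.frame(
    sample_id = rep(rownames(composition), ncol(composition)),
    strain_id = rep(colnames(composition), each = nrow(composition)),
    abundance = as.vector(composition)
  )
  if (drop_zero) df <- df[df$abundance > 0, ]
  df <- df[order(df$sample_id, df$strain_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$sample_id); st <- unique(df$strain_id)
  m <- matrix(0, length(ids), length(st), dimnames = list(ids, st))
  m[cbind(match(df$sample_id, ids), match(df$strain_id, st))] <- df$abundance
  m
}
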