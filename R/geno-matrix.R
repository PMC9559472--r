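#' Genotype matrix container
#'
#' A `geno_matrix` bundles an ordered set of samples, a variant table and an
#' integer allele-dosage matrix (samples in rows, variants in columns). Dosage
#' is the count of alternate alleles per diploid genotype: 0, 1 or 2, with `NA`
#' marking a missing call. It is the substrate every statistic in the package
#' consumes.
#'
#' @param dosage integer matrix, samples x variants; entries in `{0, 1, 2, NA}`.
#' @param variants tibble with at least `chrom`, `pos`, `ref`, `alt` (one row
#'   per column of `dosage`). Positions are 1-based, VCF convention.
#' @param samples character vector of sample identifiers (one per row).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- tibble::as_tibble(variants)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  samples <- as.character(samples)
  stopifnot(
    nrow(dosage) == length(samples),
    ncol(dosage) == nrow(variants),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants))
  )
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1", call. = FALSE)
  rownames(dosage) <- samples
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%.1f%% missing)\n",
    length(x$samples), nrow(x$variants), 100 * miss
  ))
  chroms <- unique(x$variants$chrom)
  cat("  chromosomes:", paste(utils::head(chroms, 6), collapse = ", "),
      if (length(chroms) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param samples sample identifiers or logical/integer row index (optional).
#' @param sites logical/integer column index over variants (optional).
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  ri <- seq_along(x$samples)
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, x$samples) else which(seq_along(x$samples) %in% seq_along(x$samples))[samples]
    if (is.character(samples) && anyNA(ri)) {
      stop("unknown sample(s): ", paste(samples[is.na(ri)], collapse = ", "), call. = FALSE)
    }
  }
  ci <- seq_len(nrow(x$variants))
  if (!is.null(sites)) ci <- ci[sites]
  geno_matrix(
    x$dosage[ri, ci, drop = FALSE],
    x$variants[ci, , drop = FALSE],
    x$samples[ri]
  )
}

#' Per-site allele frequencies and call counts
#'
#' Alternate-allele frequency per site computed on called genotypes only.
#'
#' @param x a [geno_matrix()] or a dosage matrix.
#' @return A tibble with one row per site: `n_called` (called diploid
#'   genotypes), `n_alleles` (2 x n_called), `alt_count`, `alt_freq`,
#'   `miss_frac` (fraction of missing genotypes).
#' @export
site_frequencies <- function(x) {
  d <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  called <- colSums(!is.na(d))
  altc <- colSums(d, na.rm = TRUE)
  tibble::tibble(
    n_called = as.integer(called),
    n_alleles = 2L * as.integer(called),
    alt_count = as.integer(altc),
    alt_freq = ifelse(called > 0, altc / (2 * called), NA_real_),
    miss_frac = 1 - called / nrow(d)
  )
}

#' Split sample indices by population
#'
#' @param x a [geno_matrix()].
#' @param popmap tibble with columns `sample`, `population`.
#' @return Named list of integer row indices, one element per population.
#' @keywords internal
pop_indices <- function(x, popmap) {
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  pm <- popmap[popmap$sample %in% x$samples, ]
  split(match(pm$sample, x$samples), pm$population)
}
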