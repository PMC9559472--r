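#' QC filter configuration
#'
#' Hard-filter thresholds follow the standard GATK recommendations for
#' germline short variants; every comparison is a strict inequality, so a
#' record sitting exactly on a threshold passes. Absent INFO annotations never
#' fail a record (GATK emits the rank-sum annotations only at sites carrying a
#' heterozygote).
#'
#' @param snp_thresholds named list of fail conditions for SNPs. Names are
#'   lower-cased INFO keys plus `qual`; values are `c(op, threshold)` pairs
#'   encoded as a list of `list(op=, value=)`.
#' @param maf_min minimum minor-allele frequency (sites with MAF strictly
#'   below are removed); default 0.03.
#' @param max_missing maximum missing-genotype fraction (sites strictly above
#'   are removed); default 0.20.
#' @return A `filter_config` list.
#' @export
filter_config <- function(snp_thresholds = NULL, maf_min = 0.03,
                          max_missing = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  if (is.null(snp_thresholds)) {
    snp_thresholds <- list(
      qd = list(op = "<", value = 2.0),
      qual = list(op = "<", value = 30.0),
      sor = list(op = ">", value = 3.0),
      fs = list(op = ">", value = 60.0),
      mq = list(op = "<", value = 40.0),
      mqranksum = list(op = "<", value = -12.5),
      readposranksum = list(op = "<", value = -8.0)
    )
  }
  indel_thresholds <- list(
    qd = list(op = "<", value = 2.0),
    qual = list(op = "<", value = 30.0),
    fs = list(op = ">", value = 200.0),
    mq = list(op = "<", value = 40.0),
    readposranksum = list(op = "<", value = -20.0)
  )
  structure(list(snp_thresholds = snp_thresholds,
                 indel_thresholds = indel_thresholds,
                 maf_min = maf_min, max_missing = max_missing),
            class = "filter_config")
}

#' Evaluate hard filters on a variant table
#'
#' @param variants tibble of variants (as carried by a [geno_matrix()]); the
#'   threshold names are matched against its columns.
#' @param config a [filter_config()].
#' @param type `"snp"` or `"indel"` threshold set.
#' @return A tibble with one row per variant: `pass` (logical) and `reasons`
#'   (comma-separated violated keys, `""` when passing).
#' @export
hard_filter <- function(variants, config = filter_config(),
                        type = c("snp", "indel")) {
  type <- match.arg(type)
  thr <- if (type == "snp") config$snp_thresholds else config$indel_thresholds
  n <- nrow(variants)
  fails <- matrix(FALSE, n, length(thr),
                  dimnames = list(NULL, names(thr)))
  for (key in names(thr)) {
    if (!key %in% names(variants)) next
    val <- variants[[key]]
    hit <- if (thr[[key]]$op == "<") val < thr[[key]]$value else val > thr[[key]]$value
    hit[is.na(hit)] <- FALSE  # absent annotation never fails
    fails[, key] <- hit
  }
  canon <- c(qd = "QD", qual = "QUAL", sor = "SOR", fs = "FS", mq = "MQ",
             mqranksum = "MQRankSum", readposranksum = "ReadPosRankSum")
  reasons <- apply(fails, 1, function(r) {
    keys <- names(thr)[r]
    paste(ifelse(keys %in% names(canon), canon[keys], keys), collapse = ",")
  })
  tibble::tibble(pass = rowSums(fails) == 0, reasons = reasons)
}

#' Apply hard filters to a genotype matrix
#'
#' @param geno a [geno_matrix()].
#' @inheritParams hard_filter
#' @return The filtered `geno_matrix`, with attribute `filter_report`: a
#'   tibble of removed sites (`chrom`, `pos`, `reasons`).
#' @export
hard_filter_geno <- function(geno, config = filter_config()) {
  status <- hard_filter(geno$variants, config, type = "snp")
  out <- subset_geno(geno, sites = status$pass)
  rep <- dplyr::bind_cols(
    geno$variants[!status$pass, c("chrom", "pos")],
    reasons = status$reasons[!status$pass]
  )
  attr(out, "filter_report") <- tibble::as_tibble(rep)
  out
}

#' MAF / missingness filtering
#'
#' Removes a site iff its minor-allele frequency (computed on called alleles
#' only) is strictly below `maf_min`, or its missing-genotype fraction is
#' strictly above `max_missing`, or no genotype is called at all. Boundary
#' values are retained. Idempotent.
#'
#' @param geno a [geno_matrix()].
#' @param config a [filter_config()].
#' @return The filtered `geno_matrix` with attribute `qc_report`, a one-row
#'   tibble counting removals per reason (`n_input`, `n_kept`, `n_low_maf`,
#'   `n_high_missing`, `n_all_missing`; a site failing both predicates counts
#'   under both).
#' @export
filter_maf_missing <- function(geno, config = filter_config()) {
  sf <- site_frequencies(geno)
  maf <- pmin(sf$alt_freq, 1 - sf$alt_freq)
  all_missing <- sf$n_called == 0
  low_maf <- !all_missing & maf < config$maf_min
  high_miss <- !all_missing & sf$miss_frac > config$max_missing
  keep <- !all_missing & !low_maf & !high_miss
  out <- subset_geno(geno, sites = keep)
  attr(out, "qc_report") <- tibble::tibble(
    n_input = length(keep), n_kept = sum(keep),
    n_low_maf = sum(low_maf), n_high_missing = sum(high_miss),
    n_all_missing = sum(all_missing)
  )
  out
}
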