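#' Polymorphism information content
#'
#' Marker informativeness for a site with allele frequencies `P_1..P_n`:
#' \deqn{PIC = 1 - \sum_i P_i^2 - \sum_i \sum_{j>i} 2 P_i^2 P_j^2}
#' For a biallelic site the maximum is 0.375 at p = 0.5, and PIC never
#' exceeds the expected heterozygosity `1 - sum(P^2)`.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return PIC value in `[0, 1]`.
#' @export
pic <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  n <- length(freqs)
  cross <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      cross <- cross + sum(2 * freqs[i]^2 * freqs[(i + 1):n]^2)
    }
  }
  1 - sum(freqs^2) - cross
}

#' Per-site nucleotide diversity
#'
#' Unordered-pair mismatch fraction among called alleles at one site:
#' `pi = 2 j (n - j) / (n (n - 1))` for alternate-allele count `j` among `n`
#' called alleles. Equivalent to counting mismatching haplotype pairs over all
#' `choose(n, 2)` pairs.
#'
#' @param alt_count alternate-allele count `j` (vectorized).
#' @param n_alleles called allele count `n` (vectorized); sites with `n < 2`
#'   return `NA`.
#' @return Numeric vector of per-site pi in `[0, 1]`.
#' @export
site_pi <- function(alt_count, n_alleles) {
  out <- 2 * alt_count * (n_alleles - alt_count) /
    (n_alleles * (n_alleles - 1))
  out[n_alleles < 2] <- NA_real_
  out
}

#' Observed heterozygosity per site
#'
#' @param dosage integer vector/matrix of dosages (columns = sites).
#' @return Heterozygote fraction among called genotypes per site (`NA` when no
#'   genotype is called).
#' @export
site_ho <- function(dosage) {
  d <- as.matrix(dosage)
  colSums(d == 1L, na.rm = TRUE) / colSums(!is.na(d))
}

#' Expected heterozygosity (genetic diversity) per site
#'
#' `GD = 1 - sum(P_i^2)`, uncorrected for sample size.
#'
#' @param alt_freq alternate-allele frequency (vectorized).
#' @return Numeric vector in `[0, 0.5]` for biallelic sites.
#' @export
site_gd <- function(alt_freq) {
  1 - alt_freq^2 - (1 - alt_freq)^2
}

#' Average per-individual variant count (K)
#'
#' Primary definition (literal "sum of nucleotide variations of all
#' individuals divided by the number of individuals"): the mean over
#' individuals of the number of sites at which the individual carries at least
#' one alternate allele. The classical mean pairwise difference (mean over
#' individual pairs of the summed absolute dosage difference) is returned
#' alongside as `k_pairwise`.
#'
#' @param geno a [geno_matrix()].
#' @param sample_idx optional integer row index restricting to one population.
#' @return A one-row tibble: `k_indiv`, `k_pairwise`.
#' @export
k_statistic <- function(geno, sample_idx = NULL) {
  d <- geno$dosage
  if (!is.null(sample_idx)) d <- d[sample_idx, , drop = FALSE]
  if (nrow(d) == 0) stop("empty population", call. = FALSE)
  per_ind <- rowSums(d >= 1L, na.rm = TRUE)
  k_ind <- mean(per_ind)
  n <- nrow(d)
  k_pair <- NA_real_
  if (n >= 2) {
    # sum over sites of summed |d_i - d_j| across called pairs, via genotype
    # counts: n0*n1 + n1*n2 + 2*n0*n2 per site; missing pairs contribute 0
    n0 <- colSums(d == 0L, na.rm = TRUE)
    n1 <- colSums(d == 1L, na.rm = TRUE)
    n2 <- colSums(d == 2L, na.rm = TRUE)
    k_pair <- sum(n0 * n1 + n1 * n2 + 2 * n0 * n2) / choose(n, 2)
  }
  tibble::tibble(k_indiv = k_ind, k_pairwise = k_pair)
}

#' Per-population diversity summary
#'
#' For each population: allele frequencies are recomputed from that
#' population's called genotypes; PIC, Ho, GD and pi are averaged over the
#' sites polymorphic within the population; K statistics use all sites.
#'
#' @param geno a QC-filtered [geno_matrix()].
#' @param popmap tibble with `sample`, `population`.
#' @return A tibble with one row per population: `population`, `n_samples`,
#'   `n_polymorphic`, `pic`, `ho`, `gd`, `pi`, `k_indiv`, `k_pairwise`.
#' @export
diversity_summary <- function(geno, popmap) {
  idx <- pop_indices(geno, popmap)
  if (!length(idx)) stop("no mapped samples in matrix", call. = FALSE)
  purrr::map_dfr(names(idx), function(pop) {
    sub <- geno$dosage[idx[[pop]], , drop = FALSE]
    sf <- site_frequencies(sub)
    poly <- !is.na(sf$alt_freq) & sf$alt_freq > 0 & sf$alt_freq < 1 &
      sf$n_alleles >= 2
    p <- sf$alt_freq[poly]
    pic_vals <- vapply(p, function(pp) pic(c(pp, 1 - pp)), numeric(1))
    ho_vals <- site_ho(sub[, poly, drop = FALSE])
    pi_vals <- site_pi(sf$alt_count[poly], sf$n_alleles[poly])
    ks <- k_statistic(geno, idx[[pop]])
    tibble::tibble(
      population = pop,
      n_samples = length(idx[[pop]]),
      n_polymorphic = sum(poly),
      pic = if (sum(poly)) mean(pic_vals) else 0,
      ho = if (sum(poly)) mean(ho_vals, na.rm = TRUE) else 0,
      gd = if (sum(poly)) mean(site_gd(p)) else 0,
      pi = if (sum(poly)) mean(pi_vals, na.rm = TRUE) else 0,
      k_indiv = ks$k_indiv,
      k_pairwise = ks$k_pairwise
    )
  })
}
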