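#' Per-site Weir-Cockerham variance components and Fst
#'
#' Computes the Weir & Cockerham (1984) analysis-of-variance estimator for
#' each site from diploid genotypes: `a` (among-population), `b`
#' (among-individuals-within-population) and `c` (within-individual) variance
#' components, with `Fst = a / (a + b + c)`. Negative per-site estimates are
#' kept unclamped. A site is undefined (`NA`) when any population has no
#' called genotype there, when the mean sample size is below 2, or when the
#' total variance is zero.
#'
#' @param geno a [geno_matrix()] (or a dosage matrix with samples in rows).
#' @param popmap tibble `sample`, `population` (>= 2 populations).
#' @return A tibble with one row per site: `a`, `b`, `c`, `abc` (their sum)
#'   and `fst`.
#' @export
wc_fst <- function(geno, popmap) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  if (inherits(geno, "geno_matrix")) {
    idx <- pop_indices(geno, popmap)
  } else {
    pm <- popmap[popmap$sample %in% rownames(d), ]
    idx <- split(match(pm$sample, rownames(d)), pm$population)
  }
  if (length(idx) < 2) stop("need >= 2 populations for Fst", call. = FALSE)
  r <- length(idx)
  m <- ncol(d)

  n_i <- sapply(idx, function(ii) colSums(!is.na(d[ii, , drop = FALSE])))
  p_i <- sapply(idx, function(ii) {
    colSums(d[ii, , drop = FALSE], na.rm = TRUE)
  })
  h_i <- sapply(idx, function(ii) {
    colSums(d[ii, , drop = FALSE] == 1L, na.rm = TRUE)
  })
  if (m == 1) {
    n_i <- matrix(n_i, nrow = 1); p_i <- matrix(p_i, nrow = 1)
    h_i <- matrix(h_i, nrow = 1)
  }
  p_i <- p_i / (2 * n_i)   # alt-allele frequency per pop
  h_i <- h_i / n_i         # observed het fraction per pop

  n_sum <- rowSums(n_i)
  n_bar <- n_sum / r
  n_c <- (n_sum - rowSums(n_i^2) / n_sum) / (r - 1)
  p_bar <- rowSums(n_i * p_i) / n_sum
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_i * h_i) / n_sum

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2

  bad <- apply(n_i, 1, min) < 1 | n_bar <= 1 | !is.finite(n_c) | n_c <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  abc <- a + b + cc
  fst <- ifelse(!is.na(abc) & abc != 0, a / abc, NA_real_)
  tibble::tibble(a = a, b = b, c = cc, abc = abc, fst = fst)
}
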