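#' Pairwise genotypic r-squared
#'
#' Squared Pearson correlation of allele dosages across pairwise-complete
#' samples (the composite genotypic measure of linkage disequilibrium,
#' standard for unphased data). Invariant to swapping reference and alternate
#' labels at either site.
#'
#' @param dosage_a,dosage_b integer dosage vectors for two sites.
#' @return r-squared in `[0, 1]`, or `NA` if fewer than two complete pairs or
#'   either site is monomorphic among complete cases.
#' @export
pair_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Scores every within-chromosome site pair up to `max_dist` apart with
#' [pair_r2()] and averages r-squared in contiguous distance bins.
#'
#' @param geno a [geno_matrix()].
#' @param popmap optional tibble `sample`, `population`; used with
#'   `population`.
#' @param population population label to condition on (`NULL` = all samples
#'   pooled).
#' @param max_dist maximum inter-SNP distance in bp (default 300 kb).
#' @param bin_width distance bin width in bp (default 1 kb).
#' @return A tibble of class `ld_decay`: `distance_lo`, `distance_hi`,
#'   `mean_r2`, `n_pairs` (only non-empty bins). Zero eligible pairs gives an
#'   empty tibble with a warning.
#' @export
ld_decay <- function(geno, popmap = NULL, population = NULL,
                     max_dist = 3e5, bin_width = 1e3) {
  stopifnot(max_dist > 0, bin_width > 0)
  d <- geno$dosage
  if (!is.null(population)) {
    stopifnot(!is.null(popmap))
    idx <- pop_indices(geno, popmap)[[population]]
    if (is.null(idx)) stop("population not in map: ", population, call. = FALSE)
    d <- d[idx, , drop = FALSE]
  }
  v <- geno$variants
  dists <- numeric(0)
  r2s <- numeric(0)
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    if (length(cols) < 2) next
    ord <- cols[order(v$pos[cols])]
    pos <- v$pos[ord]
    for (i in seq_len(length(ord) - 1)) {
      j <- i + 1
      while (j <= length(ord) && pos[j] - pos[i] <= max_dist) {
        r2 <- pair_r2(d[, ord[i]], d[, ord[j]])
        if (!is.na(r2)) {
          dists <- c(dists, pos[j] - pos[i])
          r2s <- c(r2s, r2)
        }
        j <- j + 1
      }
    }
  }
  if (!length(r2s)) {
    warning("no eligible site pairs for LD decay", call. = FALSE)
    out <- tibble::tibble(distance_lo = numeric(), distance_hi = numeric(),
                          mean_r2 = numeric(), n_pairs = integer())
    class(out) <- c("ld_decay", class(out))
    return(out)
  }
  bin <- pmin(floor((dists - 1) / bin_width), ceiling(max_dist / bin_width) - 1)
  out <- tibble::tibble(bin = bin, r2 = r2s) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::transmute(
      distance_lo = .data$bin * bin_width + 1,
      distance_hi = (.data$bin + 1) * bin_width,
      mean_r2 = .data$mean_r2,
      n_pairs = as.integer(.data$n_pairs)
    )
  class(out) <- c("ld_decay", class(out))
  out
}

#' Plot an LD decay curve
#'
#' @param object an `ld_decay` tibble from [ld_decay()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$distance_lo + .data$distance_hi) / 2e3, y = .data$mean_r2)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "Distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}
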