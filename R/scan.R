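#' Sliding-window Fst and nucleotide-diversity statistics
#'
#' Tiles each chromosome with windows of `window` bp advanced by `step` bp,
#' anchored at position 1, and summarizes every window that contains at least
#' one SNP: weighted Fst (ratio of summed Weir-Cockerham `a` components over
#' summed `a+b+c`), mean per-site Fst, per-bp nucleotide diversity in the
#' reference and target populations, and their ratio
#' `pi_ratio = pi_ref / pi_target`. A window with `pi_target = 0` and
#' `pi_ref > 0` gets an infinite ratio (high tail by convention); a window
#' with both zero is unrankable (`pi_ratio = NA`). Windows with fewer than
#' `min_snps` SNPs are kept in the output but flagged unrankable.
#'
#' @param geno a QC-filtered [geno_matrix()].
#' @param popmap tibble `sample`, `population`.
#' @param ref_pop,target_pop population labels; the target is the population
#'   in which a sweep depresses diversity (low `pi_ratio` means diversity loss
#'   in the reference; high means loss in the target).
#' @param window,step window size and step in bp (defaults 100 kb / 50 kb).
#' @param min_snps minimum SNPs for a window to be rankable (default 3).
#' @return A tibble of class `scan_windows`: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_snps`, `fst_weighted`, `fst_mean`, `pi_ref`, `pi_target`,
#'   `pi_ratio`, `rankable`.
#' @export
window_stats <- function(geno, popmap, ref_pop, target_pop,
                         window = 1e5, step = 5e4, min_snps = 3) {
  if (window <= 0 || step <= 0) stop("window and step must be > 0", call. = FALSE)
  idx <- pop_indices(geno, popmap)
  if (!ref_pop %in% names(idx)) stop("unknown ref_pop: ", ref_pop, call. = FALSE)
  if (!target_pop %in% names(idx)) stop("unknown target_pop: ", target_pop, call. = FALSE)
  pm2 <- popmap[popmap$population %in% c(ref_pop, target_pop), ]
  comp <- wc_fst(geno, pm2)

  pi_pop <- function(ii) {
    sub <- geno$dosage[ii, , drop = FALSE]
    sf <- site_frequencies(sub)
    p <- site_pi(sf$alt_count, sf$n_alleles)
    ifelse(is.na(p), 0, p)  # uncallable sites contribute no diversity
  }
  pr <- pi_pop(idx[[ref_pop]])
  pt <- pi_pop(idx[[target_pop]])

  v <- geno$variants
  w_max <- (v$pos - 1) %/% step
  w_min <- pmax(0, ceiling((v$pos - window) / step))
  reps <- w_max - w_min + 1
  site_rep <- rep(seq_len(nrow(v)), reps)
  win_idx <- unlist(mapply(seq, w_min, w_max, SIMPLIFY = FALSE))

  df <- tibble::tibble(
    chrom = v$chrom[site_rep],
    win = win_idx,
    a = comp$a[site_rep],
    abc = comp$abc[site_rep],
    fst = comp$fst[site_rep],
    pi_r = pr[site_rep],
    pi_t = pt[site_rep]
  )
  out <- df |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      sum_a = sum(.data$a, na.rm = TRUE),
      sum_abc = sum(.data$abc, na.rm = TRUE),
      fst_mean = mean(.data$fst, na.rm = TRUE),
      pi_ref = sum(.data$pi_r) / window,
      pi_target = sum(.data$pi_t) / window,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      start = .data$win * step + 1,
      end = .data$win * step + window,
      fst_weighted = ifelse(.data$sum_abc != 0,
                            .data$sum_a / .data$sum_abc, NA_real_),
      fst_mean = ifelse(is.nan(.data$fst_mean), NA_real_, .data$fst_mean),
      pi_ratio = dplyr::case_when(
        .data$pi_target > 0 ~ .data$pi_ref / .data$pi_target,
        .data$pi_ref > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      rankable = .data$n_snps >= min_snps & !is.na(.data$fst_weighted) &
        !is.na(.data$pi_ratio)
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "n_snps", "fst_weighted",
                  "fst_mean", "pi_ref", "pi_target", "pi_ratio", "rankable")
  attr(out, "scan_params") <- list(window = window, step = step,
                                   min_snps = min_snps, ref_pop = ref_pop,
                                   target_pop = target_pop)
  class(out) <- c("scan_windows", class(out))
  out
}

# empirical order-statistic quantile (type 1, no interpolation)
quantile_type1 <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[max(1L, ceiling(length(x) * p))]
}

#' Joint-tail candidate-window selection
#'
#' A rankable window is selected iff its weighted Fst strictly exceeds the
#' empirical `fst_quantile` threshold AND its pi ratio falls strictly in
#' either tail of the ratio distribution (below the lower or above the upper
#' `ratio_tails` quantile). Thresholds are order-statistic quantiles (type 1,
#' no interpolation), computed on rankable windows only.
#'
#' @param windows a `scan_windows` tibble from [window_stats()].
#' @param fst_quantile upper Fst quantile (default 0.95).
#' @param ratio_tails lower/upper pi-ratio quantiles (default `c(0.05, 0.95)`).
#' @return The input with logical `selected` and `tail` (`"low"`, `"high"` or
#'   `NA`) columns; thresholds in attribute `thresholds`.
#' @export
select_candidates <- function(windows, fst_quantile = 0.95,
                              ratio_tails = c(0.05, 0.95)) {
  rk <- windows$rankable
  if (!any(rk)) stop("no rankable window", call. = FALSE)
  fst_thr <- quantile_type1(windows$fst_weighted[rk], fst_quantile)
  lo_thr <- quantile_type1(windows$pi_ratio[rk], ratio_tails[1])
  hi_thr <- quantile_type1(windows$pi_ratio[rk], ratio_tails[2])
  low_tail <- rk & windows$pi_ratio < lo_thr
  high_tail <- rk & windows$pi_ratio > hi_thr
  sel <- rk & windows$fst_weighted > fst_thr & (low_tail | high_tail)
  out <- dplyr::mutate(
    windows,
    selected = sel,
    tail = dplyr::case_when(sel & low_tail ~ "low", sel & high_tail ~ "high",
                            TRUE ~ NA_character_)
  )
  attr(out, "scan_params") <- attr(windows, "scan_params")
  attr(out, "thresholds") <- list(fst = fst_thr, ratio_lo = lo_thr,
                                  ratio_hi = hi_thr)
  class(out) <- unique(c("scan_windows", class(out)))
  out
}

#' Merge selected windows into candidate regions
#'
#' Selected windows on the same chromosome and the same ratio-tail side that
#' overlap or abut (next start <= previous end + 1) merge into one region
#' whose bounds are the union of its members.
#'
#' @param windows output of [select_candidates()].
#' @return A tibble: `chrom`, `start`, `end`, `n_windows`, `max_fst`, `tail`.
#' @export
merge_regions <- function(windows) {
  sel <- windows[windows$selected %||% FALSE, , drop = FALSE]
  if (!nrow(sel)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          max_fst = numeric(), tail = character()))
  }
  sel <- dplyr::arrange(sel, .data$chrom, .data$tail, .data$start)
  new_grp <- with(sel, c(TRUE, chrom[-1] != chrom[-nrow(sel)] |
                           tail[-1] != tail[-nrow(sel)] |
                           start[-1] > cummax_by(end, chrom, tail)[-nrow(sel)] + 1))
  grp <- cumsum(new_grp)
  sel |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      max_fst = max(.data$fst_weighted),
      tail = .data$tail[1],
      .groups = "drop"
    ) |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# running max of `end` within (chrom, tail) groups, in the given order
cummax_by <- function(end, chrom, tail) {
  key <- paste(chrom, tail)
  out <- numeric(length(end))
  for (k in unique(key)) {
    ii <- which(key == k)
    out[ii] <- cummax(end[ii])
  }
  out
}

#' Attach overlapping genes to candidate regions
#'
#' Gene intervals use BED coordinates (0-based half-open); regions are 1-based
#' inclusive. A gene is attached iff the overlap is at least 1 bp after
#' conversion.
#'
#' @param regions tibble from [merge_regions()].
#' @param genes tibble from [read_bed()] (`chrom`, `start`, `end`, `name`).
#' @return `regions` with a list-column `genes` and a collapsed `gene_names`
#'   string.
#' @export
annotate_regions <- function(regions, genes) {
  check_intervals(genes)
  glist <- purrr::map2(regions$chrom, seq_len(nrow(regions)), function(ch, i) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # BED [start, end) -> 1-based inclusive [start + 1, end]
    hit <- (g$start + 1) <= regions$end[i] & g$end >= regions$start[i]
    g$name[hit]
  })
  dplyr::mutate(regions,
                genes = glist,
                gene_names = vapply(glist, paste, character(1), collapse = ","))
}

#' Top-Fst SNPs inside candidate regions
#'
#' Recomputes per-site Weir-Cockerham Fst for all sites inside the candidate
#' regions and returns the `k` highest, ties broken by `(chrom, pos)`.
#'
#' @param regions annotated regions ([annotate_regions()]).
#' @param geno a [geno_matrix()].
#' @param popmap tibble `sample`, `population`.
#' @param k number of SNPs to return (default 25); if fewer sites are
#'   available all are returned with a warning.
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `fst`, `region_tail`,
#'   `genes`.
#' @export
top_sites <- function(regions, geno, popmap, k = 25) {
  v <- geno$variants
  in_region <- rep(FALSE, nrow(v))
  region_of <- rep(NA_integer_, nrow(v))
  for (i in seq_len(nrow(regions))) {
    hit <- v$chrom == regions$chrom[i] & v$pos >= regions$start[i] &
      v$pos <= regions$end[i]
    region_of[hit & !in_region] <- i
    in_region <- in_region | hit
  }
  if (!any(in_region)) {
    warning("no sites inside candidate regions", call. = FALSE)
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          fst = numeric(), region_tail = character(),
                          genes = character()))
  }
  sub <- subset_geno(geno, sites = in_region)
  fst <- wc_fst(sub, popmap)$fst
  res <- tibble::tibble(
    chrom = sub$variants$chrom, pos = sub$variants$pos,
    ref = sub$variants$ref, alt = sub$variants$alt, fst = fst,
    region_tail = regions$tail[region_of[in_region]],
    genes = if ("gene_names" %in% names(regions)) {
      regions$gene_names[region_of[in_region]]
    } else NA_character_
  )
  res <- dplyr::arrange(res, dplyr::desc(.data$fst), .data$chrom, .data$pos)
  if (k > nrow(res)) {
    warning(sprintf("only %d sites available (k = %d)", nrow(res), k),
            call. = FALSE)
    k <- nrow(res)
  }
  res[seq_len(k), , drop = FALSE]
}

#' Run the full selective-sweep scan
#'
#' Convenience wrapper chaining [window_stats()], [select_candidates()],
#' [merge_regions()] and (when gene intervals are supplied)
#' [annotate_regions()].
#'
#' @inheritParams window_stats
#' @inheritParams select_candidates
#' @param genes optional gene intervals ([read_bed()] tibble).
#' @return An object of class `sweep_scan` with elements `windows`,
#'   `regions`, `thresholds`, `params`.
#' @export
sweep_scan <- function(geno, popmap, ref_pop, target_pop,
                       window = 1e5, step = 5e4, min_snps = 3,
                       fst_quantile = 0.95, ratio_tails = c(0.05, 0.95),
                       genes = NULL) {
  w <- window_stats(geno, popmap, ref_pop, target_pop, window, step, min_snps)
  w <- select_candidates(w, fst_quantile, ratio_tails)
  regions <- merge_regions(w)
  if (!is.null(genes) && nrow(regions)) {
    regions <- annotate_regions(regions, genes)
  }
  structure(list(
    windows = w, regions = regions,
    thresholds = attr(w, "thresholds"),
    params = c(attr(w, "scan_params"),
               list(fst_quantile = fst_quantile, ratio_tails = ratio_tails))
  ), class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "<sweep_scan> %d windows (%d rankable), %d selected -> %d regions\n",
    nrow(x$windows), sum(x$windows$rankable), sum(x$windows$selected),
    nrow(x$regions)))
  cat(sprintf("  thresholds: fst > %.4f, ratio < %.4f or > %.4f\n",
              x$thresholds$fst, x$thresholds$ratio_lo, x$thresholds$ratio_hi))
  invisible(x)
}

#' Tidy a sweep scan into its window table
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return The window tibble with selection flags.
#' @method tidy sweep_scan
#' @export
tidy.sweep_scan <- function(x, ...) tibble::as_tibble(x$windows)

#' One-row summary of a sweep scan
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return A one-row tibble with window/selection counts and thresholds.
#' @method glance sweep_scan
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_rankable = sum(x$windows$rankable),
    n_selected = sum(x$windows$selected),
    n_regions = nrow(x$regions),
    fst_threshold = x$thresholds$fst,
    ratio_lo = x$thresholds$ratio_lo,
    ratio_hi = x$thresholds$ratio_hi
  )
}

#' Plot a sweep scan
#'
#' Weighted Fst per window along the genome, selected windows highlighted.
#'
#' @param object a `sweep_scan`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sweep_scan
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows
  w$mid <- (w$start + w$end) / 2e6
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid, y = .data$fst_weighted,
                                  color = .data$selected)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$thresholds$fst,
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Position (Mb)", y = "Weighted Fst",
                  title = "Windowed Fst scan") +
    ggplot2::theme_minimal()
}
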