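#' Genotype and allele contingency tables for one SNP
#'
#' @param geno a [geno_matrix()].
#' @param group_map tibble `sample`, `group` (two or more groups).
#' @param snp column index or `"chrom:pos"` string identifying the SNP.
#' @return A list with `genotype` (groups x {hom_ref, het, hom_alt} integer
#'   matrix; missing genotypes excluded) and `allele` (groups x {ref, alt},
#'   each genotype contributing two alleles).
#' @export
build_tables <- function(geno, group_map, snp) {
  j <- resolve_snp(geno, snp)
  d <- geno$dosage[, j]
  grp <- group_map$group[match(geno$samples, group_map$sample)]
  keep <- !is.na(grp)
  d <- d[keep]
  grp <- factor(grp[keep])
  if (nlevels(grp) < 2) stop("need >= 2 groups", call. = FALSE)
  called <- tapply(!is.na(d), grp, sum)
  if (any(called == 0)) {
    stop("group with zero called genotypes at SNP: ",
         paste(names(called)[called == 0], collapse = ", "), call. = FALSE)
  }
  gt <- factor(d, levels = 0:2, labels = c("hom_ref", "het", "hom_alt"))
  genotype <- table(grp, gt)
  allele <- cbind(
    ref = tapply(ifelse(is.na(d), 0L, 2L - d), grp, sum),
    alt = tapply(ifelse(is.na(d), 0L, d), grp, sum)
  )
  list(genotype = unclass(as.matrix(genotype)),
       allele = allele)
}

resolve_snp <- function(geno, snp) {
  if (is.numeric(snp)) {
    j <- as.integer(snp)
    if (j < 1 || j > nrow(geno$variants)) stop("SNP index out of range", call. = FALSE)
    return(j)
  }
  parts <- strsplit(snp, ":", fixed = TRUE)[[1]]
  j <- which(geno$variants$chrom == parts[1] &
               geno$variants$pos == as.integer(parts[2]))
  if (!length(j)) stop("SNP not found: ", snp, call. = FALSE)
  j[1]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (relative tie tolerance 1e-7). A
#' table with a zero row or column margin returns p = 1 by convention.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Fisher's exact test for an r x c table (Freeman-Halton)
#'
#' Exact two-sided p by enumeration of all tables sharing the observed
#' margins, summing multivariate-hypergeometric probabilities no larger than
#' the observed one. Guarded at a table total of 1000; larger tables must use
#' `monte_carlo = TRUE` (p estimated by table simulation under the null).
#'
#' @param table r x c non-negative integer matrix.
#' @param monte_carlo use Monte-Carlo estimation instead of enumeration.
#' @param B number of simulated tables when `monte_carlo = TRUE`.
#' @return Two-sided p-value.
#' @export
fisher_exact_rxc <- function(table, monte_carlo = FALSE, B = 1e5) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    # drop empty margins; a degenerate 1 x c or r x 1 remainder has p = 1
    table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
    if (nrow(table) < 2 || ncol(table) < 2) return(1)
  }
  if (monte_carlo) {
    return(stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  }
  if (sum(table) > 1000) {
    stop("table total exceeds the exact-enumeration guard (1000); ",
         "call with monte_carlo = TRUE", call. = FALSE)
  }
  stats::fisher.test(table, workspace = 2e7)$p.value
}

#' Exact-test validation of candidate SNPs against trait groups
#'
#' For each SNP and each grouping, runs the genotype-table (2 x 3,
#' Freeman-Halton) and allele-table (2 x 2) Fisher exact tests and flags
#' significance at each alpha level. No multiplicity correction is applied by
#' default; `p_adjust` switches on a standard correction applied to the
#' genotype p-values across SNPs within each comparison.
#'
#' @param geno a [geno_matrix()].
#' @param group_maps named list of group-map tibbles (`sample`, `group`), one
#'   per comparison.
#' @param snp_list vector of SNP indices or `"chrom:pos"` strings.
#' @param alpha_levels significance thresholds (default `c(0.05, 0.01)`).
#' @param p_adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A tibble with one row per SNP x comparison: `snp`, `chrom`, `pos`,
#'   `comparison`, `genotype_p`, `allele_p`, one logical `sig_<alpha>` column
#'   per level, and collapsed genotype counts per group.
#' @export
validate_snps <- function(geno, group_maps, snp_list,
                          alpha_levels = c(0.05, 0.01),
                          p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(snp_list)) stop("snp_list is empty", call. = FALSE)
  if (!is.list(group_maps) || is.data.frame(group_maps)) {
    group_maps <- list(comparison1 = group_maps)
  }
  if (is.null(names(group_maps))) {
    names(group_maps) <- paste0("comparison", seq_along(group_maps))
  }
  rows <- purrr::map_dfr(names(group_maps), function(cmp) {
    purrr::map_dfr(snp_list, function(snp) {
      j <- resolve_snp(geno, snp)
      tabs <- build_tables(geno, group_maps[[cmp]], j)
      tibble::tibble(
        snp = if (is.numeric(snp)) {
          paste0(geno$variants$chrom[j], ":", geno$variants$pos[j])
        } else as.character(snp),
        chrom = geno$variants$chrom[j],
        pos = geno$variants$pos[j],
        comparison = cmp,
        genotype_p = fisher_exact_rxc(tabs$genotype),
        allele_p = fisher_exact_2x2(tabs$allele),
        counts = paste(apply(tabs$genotype, 1, paste, collapse = "/"),
                       collapse = " vs ")
      )
    })
  })
  if (p_adjust != "none") {
    rows <- rows |>
      dplyr::group_by(.data$comparison) |>
      dplyr::mutate(genotype_p = stats::p.adjust(.data$genotype_p,
                                                 method = p_adjust)) |>
      dplyr::ungroup()
  }
  for (a in alpha_levels) {
    rows[[paste0("sig_", a)]] <- rows$genotype_p < a
  }
  rows
}
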