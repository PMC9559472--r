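#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or gzip text) and converts per-sample GT
#' calls into alternate-allele dosages. Only biallelic SNPs are kept:
#' multiallelic records and records whose REF or ALT allele is longer than one
#' base are dropped (counts of both are recorded). Phased separators are
#' treated as unphased; half calls such as `./1` are conservatively set to
#' missing.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param keep_info_keys INFO keys to parse as numeric columns of the variant
#'   table (absent keys become `NA`). The record QUAL column is always kept.
#' @return A [geno_matrix()]. The variant table carries `chrom`, `pos`, `ref`,
#'   `alt`, `qual` and one lower-case column per requested INFO key; attributes
#'   `n_multiallelic` and `n_non_snp` count dropped records.
#' @export
read_vcf <- function(path,
                     keep_info_keys = c("QD", "SOR", "FS", "MQ",
                                        "MQRankSum", "ReadPosRankSum")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path, call. = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) {
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)
  }
  has_gt <- vapply(strsplit(gt_raw[, "FORMAT"], ":", fixed = TRUE),
                   function(k) "GT" %in% k, logical(1))
  if (!all(has_gt)) {
    stop("GT missing from FORMAT on data line(s): ",
         paste(utils::head(which(!has_gt), 5), collapse = ", "), call. = FALSE)
  }

  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  is_snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L & alt != ref
  keep <- which(!multi & is_snp)

  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  gt <- gt[keep, , drop = FALSE]

  dosage <- gt_to_dosage(gt)

  variants <- tibble::tibble(
    chrom = unname(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = unname(ref[keep]),
    alt = unname(alt[keep]),
    qual = suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  )
  info_raw <- fix[keep, "INFO"]
  for (key in keep_info_keys) {
    variants[[tolower(key)]] <- parse_info_numeric(info_raw, key)
  }

  gm <- geno_matrix(t(dosage), variants, samples)
  attr(gm, "n_multiallelic") <- sum(multi)
  attr(gm, "n_non_snp") <- sum(!multi & !is_snp)
  gm
}

# GT strings (sites x samples) -> integer dosage matrix; half calls -> NA
gt_to_dosage <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g == "0/0"] <- 0L
  out[g == "0/1" | g == "1/0"] <- 1L
  out[g == "1/1"] <- 2L
  out
}

parse_info_numeric <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  suppressWarnings(as.numeric(m))
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT. Any numeric variant-table
#' columns beyond the coordinate set are serialized as INFO keys (upper-cased,
#' standard GATK capitalization for the hard-filter annotations). Re-reading
#' the file with [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param x a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  v <- x$variants
  core <- c("chrom", "pos", "ref", "alt", "qual")
  info_cols <- setdiff(names(v)[vapply(v, is.numeric, logical(1))],
                       c(core, "id"))
  canon <- c(qd = "QD", sor = "SOR", fs = "FS", mq = "MQ",
             mqranksum = "MQRankSum", readposranksum = "ReadPosRankSum")
  info_names <- ifelse(info_cols %in% names(canon), canon[info_cols],
                       toupper(info_cols))

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    if (length(info_cols)) {
      sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
              info_names, info_names)
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  # build INFO field per record
  if (length(info_cols)) {
    info_mat <- vapply(seq_along(info_cols), function(i) {
      val <- v[[info_cols[i]]]
      ifelse(is.na(val), NA_character_,
             paste0(info_names[i], "=", format(val, trim = TRUE, scientific = FALSE)))
    }, character(nrow(v)))
    if (nrow(v) == 1L) info_mat <- matrix(info_mat, nrow = 1)
    info_str <- apply(info_mat, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) "." else paste(r, collapse = ";")
    })
  } else {
    info_str <- rep(".", nrow(v))
  }

  d <- t(x$dosage)  # sites x samples
  gt_chr <- matrix("./.", nrow(d), ncol(d))
  gt_chr[!is.na(d) & d == 0L] <- "0/0"
  gt_chr[!is.na(d) & d == 1L] <- "0/1"
  gt_chr[!is.na(d) & d == 2L] <- "1/1"

  qual_str <- ifelse(is.na(v$qual %||% rep(NA_real_, nrow(v))), ".",
                     format(v$qual %||% rep(NA_real_, nrow(v)),
                            trim = TRUE, scientific = FALSE))
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, qual_str, "PASS", info_str, "GT",
    apply(gt_chr, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample-to-population map
#'
#' @param path two-column tab-separated file, `sample<TAB>population`, no
#'   header.
#' @return A tibble with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0) stop("no samples in population map: ", path, call. = FALSE)
  if (ncol(df) != 2) stop("population map must have exactly 2 columns", call. = FALSE)
  names(df) <- c("sample", "population")
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample(s) in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$population))) stop("empty population label", call. = FALSE)
  tibble::as_tibble(df)
}

#' Write a population map
#' @param popmap tibble with `sample`, `population`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "population")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write BED4 gene intervals
#'
#' BED semantics: 0-based, half-open `[start, end)`. Internally the package
#' works in VCF 1-based coordinates; conversion happens at the point of use
#' ([annotate_regions()]), never silently here.
#'
#' @param path path to a 4-column BED file (`chrom start end name`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, sorted by
#'   `(chrom, start)`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character"), quote = "")
  names(df) <- c("chrom", "start", "end", "name")
  check_intervals(df)
  dplyr::arrange(tibble::as_tibble(df), .data$chrom, .data$start)
}

#' @rdname read_bed
#' @param intervals tibble with `chrom`, `start`, `end`, `name` (BED
#'   coordinates).
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  utils::write.table(intervals[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

check_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(x)))
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    stop(sprintf("interval start >= end at line %d (%s:%d-%d)",
                 bad, x$chrom[bad], x$start[bad], x$end[bad]), call. = FALSE)
  }
  invisible(x)
}
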