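#' Pipeline configuration
#'
#' Collects every stage parameter plus input/output paths into one validated
#' list. Any field can be overridden; the whole object is serialized verbatim
#' into the run manifest so a run can be replayed exactly.
#'
#' @param vcf,popmap,genes input paths (genes optional, may be `NA`).
#' @param outdir output directory.
#' @param ref_pop,target_pop population labels for the scan.
#' @param maf_min,max_missing QC thresholds (see [filter_config()]).
#' @param window,step,min_snps scan window geometry.
#' @param fst_quantile,ratio_tails joint-tail selection quantiles.
#' @param ld_max_dist,ld_bin_width LD decay settings.
#' @param pca_k number of principal components.
#' @param top_k number of top-Fst SNPs to extract.
#' @param alpha_levels association significance thresholds.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, popmap, outdir, genes = NA,
                            ref_pop = "A", target_pop = "B",
                            maf_min = 0.03, max_missing = 0.20,
                            window = 1e5, step = 5e4, min_snps = 3,
                            fst_quantile = 0.95, ratio_tails = c(0.05, 0.95),
                            ld_max_dist = 3e5, ld_bin_width = 1e3,
                            pca_k = 2, top_k = 25,
                            alpha_levels = c(0.05, 0.01), seed = 1L) {
  if (window <= 0 || step <= 0) stop("window and step must be > 0", call. = FALSE)
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min out of [0, 0.5]", call. = FALSE)
  if (max_missing < 0 || max_missing > 1) stop("max_missing out of [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: QC (hard filters then MAF/missingness) -> per-population diversity
#' -> LD decay -> structure (PCA + NJ tree) -> windowed Fst / pi-ratio sweep
#' scan with candidate regions and top SNPs -> optional exact-test validation.
#' Every stage writes a TSV (or Newick) into `outdir`; a JSON manifest records
#' input hashes, the full configuration and package version. Reruns with
#' identical inputs and configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param group_maps optional named list of trait group maps for the
#'   association stage (tibbles `sample`, `group`).
#' @return The output directory path, invisibly; stage results as attribute
#'   `results`.
#' @export
run_pipeline <- function(config, group_maps = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  geno <- read_vcf(config$vcf)
  popmap <- read_popmap(config$popmap)
  genes <- if (!is.na(config$genes)) read_bed(config$genes) else NULL

  fc <- filter_config(maf_min = config$maf_min,
                      max_missing = config$max_missing)
  geno_hf <- hard_filter_geno(geno, fc)
  geno_qc <- filter_maf_missing(geno_hf, fc)
  qc_rep <- attr(geno_qc, "qc_report")
  readr::write_tsv(qc_rep, file.path(config$outdir, "qc_report.tsv"))

  div <- diversity_summary(geno_qc, popmap)
  readr::write_tsv(div, file.path(config$outdir, "diversity.tsv"))

  for (pop in unique(popmap$population)) {
    ld <- ld_decay(geno_qc, popmap, pop, config$ld_max_dist,
                   config$ld_bin_width)
    readr::write_tsv(ld, file.path(config$outdir,
                                   paste0("ld_decay_", pop, ".tsv")))
  }

  pca <- genotype_pca(geno_qc, config$pca_k, popmap)
  readr::write_tsv(pca$scores, file.path(config$outdir, "pca_scores.tsv"))
  tree <- nj_tree(allele_sharing_distance(geno_qc))
  write_newick(tree, file.path(config$outdir, "nj_tree.nwk"))

  scan <- sweep_scan(geno_qc, popmap, config$ref_pop, config$target_pop,
                     config$window, config$step, config$min_snps,
                     config$fst_quantile, config$ratio_tails, genes)
  readr::write_tsv(tidy.sweep_scan(scan),
                   file.path(config$outdir, "scan_windows.tsv"))
  reg_flat <- scan$regions
  if ("genes" %in% names(reg_flat)) reg_flat$genes <- NULL
  readr::write_tsv(reg_flat, file.path(config$outdir, "candidate_regions.tsv"))
  top <- if (nrow(scan$regions)) {
    suppressWarnings(top_sites(scan$regions, geno_qc, popmap, config$top_k))
  } else {
    tibble::tibble()
  }
  readr::write_tsv(top, file.path(config$outdir, "top_sites.tsv"))

  assoc <- NULL
  if (!is.null(group_maps) && nrow(top)) {
    assoc <- validate_snps(geno_qc, group_maps,
                           paste0(top$chrom, ":", top$pos),
                           config$alpha_levels)
    readr::write_tsv(assoc, file.path(config$outdir, "association.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    inputs = list(
      vcf = unname(tools::md5sum(config$vcf)),
      popmap = unname(tools::md5sum(config$popmap)),
      genes = if (!is.na(config$genes)) unname(tools::md5sum(config$genes))
    ),
    config = config[setdiff(names(config), character(0))],
    funnel = list(
      n_input = nrow(geno$variants) + attr(geno, "n_multiallelic") +
        attr(geno, "n_non_snp"),
      n_multiallelic_dropped = attr(geno, "n_multiallelic"),
      n_non_snp_dropped = attr(geno, "n_non_snp"),
      n_hard_filtered = nrow(geno$variants) - nrow(geno_hf$variants),
      n_qc_removed = qc_rep$n_input - qc_rep$n_kept,
      n_final = nrow(geno_qc$variants)
    )
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)

  res <- list(geno_qc = geno_qc, diversity = div, pca = pca, tree = tree,
              scan = scan, top = top, assoc = assoc)
  out <- config$outdir
  attr(out, "results") <- res
  invisible(out)
}

#' Command-line entry point
#'
#' Thin dispatcher behind `inst/cli/sweepscan.R`. Subcommands: `simulate`,
#' `run`, `scan`. Options are `--key value` pairs; `run` reads a YAML config
#' file (`--config`) whose keys mirror [pipeline_config()], with any
#' remaining flags overriding the file.
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit code (0 = success, 2 = usage error), invisibly.
#' @export
cli_main <- function(argv) {
  usage <- function() {
    message("usage: sweepscan <simulate|run|scan> [--key value ...]\n",
            "  simulate --seed S --out DIR [--n-sites N] [--sweeps K]\n",
            "  run --config FILE [--outdir DIR]\n",
            "  scan --vcf F --popmap F --out DIR [--window W] [--step S]")
    invisible(2L)
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  if (is.null(opts)) return(usage())
  switch(
    cmd,
    simulate = {
      if (is.null(opts$seed) || is.null(opts$out)) return(usage())
      n_sites <- as.integer(opts[["n-sites"]] %||% 5000)
      n_sweeps <- as.integer(opts$sweeps %||% 1)
      cfg <- sim_config(
        n_sites = n_sites, seed = as.integer(opts$seed),
        sweep_loci = if (n_sweeps > 0) {
          tibble::tibble(
            position = round(seq(0.2, 0.8, length.out = n_sweeps) * 5e6),
            s = 0.3, pop = "B", chrom = "chr1")
        }
      )
      sim <- simulate_two_pop(cfg)
      write_simulation(sim, opts$out, cfg)
      invisible(0L)
    },
    run = {
      if (is.null(opts$config)) return(usage())
      y <- yaml::read_yaml(opts$config)
      if (!is.null(opts$outdir)) y$outdir <- opts$outdir
      cfg <- do.call(pipeline_config, y)
      run_pipeline(cfg)
      invisible(0L)
    },
    scan = {
      if (is.null(opts$vcf) || is.null(opts$popmap) || is.null(opts$out)) {
        return(usage())
      }
      geno <- filter_maf_missing(read_vcf(opts$vcf))
      popmap <- read_popmap(opts$popmap)
      pops <- unique(popmap$population)
      sc <- sweep_scan(geno, popmap,
                       ref_pop = opts$ref %||% pops[1],
                       target_pop = opts$target %||% pops[2],
                       window = as.numeric(opts$window %||% 1e5),
                       step = as.numeric(opts$step %||% 5e4))
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      readr::write_tsv(tidy.sweep_scan(sc),
                       file.path(opts$out, "scan_windows.tsv"))
      invisible(0L)
    },
    usage()
  )
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args)) return(NULL)
    opts[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
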