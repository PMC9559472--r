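#' Simulation configuration for the two-population Wright-Fisher model
#'
#' Defines a clean-split demography: a single ancestral population whose site
#' frequencies are drawn from a symmetric Beta distribution, followed by
#' `split_generations` generations of independent Wright-Fisher drift in two
#' demes (A and B). Directional selection can act at chosen loci in one deme,
#' producing localized sweeps. Two engines are available:
#'
#' * `"sitewise"` — each site evolves independently by binomial resampling of
#'   allele frequencies; fast, no linkage. At a sweep locus the deterministic
#'   update `p' = p(1+s)/(1+sp)` is applied before each resampling step, and
#'   the hitchhiking footprint is emulated by applying the same update to
#'   flanking sites with a distance-decayed coefficient `s*exp(-d/L)`
#'   (`L = sweep_footprint`), so that a sweep locally depresses diversity and
#'   elevates differentiation the way a real sweep does.
#' * `"haplotype"` — explicit 2N haplotypes per deme reproduce by random union
#'   of gametes with Poisson-distributed crossovers, giving genuine linkage
#'   disequilibrium (selection weights parents by multiplicative fitness
#'   `(1+s)` per sweep allele).
#'
#' Sample sizes default to the 26 + 54 two-breed design the package's
#' end-to-end checks emulate.
#'
#' @param n_pop_a,n_pop_b diploid sample sizes drawn from demes A and B.
#' @param effective_size Wright-Fisher diploid population size per deme.
#' @param split_generations generations of independent drift after the split.
#' @param n_sites number of biallelic SNPs.
#' @param chrom_length chromosome length in bp (positions drawn uniformly).
#' @param n_chrom number of chromosomes; sites are split evenly across them.
#' @param sweep_loci tibble with columns `position` (bp), `s` (selection
#'   coefficient, > 0), `pop` (`"A"` or `"B"`: the deme under selection), and
#'   optionally `chrom`. Empty tibble = neutral simulation.
#' @param sweep_footprint exponential decay scale (bp) of the effective
#'   selection coefficient around each sweep position (sitewise mode only).
#' @param recombination_rate per-bp per-generation crossover probability
#'   (haplotype mode).
#' @param missing_rate per-genotype missingness probability.
#' @param ancestral_freq_alpha shape of the symmetric `Beta(a, a)` ancestral
#'   frequency distribution; 0.5 gives the U-shaped spectrum typical of SNP
#'   discovery panels.
#' @param mode `"sitewise"` or `"haplotype"`.
#' @param seed RNG seed; identical seeds give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pop_a = 26, n_pop_b = 54,
                       effective_size = 500,
                       split_generations = 200,
                       n_sites = 5000,
                       chrom_length = 5e6,
                       n_chrom = 1,
                       sweep_loci = NULL,
                       sweep_footprint = 5e4,
                       recombination_rate = 1e-8,
                       missing_rate = 0.02,
                       ancestral_freq_alpha = 0.5,
                       mode = c("sitewise", "haplotype"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(sweep_loci)) {
    sweep_loci <- tibble::tibble(position = numeric(), s = numeric(),
                                 pop = character())
  }
  sweep_loci <- tibble::as_tibble(sweep_loci)
  if (nrow(sweep_loci)) {
    stopifnot(all(sweep_loci$s > 0), all(sweep_loci$pop %in% c("A", "B")))
    if (any(sweep_loci$position > chrom_length) || any(sweep_loci$position < 1)) {
      stop("sweep position outside [1, chrom_length]", call. = FALSE)
    }
    if (!"chrom" %in% names(sweep_loci)) sweep_loci$chrom <- "chr1"
  }
  stopifnot(missing_rate >= 0, missing_rate < 1, split_generations >= 0,
            effective_size >= 2, n_sites >= 1, n_chrom >= 1)
  if (mode == "haplotype" && effective_size < max(n_pop_a, n_pop_b)) {
    stop("effective_size must be >= sample size in haplotype mode", call. = FALSE)
  }
  structure(list(
    n_pop_a = n_pop_a, n_pop_b = n_pop_b, effective_size = effective_size,
    split_generations = split_generations, n_sites = n_sites,
    chrom_length = chrom_length, n_chrom = n_chrom, sweep_loci = sweep_loci,
    sweep_footprint = sweep_footprint, recombination_rate = recombination_rate,
    missing_rate = missing_rate, ancestral_freq_alpha = ancestral_freq_alpha,
    mode = mode, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic directional-selection update, vectorized over sites
select_update <- function(p, s) p * (1 + s) / (1 + s * p)

#' Simulate two diverged populations
#'
#' @param config a [sim_config()].
#' @return A list with elements `geno` (a [geno_matrix()]; samples
#'   `A_1..A_n`, `B_1..B_n`), `popmap` (tibble `sample`, `population` with
#'   labels `"A"`/`"B"`), and `truth` (per-site tibble: position, ancestral
#'   and terminal allele frequencies per deme, effective selection
#'   coefficient, and the id of the sweep each site belongs to, if any).
#' @export
simulate_two_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  per_chrom <- tabulate(rep_len(seq_len(cfg$n_chrom), cfg$n_sites),
                        nbins = cfg$n_chrom)
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(cfg$chrom_length, k, replace = FALSE))
  }))

  p0 <- stats::rbeta(cfg$n_sites, cfg$ancestral_freq_alpha,
                     cfg$ancestral_freq_alpha)
  # keep ancestral frequencies away from exact fixation
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)

  # map sweeps onto sites: nearest site on the sweep's chromosome is the
  # focal locus; ancestral frequency there resampled to >= 0.05 (standing
  # variation); s decays exponentially with distance in sitewise mode
  sweeps <- cfg$sweep_loci
  s_eff_A <- numeric(cfg$n_sites)
  s_eff_B <- numeric(cfg$n_sites)
  sweep_id <- integer(cfg$n_sites)
  focal_sites <- integer(0)
  if (nrow(sweeps)) {
    for (i in seq_len(nrow(sweeps))) {
      on_chr <- which(chrom == sweeps$chrom[i])
      if (!length(on_chr)) stop("sweep chromosome has no sites", call. = FALSE)
      focal <- on_chr[which.min(abs(pos[on_chr] - sweeps$position[i]))]
      focal_sites <- c(focal_sites, focal)
      # beneficial allele segregates as standing variation on the minor side
      while (p0[focal] < 0.05 || p0[focal] > 0.5) {
        p0[focal] <- stats::rbeta(1, cfg$ancestral_freq_alpha,
                                  cfg$ancestral_freq_alpha)
      }
      d <- abs(pos[on_chr] - pos[focal])
      se <- sweeps$s[i] * exp(-d / cfg$sweep_footprint)
      se[se < 1e-4] <- 0
      if (cfg$mode == "haplotype") {
        # linkage is explicit: selection acts on the focal locus only
        se <- ifelse(on_chr == focal, sweeps$s[i], 0)
      }
      tgt <- if (sweeps$pop[i] == "A") "A" else "B"
      if (tgt == "A") {
        upd <- pmax(s_eff_A[on_chr], se)
        sweep_id[on_chr[se > 0]] <- i
        s_eff_A[on_chr] <- upd
      } else {
        upd <- pmax(s_eff_B[on_chr], se)
        sweep_id[on_chr[se > 0]] <- i
        s_eff_B[on_chr] <- upd
      }
    }
  }

  if (cfg$mode == "sitewise") {
    out <- sim_sitewise(cfg, p0, s_eff_A, s_eff_B)
  } else {
    out <- sim_haplotype(cfg, chrom, pos, p0, focal_sites, sweeps)
  }
  dosage <- out$dosage

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[mask] <- NA_integer_
  }

  samples <- c(paste0("A_", seq_len(cfg$n_pop_a)),
               paste0("B_", seq_len(cfg$n_pop_b)))
  rownames(dosage) <- samples
  alleles <- matrix(c("A", "C", "G", "T")[
    t(replicate(cfg$n_sites, sample.int(4, 2)))], ncol = 2)

  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = alleles[, 1], alt = alleles[, 2],
                             qual = rep(100, cfg$n_sites))
  geno <- geno_matrix(dosage, variants, samples)
  popmap <- tibble::tibble(
    sample = samples,
    population = rep(c("A", "B"), c(cfg$n_pop_a, cfg$n_pop_b))
  )
  truth <- tibble::tibble(
    site = seq_len(cfg$n_sites), chrom = chrom, pos = as.integer(pos),
    p_ancestral = p0, p_a = out$pA, p_b = out$pB,
    s_eff = pmax(s_eff_A, s_eff_B),
    sweep_id = sweep_id,
    is_focal = seq_len(cfg$n_sites) %in% focal_sites
  )
  list(geno = geno, popmap = popmap, truth = truth)
}

sim_sitewise <- function(cfg, p0, s_eff_A, s_eff_B) {
  two_n <- 2L * cfg$effective_size
  pA <- p0
  pB <- p0
  selA <- which(s_eff_A > 0)
  selB <- which(s_eff_B > 0)
  for (g in seq_len(cfg$split_generations)) {
    if (length(selA)) pA[selA] <- select_update(pA[selA], s_eff_A[selA])
    if (length(selB)) pB[selB] <- select_update(pB[selB], s_eff_B[selB])
    pA <- stats::rbinom(cfg$n_sites, two_n, pA) / two_n
    pB <- stats::rbinom(cfg$n_sites, two_n, pB) / two_n
  }
  dosA <- matrix(stats::rbinom(cfg$n_pop_a * cfg$n_sites, 2L,
                               rep(pA, each = cfg$n_pop_a)),
                 nrow = cfg$n_pop_a)
  dosB <- matrix(stats::rbinom(cfg$n_pop_b * cfg$n_sites, 2L,
                               rep(pB, each = cfg$n_pop_b)),
                 nrow = cfg$n_pop_b)
  list(dosage = rbind(dosA, dosB), pA = pA, pB = pB)
}

# explicit-haplotype WF reproduction with recombination; selection weights
# parents by (1+s)^(sweep-allele count) in the deme under selection
sim_haplotype <- function(cfg, chrom, pos, p0, focal_sites, sweeps) {
  n_sites <- cfg$n_sites
  N <- cfg$effective_size
  demes <- list(
    A = matrix(stats::rbinom(2L * N * n_sites, 1L, rep(p0, each = 2L * N)),
               nrow = 2L * N),
    B = matrix(stats::rbinom(2L * N * n_sites, 1L, rep(p0, each = 2L * N)),
               nrow = 2L * N)
  )
  sel <- list(A = numeric(n_sites), B = numeric(n_sites))
  if (nrow(sweeps)) {
    for (i in seq_len(nrow(sweeps))) {
      sel[[sweeps$pop[i]]][focal_sites[i]] <-
        max(sel[[sweeps$pop[i]]][focal_sites[i]], sweeps$s[i])
    }
  }
  for (dm in c("A", "B")) {
    hap <- demes[[dm]]
    s_vec <- sel[[dm]]
    sel_sites <- which(s_vec > 0)
    for (g in seq_len(cfg$split_generations)) {
      if (length(sel_sites)) {
        cnt <- hap[seq(1, 2 * N, 2), sel_sites, drop = FALSE] +
          hap[seq(2, 2 * N, 2), sel_sites, drop = FALSE]
        w <- exp(cnt %*% log1p(s_vec[sel_sites]))
        prob <- w / sum(w)
      } else {
        prob <- NULL
      }
      mothers <- sample.int(N, N, replace = TRUE, prob = prob)
      fathers <- sample.int(N, N, replace = TRUE, prob = prob)
      nxt <- matrix(0L, 2L * N, n_sites)
      for (k in seq_len(N)) {
        nxt[2L * k - 1L, ] <- make_gamete(hap, mothers[k], pos, cfg)
        nxt[2L * k, ] <- make_gamete(hap, fathers[k], pos, cfg)
      }
      hap <- nxt
    }
    demes[[dm]] <- hap
  }
  pick <- function(hap, n) {
    ids <- sample.int(N, n, replace = FALSE)
    hap[2L * rep(ids, each = 1L) - 1L, , drop = FALSE] +
      hap[2L * ids, , drop = FALSE]
  }
  dosA <- pick(demes$A, cfg$n_pop_a)
  dosB <- pick(demes$B, cfg$n_pop_b)
  list(dosage = rbind(dosA, dosB),
       pA = colMeans(demes$A), pB = colMeans(demes$B))
}

make_gamete <- function(hap, parent, pos, cfg) {
  h1 <- hap[2L * parent - 1L, ]
  h2 <- hap[2L * parent, ]
  n_x <- stats::rpois(1, cfg$recombination_rate * cfg$chrom_length)
  use_h1 <- stats::runif(1) < 0.5
  if (n_x == 0L) return(if (use_h1) h1 else h2)
  breaks <- sort(stats::runif(n_x, 0, cfg$chrom_length))
  seg <- findInterval(pos, breaks)  # segment index per site
  take1 <- (seg %% 2L == 0L) == use_h1
  ifelse(take1, h1, h2)
}

#' Trait-cohort configuration
#'
#' @param n_group1,n_group2 design sizes of the two trait groups (defaults
#'   77 and 68, the monotocous/polytocous validation design the package
#'   emulates). Their sum must equal the number of samples labelled.
#' @param causal_snp_index column index of the causal SNP.
#' @param group2_prob per-genotype probabilities of membership in group 2 for
#'   dosages 0, 1, 2 (length-3 numeric in `[0, 1]`). Equal probabilities give
#'   a null cohort.
#' @param seed RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_group1 = 77, n_group2 = 68,
                          causal_snp_index = 1L,
                          group2_prob = c(0.1, 0.9, 0.9),
                          seed = 1L) {
  stopifnot(length(group2_prob) == 3, all(group2_prob >= 0),
            all(group2_prob <= 1))
  structure(list(n_group1 = n_group1, n_group2 = n_group2,
                 causal_snp_index = as.integer(causal_snp_index),
                 group2_prob = group2_prob, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Assign trait groups driven by one causal SNP
#'
#' Each sample is assigned to group 2 with a probability determined by its
#' genotype at the causal SNP; all other SNPs are independent of the grouping.
#' Samples with a missing causal genotype are assigned with the average of the
#' three probabilities.
#'
#' @param geno a [geno_matrix()] with `n_group1 + n_group2` samples.
#' @param config a [cohort_config()].
#' @return A tibble with columns `sample`, `group` (`"G1"`/`"G2"`).
#' @export
simulate_trait_cohort <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "cohort_config"))
  n <- length(geno$samples)
  if (n != config$n_group1 + config$n_group2) {
    stop(sprintf("matrix has %d samples but design wants %d + %d",
                 n, config$n_group1, config$n_group2), call. = FALSE)
  }
  j <- config$causal_snp_index
  if (j < 1L || j > ncol(geno$dosage)) {
    stop("causal SNP index out of range", call. = FALSE)
  }
  set.seed(config$seed)
  d <- geno$dosage[, j]
  pr <- config$group2_prob[d + 1L]
  pr[is.na(pr)] <- mean(config$group2_prob)
  grp <- ifelse(stats::runif(n) < pr, "G2", "G1")
  tibble::tibble(sample = geno$samples, group = grp)
}

#' Write a complete simulated dataset to disk
#'
#' Emits the VCF, population map, per-site truth table and a gene BED with
#' random non-overlapping intervals, one of which is forced to cover each
#' sweep locus (so the annotation stage is exercised with a known answer;
#' these genes are named `sweep_gene_<i>`).
#'
#' @param sim result of [simulate_two_pop()].
#' @param dir output directory (created if absent).
#' @param n_genes number of random gene intervals per chromosome.
#' @param gene_length gene length in bp.
#' @param config the [sim_config()] used (for sweep positions).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir, config, n_genes = 20,
                             gene_length = 2e4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "simulated.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    truth = file.path(dir, "truth.tsv"),
    genes = file.path(dir, "genes.bed")
  )
  write_vcf(sim$geno, paths["vcf"])
  write_popmap(sim$popmap, paths["popmap"])
  readr::write_tsv(sim$truth, paths["truth"])
  write_bed(simulate_genes(sim, config, n_genes, gene_length), paths["genes"])
  invisible(paths)
}

simulate_genes <- function(sim, config, n_genes = 20, gene_length = 2e4) {
  chroms <- unique(sim$geno$variants$chrom)
  L <- config$chrom_length
  genes <- dplyr::bind_rows(lapply(chroms, function(ch) {
    starts <- sort(sample.int(max(1, L - gene_length), n_genes))
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + gene_length, L),
                   name = paste0(ch, "_gene_", seq_along(starts)))
  }))
  sweeps <- config$sweep_loci
  if (nrow(sweeps)) {
    forced <- tibble::tibble(
      chrom = sweeps$chrom,
      start = pmax(0, as.integer(sweeps$position - gene_length / 2)),
      end = pmin(L, as.integer(sweeps$position + gene_length / 2)),
      name = paste0("sweep_gene_", seq_len(nrow(sweeps)))
    )
    genes <- dplyr::bind_rows(genes, forced)
  }
  dplyr::arrange(genes, .data$chrom, .data$start)
}
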