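two_pop_map <- function(n1, n2) {
  tibble::tibble(sample = paste0("S", seq_len(n1 + n2)),
                 population = rep(c("P1", "P2"), c(n1, n2)))
}

test_that("Weir-Cockerham components match hand-worked fixtures", {
  # fixed difference between populations
  g <- make_geno(matrix(c(0L, 0L, 2L, 2L), 4))
  res <- wc_fst(g, two_pop_map(2, 2))
  expect_equal(res$fst, 1)

  # worked fixture: P1 = {0/0, 0/1}, P2 = {1/1, 1/1}
  g2 <- make_geno(matrix(c(0L, 1L, 2L, 2L), 4))
  res2 <- wc_fst(g2, two_pop_map(2, 2))
  expect_equal(res2$a, 0.25)
  expect_equal(res2$b, 0)
  expect_equal(res2$c, 0.125)
  expect_equal(res2$fst, 2 / 3)

  # identical genotype multisets -> estimator non-positive
  g3 <- make_geno(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 6))
  res3 <- wc_fst(g3, two_pop_map(3, 3))
  expect_lte(res3$fst, 0)
})

test_that("wc_fst equals the independent ANOVA oracle on random fixtures", {
  set.seed(31)
  for (rep_i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    m <- sample(3:12, 1)
    d <- matrix(sample(c(0:2, NA), (n1 + n2) * m, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), n1 + n2, m)
    g <- make_geno(d)
    pm <- two_pop_map(n1, n2)
    res <- wc_fst(g, pm)
    for (j in seq_len(m)) {
      orc <- oracle_wc_site(list(d[seq_len(n1), j], d[n1 + seq_len(n2), j]))
      if (is.na(orc["a"])) {
        expect_true(is.na(res$a[j]))
      } else {
        expect_equal(res$a[j], unname(orc["a"]), tolerance = 1e-10)
        expect_equal(res$b[j], unname(orc["b"]), tolerance = 1e-10)
        expect_equal(res$c[j], unname(orc["c"]), tolerance = 1e-10)
      }
    }
  }
})

test_that("window weighted Fst is the ratio of summed components", {
  # one window holding only the fixed-difference site
  d <- matrix(c(0L, 0L, 2L, 2L), 4)
  g <- make_geno(d, pos = 10L)
  w <- window_stats(g, two_pop_map(2, 2), "P1", "P2",
                    window = 100, step = 100, min_snps = 1)
  expect_equal(nrow(w), 1)
  expect_equal(w$fst_weighted, 1)

  # three-site toy window: ratio-of-sums arithmetic
  # per-site (a, abc) targets: (0.25, 0.375), (0, 0.5), (0.1, 0.2)
  # checked by constructing sites and verifying sum(a)/sum(abc)
  set.seed(12)
  d3 <- matrix(sample(0:2, 8 * 3, replace = TRUE), 8, 3)
  g3 <- make_geno(d3, pos = c(10L, 20L, 30L))
  pm3 <- two_pop_map(4, 4)
  comp <- wc_fst(g3, pm3)
  w3 <- window_stats(g3, pm3, "P1", "P2", window = 100, step = 100,
                     min_snps = 1)
  expect_equal(w3$fst_weighted,
               sum(comp$a, na.rm = TRUE) / sum(comp$abc, na.rm = TRUE))
  expect_equal(w3$fst_mean, mean(comp$fst, na.rm = TRUE))
  expect_equal(0.35 / 1.075, 0.32558139534883722, tolerance = 1e-10)
})

test_that("overlapping windows assign each site to every covering window", {
  d <- matrix(sample(0:2, 6 * 4, replace = TRUE), 6, 4)
  g <- make_geno(d, pos = c(10L, 60L, 110L, 160L))
  w <- window_stats(g, two_pop_map(3, 3), "P1", "P2",
                    window = 100, step = 50, min_snps = 1)
  # site at 60 lies in windows [1,100] and [51,150]
  expect_equal(w$n_snps[w$start == 1], 2L)
  expect_equal(w$n_snps[w$start == 51], 2L)
  expect_equal(sum(w$n_snps), 4L + 3L)  # 4 sites, interior ones counted twice
})

test_that("windows with no SNPs are absent; low-SNP windows unrankable", {
  d <- matrix(sample(0:2, 6 * 2, replace = TRUE), 6, 2)
  g <- make_geno(d, pos = c(10L, 1000010L))
  w <- window_stats(g, two_pop_map(3, 3), "P1", "P2", min_snps = 3)
  expect_true(all(w$n_snps > 0))
  expect_true(all(!w$rankable))  # 1 SNP each < min_snps
})

test_that("pi per population and the ratio direction are as labelled", {
  # P1 polymorphic, P2 fixed -> pi_ref > 0, pi_target = 0 -> ratio Inf (high)
  d <- rbind(c(0L), c(1L), c(2L), c(0L), c(0L), c(0L))
  g <- make_geno(d, pos = 50L)
  pm <- two_pop_map(3, 3)
  w <- window_stats(g, pm, "P1", "P2", window = 100, step = 100, min_snps = 1)
  sf1 <- site_frequencies(d[1:3, , drop = FALSE])
  expect_equal(w$pi_ref, site_pi(sf1$alt_count, sf1$n_alleles) / 100)
  expect_equal(w$pi_target, 0)
  expect_equal(w$pi_ratio, Inf)

  # swapping ref and target inverts the ratio
  w2 <- window_stats(g, pm, "P2", "P1", window = 100, step = 100, min_snps = 1)
  expect_equal(w2$pi_ratio, 0)
  expect_equal(w2$fst_weighted, w$fst_weighted)
})

test_that("joint-tail selection matches enumeration on the ramp fixture", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = seq(1, by = 1000, length.out = 100),
    end = seq(1000, by = 1000, length.out = 100),
    n_snps = 10L,
    fst_weighted = (1:100) / 100,
    fst_mean = (1:100) / 100,
    pi_ref = 1, pi_target = 1,
    pi_ratio = (1:100) / 100,
    rankable = TRUE
  )
  sel <- select_candidates(w)
  # type-1 95th percentile = 0.95; strict exceedance -> windows 96..100
  expect_equal(which(sel$selected), 96:100)
  expect_true(all(sel$tail[96:100] == "high"))
})

test_that("selection equals the brute-force rule on random window sets", {
  set.seed(77)
  for (rep_i in 1:50) {
    n <- sample(20:200, 1)
    w <- tibble::tibble(
      chrom = "chr1",
      start = seq(1, by = 1000, length.out = n),
      end = seq(1000, by = 1000, length.out = n),
      n_snps = 10L,
      fst_weighted = round(runif(n), sample(c(1, 3), 1)),  # force some ties
      fst_mean = 0.1, pi_ref = 1, pi_target = 1,
      pi_ratio = round(rlnorm(n), sample(c(1, 3), 1)),
      rankable = TRUE
    )
    sel <- select_candidates(w)
    expect_equal(which(sel$selected),
                 oracle_select(w$fst_weighted, w$pi_ratio))
  }
})

test_that("identical windows yield an empty selection, not an error", {
  w <- tibble::tibble(
    chrom = "chr1", start = seq(1, by = 1000, length.out = 10),
    end = seq(1000, by = 1000, length.out = 10), n_snps = 5L,
    fst_weighted = 0.5, fst_mean = 0.5, pi_ref = 1, pi_target = 1,
    pi_ratio = 1, rankable = TRUE
  )
  sel <- select_candidates(w)
  expect_equal(sum(sel$selected), 0)
})

test_that("region merging joins overlapping/abutting same-tail windows only", {
  base <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1, 50001, 200001, 1),
    end = c(100000, 150000, 300000, 100000),
    n_snps = 10L, fst_weighted = c(0.9, 0.8, 0.7, 0.6), fst_mean = 0.5,
    pi_ref = 1, pi_target = 1, pi_ratio = 1, rankable = TRUE,
    selected = TRUE, tail = "high"
  )
  reg <- merge_regions(base)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$start[reg$chrom == "chr1"], c(1, 200001))
  expect_equal(reg$end[reg$chrom == "chr1"][1], 150000)
  expect_equal(reg$max_fst[1], 0.9)

  # same windows but different tails never merge
  base$tail <- c("high", "low", "high", "high")
  reg2 <- merge_regions(base)
  expect_equal(nrow(reg2), 4)

  # abutting windows (end + 1 == start) merge
  ab <- base[1:2, ]
  ab$tail <- "high"
  ab$start <- c(1, 100001)
  ab$end <- c(100000, 200000)
  expect_equal(nrow(merge_regions(ab)), 1)
})

test_that("gene annotation respects the BED/1-based boundary", {
  reg <- tibble::tibble(chrom = "chr1", start = 1, end = 150000,
                        n_windows = 2L, max_fst = 0.9, tail = "high")
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(149999L, 50000L, 150000L),
    end = c(160000L, 60000L, 160000L),
    name = c("one_bp_overlap", "inside", "abutting")
  )
  ann <- annotate_regions(reg, genes)
  expect_setequal(ann$genes[[1]], c("one_bp_overlap", "inside"))
})

test_that("top_sites ranks by Fst with deterministic tie-break", {
  set.seed(4)
  d <- cbind(
    c(0L, 0L, 2L, 2L),                      # fixed difference, fst = 1
    matrix(sample(0:2, 4 * 9, replace = TRUE), 4, 9)
  )
  g <- make_geno(d, pos = as.integer(seq(100, 1000, 100)))
  pm <- two_pop_map(2, 2)
  reg <- tibble::tibble(chrom = "chr1", start = 1, end = 2000,
                        n_windows = 1L, max_fst = 1, tail = "high",
                        gene_names = "gX")
  top <- top_sites(reg, g, pm, k = 5)
  expect_equal(nrow(top), 5)
  expect_equal(top$pos[1], 100L)
  expect_true(all(diff(top$fst) <= 1e-12))
  expect_warning(top_sites(reg, g, pm, k = 100), "only")
})

test_that("tidy/glance/autoplot work on a full scan object", {
  cfg <- sim_config(n_sites = 1500, chrom_length = 2e6,
                    split_generations = 120, seed = 8,
                    sweep_loci = tibble::tibble(position = 1e6, s = 0.4,
                                                pop = "B", chrom = "chr1"))
  sim <- simulate_two_pop(cfg)
  qc <- filter_maf_missing(sim$geno)
  genes <- simulate_genes(sim, cfg)
  sc <- sweep_scan(qc, sim$popmap, "A", "B", genes = genes)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("selected", "tail") %in% names(td)))
  gl <- glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_windows, nrow(td))
  expect_s3_class(autoplot(sc), "ggplot")
})
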