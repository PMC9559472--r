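test_that("contingency tables count genotypes and alleles directly", {
  # groups (A: 0/0, 0/1; B: 1/1)
  d <- matrix(c(0L, 1L, 2L), 3)
  g <- make_geno(d)
  gm <- tibble::tibble(sample = c("S1", "S2", "S3"),
                       group = c("A", "A", "B"))
  tabs <- build_tables(g, gm, 1)
  expect_equal(unname(tabs$genotype), rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(unname(tabs$allele), rbind(c(3, 1), c(0, 2)))

  # all genotypes missing in one group -> error
  d2 <- matrix(c(0L, 1L, NA), 3)
  expect_error(build_tables(make_geno(d2), gm, 1), "zero called")
})

test_that("2x2 exact p matches hypergeometric enumeration on fixtures", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(0, 0))), 1)
})

test_that("2x2 p is invariant under row swap, column swap and transpose", {
  set.seed(19)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-9)
    expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-9)
  }
})

test_that("r x c exact p matches complete enumeration for small tables", {
  expect_equal(fisher_exact_rxc(rbind(c(1, 1, 1), c(1, 1, 1))), 1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(rbind(c(5, 5, 0), c(0, 0, 0))), 1)
  set.seed(23)
  for (i in 1:30) {
    repeat {
      tab <- matrix(rpois(6, 2), 2, 3)
      if (sum(tab) > 0 && sum(tab) <= 30) break
    }
    expect_equal(fisher_exact_rxc(tab), oracle_fisher_rxc(tab),
                 tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
})

test_that("r x c with an all-zero column collapses to the 2x2 path", {
  tab <- cbind(rbind(c(4, 2), c(1, 5)), c(0, 0))
  expect_equal(fisher_exact_rxc(tab),
               fisher_exact_2x2(tab[, 1:2]), tolerance = 1e-12)
})

test_that("r x c on 2x2 input equals the 2x2 implementation", {
  set.seed(29)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2, 2)
    expect_equal(fisher_exact_rxc(tab), fisher_exact_2x2(tab),
                 tolerance = 1e-12)
  }
})

test_that("enumeration guard triggers and Monte-Carlo path works", {
  big <- matrix(500L, 2, 3)
  expect_error(fisher_exact_rxc(big), "monte_carlo")
  set.seed(1)
  p <- fisher_exact_rxc(rbind(c(200, 100, 700), c(700, 100, 200)),
                        monte_carlo = TRUE, B = 2000)
  expect_lt(p, 0.01)
})

test_that("validate_snps reports one row per SNP with significance flags", {
  set.seed(41)
  d <- matrix(sample(0:2, 60 * 25, replace = TRUE), 60, 25)
  g <- make_geno(d)
  gm <- tibble::tibble(sample = paste0("S", 1:60),
                       group = rep(c("G1", "G2"), 30))
  rep <- validate_snps(g, list(litter = gm), snp_list = 1:25)
  expect_equal(nrow(rep), 25)
  expect_true(all(c("genotype_p", "allele_p", "sig_0.05", "sig_0.01")
                  %in% names(rep)))
  expect_equal(rep$sig_0.05, rep$genotype_p < 0.05)
  # Bonferroni switch is monotone
  rep_b <- validate_snps(g, list(litter = gm), snp_list = 1:25,
                         p_adjust = "bonferroni")
  expect_true(all(rep_b$genotype_p >= rep$genotype_p - 1e-12))
})

test_that("trait cohorts: null is uniform-ish, strong effect separates", {
  # deterministic probabilities (0, 1, 1) -> perfectly separated table
  d <- matrix(c(rep(0L, 40), rep(2L, 40)), ncol = 1)
  g <- make_geno(d)
  cc <- cohort_config(n_group1 = 40, n_group2 = 40, causal_snp_index = 1,
                      group2_prob = c(0, 1, 1), seed = 5)
  gm <- simulate_trait_cohort(g, cc)
  tabs <- build_tables(g, gm, 1)
  off_diag <- tabs$genotype["G1", "hom_alt"] + tabs$genotype["G2", "hom_ref"]
  expect_equal(off_diag, 0)
  expect_lt(fisher_exact_rxc(tabs$genotype), 1e-10)

  # design-size mismatch is an error
  expect_error(
    simulate_trait_cohort(g, cohort_config(n_group1 = 10, n_group2 = 10)),
    "80 samples")
})

test_that("null causal SNP is flagged at ~alpha rate over seeds", {
  set.seed(47)
  hits <- 0
  n_seeds <- 60
  d <- matrix(sample(0:2, 145, replace = TRUE, prob = c(.36, .48, .16)),
              ncol = 1)
  g <- make_geno(d)
  for (seed in seq_len(n_seeds)) {
    cc <- cohort_config(causal_snp_index = 1,
                        group2_prob = c(0.5, 0.5, 0.5), seed = seed)
    gm <- simulate_trait_cohort(g, cc)
    tabs <- build_tables(g, gm, 1)
    if (fisher_exact_rxc(tabs$genotype) < 0.05) hits <- hits + 1
  }
  # discrete conservativeness: rate should not exceed alpha materially
  expect_lte(hits / n_seeds, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_seeds))
})
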