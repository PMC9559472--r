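# Independent brute-force oracles. These deliberately use different routes
# than the package implementation: pairwise enumeration for pi, a nested
# ANOVA on allele indicators for the Weir-Cockerham components, direct
# hypergeometric enumeration for the exact tests, and a literal sort-and-
# threshold reimplementation of the joint-tail rule.

# pi by enumerating all haplotype pairs at one site
oracle_pi <- function(j, n) {
  if (n < 2) return(NA_real_)
  alleles <- c(rep(1, j), rep(0, n - j))
  mism <- 0
  for (x in seq_len(n - 1)) {
    for (y in (x + 1):n) mism <- mism + (alleles[x] != alleles[y])
  }
  mism / choose(n, 2)
}

# Weir-Cockerham a, b, c via the nested allele-indicator ANOVA
# (mean squares among populations / among individuals / within individuals)
oracle_wc_site <- function(dos_by_pop) {
  dos_by_pop <- lapply(dos_by_pop, function(d) d[!is.na(d)])
  n_i <- vapply(dos_by_pop, length, numeric(1))
  if (any(n_i < 1)) return(c(a = NA, b = NA, c = NA, fst = NA))
  r <- length(dos_by_pop)
  n_tot <- sum(n_i)
  ybar_ij <- lapply(dos_by_pop, function(d) d / 2)
  ybar_i <- vapply(ybar_ij, mean, numeric(1))
  ybar <- sum(unlist(lapply(dos_by_pop, sum))) / (2 * n_tot)

  ssg <- sum(vapply(dos_by_pop, function(d) sum(d == 1) * 0.5, numeric(1)))
  ssi <- 2 * sum(unlist(mapply(function(y, yb) (y - yb)^2, ybar_ij, ybar_i,
                               SIMPLIFY = FALSE)))
  ssp <- 2 * sum(n_i * (ybar_i - ybar)^2)

  if (n_tot <= r) return(c(a = NA, b = NA, c = NA, fst = NA))
  msg <- ssg / n_tot
  msi <- ssi / (n_tot - r)
  msp <- ssp / (r - 1)
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)

  cc <- msg
  b <- (msi - msg) / 2
  a <- (msp - msi) / (2 * n_c)
  abc <- a + b + cc
  c(a = a, b = b, c = cc, fst = if (abc != 0) a / abc else NA)
}

# exact 2x2 p by hypergeometric enumeration over the free cell
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact r x c p by complete enumeration of margin-consistent tables
oracle_fisher_rxc <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  probs <- c()
  enum <- function(row, remaining_cols) {
    if (row == nrow(tab)) {
      m <- rbind(partial_env$rows_done, remaining_cols)
      probs <<- c(probs, exp(log_prob(m)))
      return()
    }
    cells <- enumerate_row(rs[row], remaining_cols)
    for (i in seq_len(nrow(cells))) {
      partial_env$rows_done <- rbind(partial_env$rows_done, cells[i, ])
      enum(row + 1, remaining_cols - cells[i, ])
      partial_env$rows_done <-
        partial_env$rows_done[-nrow(partial_env$rows_done), , drop = FALSE]
    }
  }
  partial_env <- new.env()
  partial_env$rows_done <- matrix(numeric(0), 0, ncol(tab))
  enum(1, cs)
  obs <- exp(log_prob(tab))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# all compositions of total `s` into cells bounded above by `caps`
enumerate_row <- function(s, caps) {
  k <- length(caps)
  if (k == 1) {
    if (s <= caps[1]) return(matrix(s, 1, 1)) else return(matrix(numeric(0), 0, 1))
  }
  out <- NULL
  for (v in 0:min(s, caps[1])) {
    rest <- enumerate_row(s - v, caps[-1])
    if (nrow(rest)) out <- rbind(out, cbind(v, rest))
  }
  if (is.null(out)) matrix(numeric(0), 0, k) else out
}

# literal reimplementation of the joint-tail selection rule
oracle_select <- function(fst, ratio, fst_q = 0.95, tails = c(0.05, 0.95)) {
  q1 <- function(x, p) sort(x)[max(1, ceiling(length(x) * p))]
  fst_thr <- q1(fst, fst_q)
  lo <- q1(ratio, tails[1])
  hi <- q1(ratio, tails[2])
  which(fst > fst_thr & (ratio < lo | ratio > hi))
}

# composite-LD r2 from explicit sums (population covariance form)
oracle_r2 <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  cov_ab <- sum(ga * gb) / n - mean(ga) * mean(gb)
  va <- sum(ga^2) / n - mean(ga)^2
  vb <- sum(gb^2) / n - mean(gb)^2
  cov_ab^2 / (va * vb)
}

# quick geno_matrix from a dosage matrix
make_geno <- function(dosage, chrom = NULL, pos = NULL, samples = NULL) {
  m <- ncol(dosage)
  geno_matrix(
    dosage,
    tibble::tibble(
      chrom = chrom %||% rep("chr1", m),
      pos = pos %||% seq_len(m),
      ref = rep("A", m), alt = rep("G", m),
      qual = rep(100, m)
    ),
    samples %||% paste0("S", seq_len(nrow(dosage)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-population dosage fixture
random_fixture <- function(n_per_pop = c(5, 5), n_sites = 20, miss = 0.1) {
  n <- sum(n_per_pop)
  d <- matrix(sample(0:2, n * n_sites, replace = TRUE), n, n_sites)
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  list(
    geno = make_geno(d),
    popmap = tibble::tibble(
      sample = paste0("S", seq_len(n)),
      population = rep(c("P1", "P2"), n_per_pop)
    )
  )
}
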