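#' Allele-sharing distance matrix
#'
#' `d(i, j)` is the mean over pairwise-complete sites of
#' `|dosage_i - dosage_j| / 2` — one minus the identity-by-state allele
#' sharing between two diploid genotypes.
#'
#' @param geno a [geno_matrix()] with >= 2 samples.
#' @return A symmetric `dist`-compatible matrix with zero diagonal, sample
#'   identifiers as dimnames.
#' @export
allele_sharing_distance <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  out <- matrix(0, n, n, dimnames = list(geno$samples, geno$samples))
  for (i in seq_len(n - 1)) {
    di <- d[i, ]
    for (j in (i + 1):n) {
      ok <- !is.na(di) & !is.na(d[j, ])
      if (!any(ok)) {
        stop(sprintf("no pairwise-complete site for samples %s and %s",
                     geno$samples[i], geno$samples[j]), call. = FALSE)
      }
      out[i, j] <- out[j, i] <- mean(abs(di[ok] - d[j, ok])) / 2
    }
  }
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix; exact on
#' additive distances. Negative branch lengths (possible on noisy input) are
#' clamped to zero.
#'
#' @param dist symmetric distance matrix with >= 3 taxa (dimnames = taxa).
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("need >= 3 taxa for a tree", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree an `ape::phylo`.
#' @param path optional output file; omitted = return the string.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site; sites are centered by twice the
#' allele frequency and scaled by `sqrt(2 p (1 - p))` (Patterson scaling);
#' monomorphic sites are dropped. Components are eigenvectors of the sample
#' covariance of the scaled matrix; each is oriented so its
#' largest-magnitude coordinate is positive.
#'
#' @param geno a [geno_matrix()] with >= 2 samples and >= 1 polymorphic site.
#' @param k number of components (must be <= samples - 1).
#' @param popmap optional tibble `sample`, `population` carried into the
#'   score table.
#' @return An object of class `geno_pca`: `scores` (tibble `sample`,
#'   `population`, `PC1..PCk`), `eigenvalues`, `var_explained`.
#' @export
genotype_pca <- function(geno, k = 2, popmap = NULL) {
  d <- geno$dosage
  n <- nrow(d)
  if (k > n - 1) stop("k must be <= samples - 1", call. = FALSE)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic site", call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(d, 2, 2 * p)          # center
  x[is.na(x)] <- 0                  # mean imputation after centering
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  cv <- tcrossprod(x) / ncol(x)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  tab <- tibble::tibble(sample = geno$samples)
  if (!is.null(popmap)) {
    tab$population <- popmap$population[match(tab$sample, popmap$sample)]
  }
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(scores))
  structure(list(
    scores = tab,
    eigenvalues = ev[seq_len(k)],
    var_explained = ev[seq_len(k)] / sum(ev)
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d components (%.1f%% variance on PC1)\n",
              nrow(x$scores), length(x$eigenvalues),
              100 * x$var_explained[1]))
  invisible(x)
}

#' Tidy PCA scores
#' @param x a `geno_pca`.
#' @param ... unused.
#' @return The per-sample score tibble.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' One-row PCA summary
#' @param x a `geno_pca`.
#' @param ... unused.
#' @return A one-row tibble with eigenvalues and variance fractions.
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  out <- tibble::as_tibble(as.list(stats::setNames(
    c(x$eigenvalues, x$var_explained),
    c(paste0("eigenvalue", seq_len(k)), paste0("var_explained", seq_len(k)))
  )))
  out
}

#' Plot PCA scores
#' @param object a `geno_pca` (needs >= 2 components).
#' @param ... unused.
#' @return A ggplot of PC1 vs PC2, colored by population when available.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, ...) {
  s <- object$scores
  aes <- if ("population" %in% names(s)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data$population)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(s, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "Genotype PCA"
    ) +
    ggplot2::theme_minimal()
}
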