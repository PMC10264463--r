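#' Genomic relationship matrix (VanRaden)
#'
#' \eqn{G = ZZ'/c} with `Z` the dosage matrix centered at twice the observed
#' allele frequencies and \eqn{c = \sum_j 2 p_j (1 - p_j)}. Monomorphic
#' markers contribute nothing and are dropped. `G` is symmetric and positive
#' semidefinite, with mean diagonal near 1 for a population evaluated at its
#' own frequencies.
#'
#' @param pop A `population` (markers are used).
#' @return The `n x n` relationship matrix.
#' @export
grm <- function(pop) {
  stopifnot(inherits(pop, "population"))
  X <- genotypes(pop, "marker")
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) {
    stop("all markers are monomorphic; G is undefined", call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / sum(2 * p * (1 - p))
  (G + t(G)) / 2
}

#' Principal-component covariates from the relationship matrix
#'
#' Eigendecomposition of `G`; the scores of the leading `K` components
#' (eigenvectors scaled by the square roots of their eigenvalues) are used as
#' fixed-effect covariates that absorb population structure - here chiefly
#' the full-sib family structure of the study design. The per-component sign
#' is fixed by making each eigenvector's largest-magnitude entry positive.
#'
#' @param G Relationship matrix from [grm()].
#' @param K Number of components (`1 <= K < n`). The study defaults are 19
#'   for the 3-major-QTL architecture and 18 for the infinitesimal one (see
#'   [default_k()]); [choose_k()] gives a variance-explained rule instead.
#' @param family_id Optional family labels stored alongside the scores (used
#'   by `autoplot`).
#' @return A `structure_pca` object: `scores` (n x K matrix), per-component
#'   `variance_explained`, `cum_variance` (cumulative fraction at K), `K`.
#' @export
pca_covariates <- function(G, K, family_id = NULL) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  n <- nrow(G)
  if (K < 1 || K >= n) {
    stop("`K` must satisfy 1 <= K < n individuals", call. = FALSE)
  }
  ee <- eigen(G, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)
  vec <- ee$vectors[, seq_len(K), drop = FALSE]
  flip <- apply(vec, 2, function(v) sign(v[which.max(abs(v))]))
  vec <- sweep(vec, 2, flip, "*")
  scores <- sweep(vec, 2, sqrt(lambda[seq_len(K)]), "*")
  colnames(scores) <- paste0("PC", seq_len(K))
  ve <- lambda / sum(lambda)
  structure(
    list(scores = scores, variance_explained = ve,
         cum_variance = sum(ve[seq_len(K)]), K = K,
         family_id = family_id),
    class = "structure_pca"
  )
}

#' @export
print.structure_pca <- function(x, ...) {
  cat("<structure_pca> K = ", x$K, " components; cumulative variance ",
      sprintf("%.1f%%", 100 * x$cum_variance), "\n", sep = "")
  invisible(x)
}

#' Study defaults for the number of structure components
#'
#' @param architecture Architecture tag.
#' @return 19 for `major3_plus97`, 18 for `infinitesimal_100`.
#' @export
default_k <- function(architecture = c("major3_plus97", "infinitesimal_100")) {
  switch(match.arg(architecture), major3_plus97 = 19L, infinitesimal_100 = 18L)
}

#' Variance-explained rule for choosing K
#'
#' Smallest `K` whose leading components explain at least `target` of the
#' genotypic variance (an alternative to a preset component count).
#'
#' @param G Relationship matrix.
#' @param target Cumulative variance fraction (default 0.85).
#' @return Integer `K`.
#' @export
choose_k <- function(G, target = 0.85) {
  stopifnot(target > 0, target < 1)
  lambda <- pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  cv <- cumsum(lambda) / sum(lambda)
  as.integer(which(cv >= target)[1])
}
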