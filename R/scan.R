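#' Genome-wide single-marker association scan
#'
#' Tests every polymorphic marker one at a time in the model
#' \deqn{Y = \mu + \alpha_j \,\mathrm{SNP}_j + \sum_{k=1}^K \beta_k
#'   \mathrm{CP}_k + \varepsilon,}
#' with the leading principal components of the genomic relationship matrix
#' as fixed structure covariates, by one of two methods:
#' \describe{
#'   \item{`"glm"`}{ordinary least squares; the marker is tested with the
#'     usual t statistic.}
#'   \item{`"qr"`}{quantile regression at level `tau`: the marker effect
#'     \eqn{\hat\alpha_j} comes from the full check-loss fit and the p-value
#'     from the regression rank-score test (one cheap reduced-model fit
#'     shared by all markers).}
#' }
#' P-values are FDR-adjusted jointly over all tested markers and a marker is
#' called significant when its q-value is at most `alpha`. Monomorphic
#' markers are skipped and listed in the `skipped` attribute.
#'
#' @param geno A `population`, or a dosage matrix (individuals x markers)
#'   with locus ids as column names.
#' @param y Phenotype vector (one value per individual, in row order).
#' @param covariates A `structure_pca` object, a numeric matrix of
#'   covariates, or `NULL` for an intercept-only null design.
#' @param method `"glm"` or `"qr"`.
#' @param tau Quantile level for `"qr"` (default 0.5).
#' @param alpha Significance level applied to q-values (default 0.01).
#' @param qvalue_method Passed to [qvalues()].
#' @param qr_effects If `TRUE` (default), the quantile scan also fits the
#'   full per-marker LP to report \eqn{\hat\alpha_j}; with `FALSE` only the
#'   rank-score p-values are computed.
#' @param marker_info Optional tibble (`locus_id`, `chrom`, `pos_cM`) mapping
#'   markers to positions when `geno` is a bare matrix (taken from the
#'   population's map otherwise).
#' @return A `gwas_scan` tibble with one row per tested marker: `locus_id`,
#'   `chrom`, `pos_cM`, `method`, `tau`, `effect`, `statistic`, `pvalue`,
#'   `qvalue`, `significant`; attributes `n`, `n_covariates`, `alpha`,
#'   `skipped`.
#' @export
gwas_scan <- function(geno, y, covariates = NULL,
                      method = c("glm", "qr"), tau = 0.5, alpha = 0.01,
                      qvalue_method = "BH", qr_effects = TRUE,
                      marker_info = NULL) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (inherits(geno, "population")) {
    marker_info <- marker_info %||% dplyr::select(
      dplyr::filter(geno$loci, .data$type == "marker"),
      "locus_id", "chrom", "pos_cM")
    M <- genotypes(geno, "marker")
  } else {
    M <- as.matrix(geno)
    if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
    marker_info <- marker_info %||% tibble(
      locus_id = colnames(M), chrom = NA_integer_,
      pos_cM = NA_real_)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(M)) {
    stop("`y` length does not match the number of individuals", call. = FALSE)
  }
  CP <- if (inherits(covariates, "structure_pca")) covariates$scores
        else if (is.null(covariates)) NULL
        else as.matrix(covariates)
  if (!is.null(CP) && nrow(CP) != length(y)) {
    stop("covariate rows do not match the number of individuals", call. = FALSE)
  }
  C <- cbind(`(Intercept)` = rep(1, length(y)), CP)
  if (qr(C)$rank < ncol(C)) {
    stop("covariate design is rank deficient", call. = FALSE)
  }

  poly <- matrixStats_colVars(M) > 0
  skipped <- tibble(locus_id = colnames(M)[!poly],
                    reason = "monomorphic in current population")
  if (!any(poly)) {
    stop("no polymorphic markers to test", call. = FALSE)
  }
  M <- M[, poly, drop = FALSE]

  if (method == "glm") {
    stats <- ols_scan_stats(y, C, M)
    tau_out <- NA_real_
  } else {
    reduced <- fit_quantile_model(y, C, tau)
    p <- rank_score_pvalues(reduced$dual, C, M, tau)
    eff <- if (qr_effects) {
      drop(cpp_rq_scan(C, M, y, tau, 1e-10, 200)$effect)
    } else {
      rep(NA_real_, ncol(M))
    }
    stats <- tibble(effect = eff, se = NA_real_,
                    statistic = attr(p, "statistic"),
                    pvalue = as.numeric(p))
    tau_out <- tau
  }
  out <- dplyr::bind_cols(
    dplyr::left_join(tibble(locus_id = colnames(M)), marker_info,
                     by = "locus_id"),
    tibble(method = method, tau = tau_out), stats
  )
  out$qvalue <- qvalues(out$pvalue, method = qvalue_method)
  out$significant <- out$qvalue <= alpha
  class(out) <- c("gwas_scan", class(out))
  attr(out, "n") <- length(y)
  attr(out, "n_covariates") <- ncol(C) - 1
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- skipped
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gwas_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gwas_scan")
  out
}

#' @export
glance.gwas_scan <- function(x, ...) {
  tibble(
    method = x$method[1], tau = x$tau[1],
    n = attr(x, "n"), n_covariates = attr(x, "n_covariates"),
    n_tested = nrow(x), n_skipped = nrow(attr(x, "skipped")),
    n_significant = sum(x$significant), alpha = attr(x, "alpha")
  )
}
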