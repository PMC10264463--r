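#' Ordinary least squares fit with a marker t-test
#'
#' Normal-equations solution of the single-marker general linear model; the
#' marker coefficient is tested with the usual t statistic (classical
#' standard error from the residual variance).
#'
#' @param y Response vector.
#' @param X Full design matrix (intercept, covariates, marker), full column
#'   rank with at least one residual degree of freedom.
#' @param marker_col Column of `X` holding the marker (default: last).
#' @return List with `coefficients`, `se`, `statistic` and `p.value` for the
#'   marker column, `residuals`, `df.residual`, `sigma2`.
#' @export
fit_ols_model <- function(y, X, marker_col = ncol(X)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) {
    stop("`y` and `X` have incompatible dimensions", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    stop("`X` is rank deficient", call. = FALSE)
  }
  if (n - p < 1) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- beta / se
  list(
    coefficients = beta, se = se,
    statistic = tstat[marker_col],
    p.value = 2 * pt(abs(tstat[marker_col]), df, lower.tail = FALSE),
    residuals = res, df.residual = df, sigma2 = sigma2
  )
}

# Vectorized per-marker OLS t-tests sharing one covariate design, via
# Frisch-Waugh projection: residualize y and every marker on [1, covariates];
# the marker slope, standard error and t statistic then equal those of the
# full model fit marker-by-marker.
ols_scan_stats <- function(y, C, M) {
  n <- length(y)
  qc <- qr(C)
  yt <- qr.resid(qc, y)
  Mt <- qr.resid(qc, M)
  sxx <- unname(colSums(Mt^2))
  beta <- unname(colSums(Mt * yt)) / sxx
  rss <- sum(yt^2) - beta^2 * sxx
  df <- n - ncol(C) - 1
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  tibble(
    effect = beta, se = se, statistic = tstat,
    pvalue = 2 * pt(abs(tstat), df, lower.tail = FALSE)
  )
}

#' FDR-adjusted q-values
#'
#' Benjamini-Hochberg step-up adjusted p-values by default (monotone,
#' order-preserving, in `[0, 1]`); optionally Storey-style q-values with a
#' point estimate \eqn{\hat\pi_0 = \min(1, \#\{p > \lambda\}/((1-\lambda)m))}
#' shrinking the adjustment when most hypotheses appear null.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda Tuning constant of the Storey \eqn{\pi_0} estimate.
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
qvalues <- function(pvalues, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  q <- p.adjust(pvalues, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
    q <- pmin(pi0 * q, 1)
  }
  q
}
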