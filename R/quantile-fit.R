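#' The check (pinball) loss
#'
#' \deqn{\rho_\tau(\varepsilon) = \tau\varepsilon \text{ if } \varepsilon \ge 0,
#'   \quad (\tau - 1)\varepsilon \text{ otherwise.}}
#' Minimizing its sum over residuals defines the \eqn{\tau}-th conditional
#' quantile fit.
#'
#' @param residual Numeric vector of residuals.
#' @param tau Quantile level in `(0, 1)`.
#' @return Non-negative losses, one per residual.
#' @export
#' @examples
#' check_loss(c(-2, 2), 0.9)  # 0.2, 1.8
check_loss <- function(residual, tau) {
  if (tau <= 0 || tau >= 1) {
    stop("`tau` must lie strictly inside (0, 1)", call. = FALSE)
  }
  ifelse(residual >= 0, tau * residual, (tau - 1) * residual)
}

#' Fit a linear quantile regression by interior-point linear programming
#'
#' Solves \eqn{\hat\theta_\tau = \arg\min_\theta \sum_i
#' \rho_\tau(y_i - x_i'\theta)} in its standard primal LP form (split
#' positive/negative residual parts) with a Mehrotra predictor-corrector
#' primal-dual interior-point method. The dual solution is returned as well:
#' at the optimum it equals \eqn{\tau} on positive residuals and
#' \eqn{\tau - 1} on negative ones, i.e. it is the regression rank-score
#' vector used by [qr_rank_score_test()].
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column), full column rank,
#'   with more rows than columns.
#' @param tau Quantile level in `(0, 1)`.
#' @param tol Relative duality-gap tolerance.
#' @param maxit Maximum interior-point iterations.
#' @return An `rq_fit` list: `coefficients`, `dual` (rank scores),
#'   `residuals`, `fitted`, `objective` (the minimized check loss),
#'   `iterations`, `converged`, `tau`.
#' @export
#' @examples
#' x <- rnorm(50)
#' f <- fit_quantile_model(2 + x + rnorm(50), cbind(1, x), tau = 0.5)
#' f$coefficients
fit_quantile_model <- function(y, X, tau, tol = 1e-10, maxit = 200) {
  if (tau <= 0 || tau >= 1) {
    stop("`tau` must lie strictly inside (0, 1)", call. = FALSE)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("`y` and `X` have incompatible dimensions", call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("`X` is rank deficient", call. = FALSE)
  }
  fit <- cpp_rq_fit(X, y, tau, tol, maxit)
  if (!fit$converged) {
    warning("interior-point solver did not reach the duality-gap tolerance in ",
            maxit, " iterations", call. = FALSE)
  }
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X) %||% paste0("b", seq_along(beta) - 1)
  structure(
    list(coefficients = beta, dual = drop(fit$dual),
         residuals = y - drop(X %*% beta), fitted = drop(X %*% beta),
         objective = fit$objective, iterations = fit$iterations,
         converged = fit$converged, tau = tau),
    class = "rq_fit"
  )
}

#' @export
print.rq_fit <- function(x, ...) {
  cat("<rq_fit> tau = ", x$tau, "; objective = ", signif(x$objective, 6),
      " (", x$iterations, " iterations)\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Rank-score test for a marker effect in quantile regression
#'
#' Regression rank-score (sign-score) test of \eqn{H_0: \alpha_j = 0} that
#' avoids estimating the error density: fit the reduced model (intercept +
#' covariates, no marker) at quantile \eqn{\tau}; take the rank scores
#' \eqn{a_i = \tau - 1\{\hat\varepsilon_i < 0\}} (the LP dual, exact on the
#' zero-residual basic observations); project the marker column off the
#' reduced design; and refer
#' \deqn{T = \frac{(\tilde x' a)^2}{\tau(1-\tau)\,\tilde x'\tilde x}}
#' to \eqn{\chi^2_1} for a two-sided p-value.
#'
#' @param y Response vector.
#' @param X_reduced Reduced design (intercept + covariates), full rank.
#' @param marker Marker dosage column to test.
#' @param tau Quantile level.
#' @return List with `statistic`, `p.value`, `score` and the reduced fit.
#' @export
qr_rank_score_test <- function(y, X_reduced, marker, tau) {
  X_reduced <- as.matrix(X_reduced)
  marker <- as.numeric(marker)
  if (qr(cbind(X_reduced, marker))$rank < ncol(X_reduced) + 1) {
    stop("marker is collinear with the reduced design", call. = FALSE)
  }
  fit <- fit_quantile_model(y, X_reduced, tau)
  p <- rank_score_pvalues(fit$dual, X_reduced, cbind(marker), tau)
  list(statistic = attr(p, "statistic")[1], p.value = p[1],
       score = attr(p, "score")[1], reduced_fit = fit)
}

# Vectorized rank-score p-values for many markers sharing one reduced fit.
# dual: rank-score vector of the reduced fit; M: n x m marker matrix.
rank_score_pvalues <- function(dual, X_reduced, M, tau) {
  Xr <- as.matrix(X_reduced)
  M <- as.matrix(M)
  proj <- solve(crossprod(Xr), crossprod(Xr, M))
  Mt <- M - Xr %*% proj
  s <- unname(drop(crossprod(Mt, dual)))
  den <- unname(colSums(Mt^2))
  stat <- ifelse(den > 0, s^2 / (tau * (1 - tau) * den), NA_real_)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  attr(p, "statistic") <- stat
  attr(p, "score") <- s
  p
}
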