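# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' LD decay plot
#'
#' Scatter of pairwise \eqn{r^2} against distance (subsampled for display),
#' the fitted decay curve, the critical \eqn{r^2} line and, when the curve
#' crosses it, the detection-window distance.
#'
#' @param pairs An `ld_pairs` tibble.
#' @param curve Optional `decay_curve` (fitted from `pairs` if omitted).
#' @param threshold Critical \eqn{r^2} level.
#' @param max_points Scatter points to display.
#' @param seed Seed for the display subsample.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(pairs, curve = NULL, threshold = 0.2,
                          max_points = 5000, seed = 1) {
  curve <- curve %||% fit_decay_curve(pairs)
  show <- as_tibble(pairs)
  if (nrow(show) > max_points) {
    show <- with_seed_maybe(seed, dplyr::slice_sample(show, n = max_points))
  }
  grid <- tibble(dist_cM = seq(0, max(pairs$dist_cM), length.out = 300))
  grid$r2 <- predict(curve, grid$dist_cM)
  w <- tryCatch(window_distance(curve, threshold), error = function(e) NA_real_)
  p <- ggplot2::ggplot(show, ggplot2::aes(x = .data$dist_cM, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_line(data = grid, colour = "red", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "genetic distance (cM)", y = expression(r^2)) +
    ggplot2::theme_minimal()
  if (is.finite(w)) {
    p <- p + ggplot2::geom_vline(xintercept = w, linetype = 3)
  }
  p
}

#' @export
autoplot.ld_pairs <- function(object, ...) plot_ld_decay(object, ...)

#' Manhattan-style plot of a scan
#'
#' \eqn{-\log_{10}} q-values along the genome, colored by chromosome, with
#' the significance level line.
#'
#' @param object A `gwas_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_scan <- function(object, ...) {
  df <- tidy(object)
  df$x <- df$pos_cM + (df$chrom - 1) * max(df$pos_cM, na.rm = TRUE) * 1.05
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                   y = -log10(pmax(.data$qvalue, 1e-300)),
                                   colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' Structure PCA plot
#'
#' First two component scores, colored by family when labels are available.
#'
#' @param object A `structure_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_pca <- function(object, ...) {
  df <- tibble(PC1 = object$scores[, 1],
               PC2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0,
               family = object$family_id %||% NA_integer_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data$family))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(colour = "family") +
    ggplot2::theme_minimal()
}

#' @export
tidy.structure_pca <- function(x, ...) {
  tibble(component = seq_along(x$variance_explained),
         variance_explained = x$variance_explained,
         cumulative = cumsum(x$variance_explained))
}

#' @export
glance.structure_pca <- function(x, ...) {
  tibble(K = x$K, cum_variance = x$cum_variance,
         n = nrow(x$scores))
}

#' Power / false-positive-rate curves across population sizes
#'
#' @param object A `scenario_result`.
#' @param metric `"power"` or `"fpr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, metric = c("power", "fpr"), ...) {
  metric <- match.arg(metric)
  s <- summarize_scenario(object)
  s$method_label <- ifelse(s$method == "qr", sprintf("QR (%.2f)", s$tau), "GLM")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$population_size,
                                  y = .data[[paste0(metric, "_mean")]],
                                  colour = .data$method_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "population size", y = metric, colour = "method") +
    ggplot2::theme_minimal()
}

#' @export
tidy.rq_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.rq_fit <- function(x, ...) {
  tibble(tau = x$tau, objective = x$objective,
         iterations = x$iterations, converged = x$converged)
}
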