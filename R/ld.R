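#' Pairwise linkage disequilibrium (r2) between markers
#'
#' Computes \eqn{r^2}, the squared Pearson correlation of allele-dosage
#' columns, for all pairs of polymorphic markers on the same chromosome.
#' Monomorphic markers (undefined correlation) are skipped with a warning
#' recording the count.
#'
#' @param pop A `population`.
#' @param max_pairs Optional cap on the number of pairs (a seeded uniform
#'   subsample is taken after computing all pairs), to bound the cost of the
#'   decay fit in large configurations.
#' @param seed Seed for the optional subsample.
#' @return An `ld_pairs` tibble: `chrom`, `locus_a`, `locus_b`, `dist_cM`,
#'   `r2`.
#' @export
pairwise_r2 <- function(pop, max_pairs = NULL, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  markers <- dplyr::filter(pop$loci, .data$type == "marker")
  X <- genotypes(pop, "marker")
  n_mono <- 0L
  res <- lapply(unique(markers$chrom), function(c) {
    idx <- which(markers$chrom == c)
    Xc <- X[, idx, drop = FALSE]
    keep <- which(matrixStats_colVars(Xc) > 0)
    n_mono <<- n_mono + (length(idx) - length(keep))
    if (length(keep) < 2) {
      return(NULL)
    }
    Xc <- Xc[, keep, drop = FALSE]
    pos <- markers$pos_cM[idx][keep]
    ids <- markers$locus_id[idx][keep]
    r2 <- cor(Xc)^2
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    tibble(
      chrom = c,
      locus_a = ids[ut[, 1]], locus_b = ids[ut[, 2]],
      dist_cM = abs(pos[ut[, 2]] - pos[ut[, 1]]),
      r2 = r2[ut]
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    stop("no valid same-chromosome marker pairs (too few polymorphic markers)",
         call. = FALSE)
  }
  out <- dplyr::filter(out, .data$dist_cM > 0)
  if (n_mono > 0) {
    warning(n_mono, " monomorphic marker(s) skipped in LD computation",
            call. = FALSE)
  }
  if (!is.null(max_pairs) && nrow(out) > max_pairs) {
    out <- with_seed_maybe(seed,
      out[sort(sample.int(nrow(out), max_pairs)), ])
  }
  class(out) <- c("ld_pairs", class(out))
  attr(out, "n_monomorphic") <- n_mono
  out
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  m <- colMeans(X)
  (colSums(X^2) - n * m^2) / (n - 1)
}

#' Fit a local-polynomial LD decay curve
#'
#' Locally weighted polynomial regression of \eqn{r^2} on genetic distance
#' (tricube weights, nearest-neighbour span), the smoother classically used
#' for LD decay plots. The fit is computed from per-distance sufficient
#' statistics, which makes evaluation cheap at arbitrary distances --
#' including below the smallest observed marker spacing, where the
#' \eqn{r^2 = 0.20} crossing typically falls on a ~1 cM grid. On interior
#' points the curve agrees with `stats::loess` (same span, degree and
#' weights); unlike `loess` it can be evaluated outside the observed
#' distance range, where the boundary-local polynomial extends smoothly.
#'
#' @param pairs An `ld_pairs` tibble.
#' @param span Fraction of pairs entering each local fit (default 0.75).
#' @param degree Local polynomial degree (1 or 2; default 2).
#' @return A `decay_curve` object; evaluate it with `predict(curve, d)`.
#' @export
fit_decay_curve <- function(pairs, span = 0.75, degree = 2) {
  stopifnot(is.data.frame(pairs), all(c("dist_cM", "r2") %in% names(pairs)))
  stopifnot(span > 0, span <= 1, degree %in% 1:2)
  d <- round(pairs$dist_cM, 9)
  stats <- dplyr::summarise(
    dplyr::group_by(tibble(d = d, r2 = pairs$r2), d),
    n = dplyr::n(), sum_r2 = sum(r2), .groups = "drop"
  )
  stats <- dplyr::arrange(stats, d)
  if (nrow(stats) < degree + 2) {
    stop("need at least ", degree + 2, " distinct distances to fit degree ",
         degree, " local polynomials", call. = FALSE)
  }
  structure(
    list(d = stats$d, n = stats$n, ybar = stats$sum_r2 / stats$n,
         n_total = sum(stats$n), span = span, degree = degree,
         range = range(stats$d)),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("<decay_curve> local polynomial (span ", x$span, ", degree ", x$degree,
      ") on ", x$n_total, " pairs over [", x$range[1], ", ", x$range[2],
      "] cM\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted LD decay curve
#'
#' @param object A `decay_curve`.
#' @param newdata Distances (cM) at which to evaluate; non-negative.
#' @param ... Unused.
#' @return Numeric vector of fitted \eqn{\hat r^2} values.
#' @export
predict.decay_curve <- function(object, newdata, ...) {
  d0 <- as.numeric(newdata)
  stopifnot(all(is.finite(d0)), all(d0 >= 0))
  q <- max(floor(object$span * object$n_total), object$degree + 1)
  vapply(d0, function(x) eval_local_poly(object, x, q), numeric(1))
}

# Tricube-weighted polynomial fit at a single evaluation point, computed on
# per-distance bins: include nearest bins until >= q pairs are covered; the
# bandwidth is the distance of the furthest included bin (its tricube weight
# vanishes, matching the span-th nearest neighbour convention).
eval_local_poly <- function(curve, x, q) {
  dist <- abs(curve$d - x)
  o <- order(dist)
  cum <- cumsum(curve$n[o])
  k <- which(cum >= q)[1]
  if (is.na(k)) k <- length(o)
  h <- dist[o[k]]
  if (h <= 0) h <- max(dist[o[min(k + 1, length(o))]], .Machine$double.eps)
  use <- which(dist <= h)
  w <- curve$n[use] * (1 - pmin(dist[use] / h, 1)^3)^3
  pos <- w > 0
  use <- use[pos]
  w <- w[pos]
  dd <- curve$d[use] - x
  X <- cbind(1, dd)
  if (curve$degree == 2) X <- cbind(X, dd^2)
  if (length(use) <= curve$degree) {
    return(sum(w * curve$ybar[use]) / sum(w))
  }
  XtW <- t(X * w)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% curve$ybar[use]),
                   error = function(e) NULL)
  if (is.null(beta)) {
    return(sum(w * curve$ybar[use]) / sum(w))
  }
  beta[1]
}

#' Detection-window distance from an LD decay curve
#'
#' The window half-width `w` is the smallest distance at which the fitted
#' decay curve falls to the critical \eqn{r^2} level (default 0.20, below
#' which linkage is conventionally taken to be eroded). Found by sign change
#' on a dense grid followed by bisection.
#'
#' @param curve A `decay_curve`.
#' @param threshold Critical \eqn{r^2} level (default 0.20).
#' @param grid_n Grid resolution for bracketing the crossing.
#' @return The window distance in cM.
#' @export
window_distance <- function(curve, threshold = 0.2, grid_n = 400) {
  stopifnot(inherits(curve, "decay_curve"), threshold > 0, threshold < 1)
  grid <- seq(0, curve$range[2], length.out = grid_n)
  vals <- predict(curve, grid)
  above <- vals > threshold
  if (!above[1]) {
    stop("fitted curve is already below the r2 threshold at distance 0; ",
         "no detection window (lower the threshold or refit)", call. = FALSE)
  }
  cross <- which(!above)[1]
  if (is.na(cross)) {
    stop("fitted curve never falls below the r2 threshold within the ",
         "observed distance range; no detection window", call. = FALSE)
  }
  uniroot(function(x) predict(curve, x) - threshold,
          lower = grid[cross - 1], upper = grid[cross],
          tol = 1e-6)$root
}

#' Map markers to QTL detection windows
#'
#' Given the window half-width `w`, a marker is QTL-associated if and only if
#' it lies within `w` cM of at least one target QTL on the same chromosome.
#' One window `[pos - w, pos + w]` is recorded per target QTL; power is later
#' scored per window and the false-positive rate over the non-associated
#' markers.
#'
#' @param map A `genome_map`.
#' @param w Window half-width in cM (> 0).
#' @param targets Target QTLs: a tibble with at least `chrom` and `pos_cM`
#'   (e.g. the major genes of an `effect_set`, or `map_qtls(map)`). Defaults
#'   to all QTLs of the map.
#' @return An `association_map`: list with `w`, a `markers` tibble carrying
#'   the `associated` flag, and a `windows` tibble (one row per target QTL
#'   with its member-marker count).
#' @export
qtl_marker_association <- function(map, w, targets = NULL) {
  stopifnot(inherits(map, "genome_map"))
  if (!is.numeric(w) || length(w) != 1 || w <= 0) {
    stop("`w` must be a positive window distance in cM", call. = FALSE)
  }
  targets <- targets %||% map_qtls(map)
  if (nrow(targets) == 0) {
    stop("empty target QTL set", call. = FALSE)
  }
  markers <- map_markers(map)
  assoc <- rep(FALSE, nrow(markers))
  n_in <- integer(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    hit <- markers$chrom == targets$chrom[i] &
      abs(markers$pos_cM - targets$pos_cM[i]) <= w
    assoc <- assoc | hit
    n_in[i] <- sum(hit)
  }
  id_col <- if ("qtl_id" %in% names(targets)) targets$qtl_id else targets$locus_id
  structure(
    list(
      w = w,
      markers = dplyr::mutate(markers, associated = assoc),
      windows = tibble(
        qtl_id = id_col, chrom = targets$chrom,
        lo = targets$pos_cM - w, hi = targets$pos_cM + w,
        n_markers = n_in
      )
    ),
    class = "association_map"
  )
}

#' @export
print.association_map <- function(x, ...) {
  cat("<association_map> w = ", signif(x$w, 4), " cM; ",
      sum(x$markers$associated), "/", nrow(x$markers),
      " markers associated across ", nrow(x$windows), " QTL windows\n",
      sep = "")
  invisible(x)
}
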