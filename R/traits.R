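#' Assign additive QTL effects under a genetic architecture
#'
#' Effects are drawn i.i.d. normal with zero mean and then rescaled to match
#' the architecture's variance partition in the supplied base population:
#' \describe{
#'   \item{`infinitesimal_100`}{all QTLs receive a small effect from the same
#'     normal law (no rescaling needed; the phenotype's error variance is
#'     calibrated to the target heritability downstream, so the absolute
#'     effect scale is immaterial).}
#'   \item{`major3_plus97`}{three QTLs (drawn at random among the polymorphic
#'     ones) are designated major genes and their effects rescaled so the
#'     realized genetic variance of the major component equals that of the 97
#'     minor loci, i.e. the major genes account for ~50% of the genetic
#'     variability. Variance accounting uses the realized (LD-aware) variance
#'     of the genetic values in `base_pop`, not idealized 2pq sums.}
#' }
#'
#' @param map A `genome_map`.
#' @param base_pop The `population` in which variance shares are computed
#'   (the study population).
#' @param architecture Architecture tag; defaults to the map's.
#' @param seed Optional integer seed.
#' @return An `effect_set` tibble: `qtl_id`, `chrom`, `pos_cM`, `effect`,
#'   `is_major`, `polymorphic`, with the architecture as an attribute.
#' @export
assign_qtl_effects <- function(map, base_pop, architecture = map$architecture,
                               seed = NULL) {
  stopifnot(inherits(map, "genome_map"), inherits(base_pop, "population"))
  architecture <- match.arg(architecture, c("major3_plus97", "infinitesimal_100"))
  qtls <- map_qtls(map)
  Q <- genotypes(base_pop, "qtl")[, qtls$locus_id, drop = FALSE]
  poly <- apply(Q, 2, var) > 0
  if (!any(poly)) {
    stop("all QTLs are monomorphic in the base population", call. = FALSE)
  }
  with_seed_maybe(seed, {
    effect <- rnorm(nrow(qtls))
    is_major <- rep(FALSE, nrow(qtls))
    if (architecture == "major3_plus97") {
      if (sum(poly) < 4) {
        stop("major3_plus97 needs at least 3 polymorphic major QTLs plus minor loci",
             call. = FALSE)
      }
      is_major[sample(which(poly), 3)] <- TRUE
      g_minor <- drop(Q[, !is_major, drop = FALSE] %*% effect[!is_major])
      g_major <- drop(Q[, is_major, drop = FALSE] %*% effect[is_major])
      vM <- var(g_major)
      vm <- var(g_minor)
      cv <- cov(g_major, g_minor)
      if (vM <= 0 || vm <= 0) {
        stop("major- or minor-gene genetic variance is zero; cannot rescale",
             call. = FALSE)
      }
      # scale s solving var(s g_M) = 0.5 var(s g_M + g_m), i.e. the major
      # genes account for exactly half of the realized genetic variance
      # including their LD covariance with the minor background
      s <- (cv + sqrt(cv^2 + vM * vm)) / vM
      effect[is_major] <- effect[is_major] * s
    }
    out <- dplyr::mutate(
      dplyr::select(qtls, "locus_id", "chrom", "pos_cM"),
      effect = effect, is_major = is_major, polymorphic = poly
    )
    out <- dplyr::rename(out, qtl_id = "locus_id")
    attr(out, "architecture") <- architecture
    class(out) <- c("effect_set", class(out))
    out
  })
}

#' Genetic values under the additive model
#'
#' \eqn{g_i = \sum_q x_{iq} \beta_q} with \eqn{x_{iq}} the QTL allele dosage.
#'
#' @param pop A `population`.
#' @param effects An `effect_set`.
#' @return Numeric vector of per-individual genotypic values.
#' @export
genetic_values <- function(pop, effects) {
  stopifnot(inherits(pop, "population"), inherits(effects, "effect_set"))
  Q <- genotypes(pop, "qtl")
  if (!all(effects$qtl_id %in% colnames(Q))) {
    stop("effect set refers to QTLs absent from the population", call. = FALSE)
  }
  drop(Q[, effects$qtl_id, drop = FALSE] %*% effects$effect)
}

#' Error variance for a target broad-sense heritability
#'
#' \eqn{\sigma^2_e = \mathrm{var}(g)\,(1 - h^2)/h^2}, so that
#' \eqn{h^2 = \mathrm{var}(g) / (\mathrm{var}(g) + \sigma^2_e)} holds exactly
#' for the realized genetic variance.
#'
#' @param genetic_values Numeric vector of genotypic values.
#' @param h2_target Broad-sense heritability in `(0, 1)`.
#' @return The error variance \eqn{\sigma^2_e}.
#' @export
#' @examples
#' calibrate_error_variance(rnorm(100), 0.5)
calibrate_error_variance <- function(genetic_values, h2_target) {
  if (h2_target <= 0 || h2_target >= 1) {
    stop("`h2_target` must lie strictly inside (0, 1)", call. = FALSE)
  }
  vg <- var(genetic_values)
  if (!is.finite(vg) || vg <= 0) {
    stop("genetic values have zero variance; heritability undefined",
         call. = FALSE)
  }
  vg * (1 - h2_target) / h2_target
}

#' Simulate phenotypes
#'
#' \eqn{Y_i = g_i + e_i} with independent \eqn{e_i \sim N(0, \sigma^2_e)}.
#'
#' @param genetic_values Numeric vector of genotypic values.
#' @param sigma2_e Error variance (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(genetic_values, sigma2_e, seed = NULL) {
  if (sigma2_e < 0) {
    stop("`sigma2_e` must be non-negative", call. = FALSE)
  }
  with_seed_maybe(seed,
    genetic_values + rnorm(length(genetic_values), 0, sqrt(sigma2_e)))
}

#' Simulate a complete trait on a population
#'
#' Convenience wrapper: assigns QTL effects under the architecture, computes
#' genetic values, calibrates the error variance to the target heritability,
#' and draws phenotypes.
#'
#' @param pop The study `population`.
#' @param map Its `genome_map`.
#' @param h2 Target broad-sense heritability.
#' @param architecture Architecture tag; defaults to the map's.
#' @param seed Optional integer seed (effects and phenotypes use derived
#'   sub-seeds).
#' @return A `trait_model` list: `effects`, `genetic_values`, `sigma2_e`,
#'   `h2_target`, and a `phenotypes` tibble (`id`, `family_id`,
#'   `genetic_value`, `phenotype`).
#' @export
simulate_trait <- function(pop, map, h2, architecture = map$architecture,
                           seed = NULL) {
  eff_seed <- if (is.null(seed)) NULL else derive_seed(seed, .stage[["effects"]])
  phe_seed <- if (is.null(seed)) NULL else derive_seed(seed, .stage[["phenotype"]])
  effects <- assign_qtl_effects(map, pop, architecture, seed = eff_seed)
  g <- genetic_values(pop, effects)
  sigma2_e <- calibrate_error_variance(g, h2)
  y <- simulate_phenotypes(g, sigma2_e, seed = phe_seed)
  structure(
    list(
      effects = effects,
      genetic_values = g,
      sigma2_e = sigma2_e,
      h2_target = h2,
      phenotypes = tibble(id = pop$id, family_id = pop$family_id,
                          genetic_value = g, phenotype = y)
    ),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> ", attr(x$effects, "architecture"), "; h2 target ",
      x$h2_target, "; var(g) = ", signif(var(x$genetic_values), 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4), "; n = ",
      nrow(x$phenotypes), "\n", sep = "")
  invisible(x)
}
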