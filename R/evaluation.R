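#' Simulation configuration
#'
#' Bundle of generator and analysis defaults describing the study design:
#' a 10 x 200 cM genome carrying 2000 SNPs (one per cM) and 100 QTLs; a
#' composite of 5000 individuals in 100 base families from two strongly
#' diverged parental populations, advanced by 5 generations of random
#' mating; a study sample of 20 full-sib families of 50; LOESS-style LD
#' decay fitting (span 0.75, degree 2) with the r2 = 0.20 window threshold.
#'
#' @param n_chromosomes,chrom_length_cM,markers_per_chrom,spacing_cM,n_qtl
#'   Genome layout, see [build_genome_map()].
#' @param composite_size,n_generations,n_families_base Composite design, see
#'   [simulate_composite()].
#' @param n_families,family_size Study sample, see
#'   [sample_fullsib_families()].
#' @param law Parental allele-frequency law, see [freq_law()].
#' @param ld_span,ld_degree,r2_threshold LD decay fit and window threshold.
#' @param max_pairs Optional cap on LD pairs, see [pairwise_r2()].
#' @param K Number of structure PCs; `NULL` means the architecture default
#'   ([default_k()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 10, chrom_length_cM = 200,
                       markers_per_chrom = 200, spacing_cM = 1, n_qtl = 100,
                       composite_size = 5000, n_generations = 5,
                       n_families_base = 100, n_families = 20,
                       family_size = 50, law = freq_law("divergent"),
                       ld_span = 0.75, ld_degree = 2, r2_threshold = 0.2,
                       max_pairs = NULL, K = NULL) {
  structure(
    list(n_chromosomes = n_chromosomes, chrom_length_cM = chrom_length_cM,
         markers_per_chrom = markers_per_chrom, spacing_cM = spacing_cM,
         n_qtl = n_qtl, composite_size = composite_size,
         n_generations = n_generations, n_families_base = n_families_base,
         n_families = n_families, family_size = family_size, law = law,
         ld_span = ld_span, ld_degree = ld_degree,
         r2_threshold = r2_threshold, max_pairs = max_pairs, K = K),
    class = "sim_config"
  )
}

#' Simulate the full study population for one replicate
#'
#' Runs the generator chain genome map -> parental frequencies -> composite
#' -> full-sib study sample, each stage on its own derived seed stream.
#'
#' @param architecture Architecture tag.
#' @param config A [sim_config()].
#' @param seed Integer master seed of the replicate.
#' @return A list: `map`, `freqs`, `composite`, `population` (the full-sib
#'   study sample).
#' @export
simulate_study_population <- function(architecture = c("major3_plus97",
                                                       "infinitesimal_100"),
                                      config = sim_config(), seed = 1) {
  architecture <- match.arg(architecture)
  map <- build_genome_map(
    n_chrom = config$n_chromosomes, chrom_length_cM = config$chrom_length_cM,
    markers_per_chrom = config$markers_per_chrom,
    spacing_cM = config$spacing_cM, n_qtl = config$n_qtl,
    architecture = architecture, seed = derive_seed(seed, .stage[["map"]])
  )
  freqs <- simulate_parental_pops(map, config$law,
                                  seed = derive_seed(seed, .stage[["parents"]]))
  composite <- simulate_composite(
    map, freqs, composite_size = config$composite_size,
    n_generations = config$n_generations,
    n_families_base = config$n_families_base,
    seed = derive_seed(seed, .stage[["composite"]])
  )
  population <- sample_fullsib_families(
    composite, map, n_families = config$n_families,
    family_size = config$family_size,
    seed = derive_seed(seed, .stage[["families"]])
  )
  list(map = map, freqs = freqs, composite = composite,
       population = population)
}

#' QTL detection power of a scan
#'
#' Proportion of the pre-established QTL detection windows that contain at
#' least one significant marker.
#'
#' @param scan A `gwas_scan`.
#' @param assoc An `association_map` sharing the scan's marker universe.
#' @return Power in `[0, 1]`.
#' @export
detection_power <- function(scan, assoc) {
  stopifnot(inherits(scan, "gwas_scan"), inherits(assoc, "association_map"))
  if (nrow(assoc$windows) == 0) {
    stop("association map has no QTL windows", call. = FALSE)
  }
  sig <- dplyr::filter(tidy(scan), .data$significant)
  hit <- vapply(seq_len(nrow(assoc$windows)), function(i) {
    any(sig$chrom == assoc$windows$chrom[i] &
          sig$pos_cM >= assoc$windows$lo[i] &
          sig$pos_cM <= assoc$windows$hi[i])
  }, logical(1))
  mean(hit)
}

#' False-positive rate of a scan
#'
#' Ratio of significant non-QTL-associated markers to all non-associated
#' markers. Markers skipped by the scan (monomorphic) enter neither the
#' numerator nor the denominator.
#'
#' @inheritParams detection_power
#' @return False-positive rate in `[0, 1]`.
#' @export
false_positive_rate <- function(scan, assoc) {
  stopifnot(inherits(scan, "gwas_scan"), inherits(assoc, "association_map"))
  tab <- dplyr::inner_join(
    dplyr::select(tidy(scan), "locus_id", "significant"),
    dplyr::select(assoc$markers, "locus_id", "associated"),
    by = "locus_id"
  )
  nonassoc <- dplyr::filter(tab, !.data$associated)
  if (nrow(nonassoc) == 0) {
    stop("no non-associated markers; false-positive rate undefined",
         call. = FALSE)
  }
  mean(nonassoc$significant)
}

#' Scenario specification
#'
#' One cell (or a nested-size series) of the study grid: an architecture, a
#' heritability, population sizes, the scan methods, and the replicate
#' count. The full study crosses 2 architectures x 2 heritabilities
#' (0.30, 0.50) x 9 population sizes (1000 down to 200 by 100), with four
#' methods per scenario (QR at tau = 0.10, 0.50, 0.90 and the GLM).
#'
#' @param architecture Architecture tag.
#' @param h2 Broad-sense heritability in `(0, 1)`.
#' @param population_size Vector of sizes; within a replicate the sizes are
#'   nested (each obtained from the previous by proportional downsampling).
#' @param methods Tibble with columns `method` and `tau` (NA for glm), e.g.
#'   [method_grid()].
#' @param alpha Significance level on q-values.
#' @param n_replicates Number of independent replicates.
#' @param master_seed Master seed; replicate r uses `derive_seed(master_seed, r)`.
#' @param config A [sim_config()].
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(architecture = c("major3_plus97", "infinitesimal_100"),
                          h2 = 0.3, population_size = 1000,
                          methods = method_grid(), alpha = 0.01,
                          n_replicates = 10, master_seed = 1,
                          config = sim_config()) {
  architecture <- match.arg(architecture)
  stopifnot(h2 > 0, h2 < 1, all(population_size >= 2),
            n_replicates >= 1)
  max_n <- config$n_families * config$family_size
  if (any(population_size > max_n)) {
    stop("population sizes exceed the study sample (", max_n, ")",
         call. = FALSE)
  }
  structure(
    list(architecture = architecture, h2 = h2,
         population_size = sort(unique(population_size), decreasing = TRUE),
         methods = methods, alpha = alpha, n_replicates = n_replicates,
         master_seed = master_seed, config = config),
    class = "scenario_spec"
  )
}

#' Scan-method grid
#'
#' @param taus Quantile levels for the QR scans.
#' @param glm Include the GLM (OLS) scan.
#' @return Tibble with columns `method`, `tau`.
#' @export
method_grid <- function(taus = c(0.10, 0.50, 0.90), glm = TRUE) {
  out <- tibble(method = rep("qr", length(taus)), tau = as.numeric(taus))
  if (glm) out <- dplyr::bind_rows(out, tibble(method = "glm", tau = NA_real_))
  out
}

#' Run a simulation scenario
#'
#' For each replicate: simulate the study population and trait, then for
#' each (nested) population size recompute the LD decay window, the
#' structure PCs, and every configured scan, scoring QTL detection power and
#' the false-positive rate against the window map. Detection targets are the
#' 3 major genes under `major3_plus97` and all QTLs under
#' `infinitesimal_100`; non-associated markers are all markers outside the
#' target windows.
#'
#' @param spec A [scenario_spec()].
#' @param verbose Print per-replicate progress.
#' @return A `scenario_result` tibble: one row per replicate x size x
#'   method, with `power`, `fpr`, `window_cM`, `n_significant`, `n_tested`.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- spec$config
  rows <- list()
  for (r in seq_len(spec$n_replicates)) {
    seed_r <- derive_seed(spec$master_seed, r)
    sim <- simulate_study_population(spec$architecture, cfg, seed = seed_r)
    trait <- simulate_trait(sim$population, sim$map, spec$h2, seed = seed_r)
    targets <- scenario_targets(sim$map, trait$effects)
    K <- cfg$K %||% default_k(spec$architecture)
    y_all <- trait$phenotypes$phenotype
    pop <- sim$population
    for (n_target in spec$population_size) {
      pop <- downsample(pop, n_target,
                        seed = derive_seed(seed_r, .stage[["downsample"]], n_target))
      y <- y_all[pop$id]
      pairs <- pairwise_r2(pop, max_pairs = cfg$max_pairs,
                           seed = derive_seed(seed_r, .stage[["ld"]], n_target))
      curve <- fit_decay_curve(pairs, span = cfg$ld_span,
                               degree = cfg$ld_degree)
      w <- window_distance(curve, threshold = cfg$r2_threshold)
      assoc <- qtl_marker_association(sim$map, w, targets = targets)
      G <- grm(pop)
      pca <- pca_covariates(G, K, family_id = pop$family_id)
      for (m in seq_len(nrow(spec$methods))) {
        method <- spec$methods$method[m]
        tau <- spec$methods$tau[m]
        scan <- gwas_scan(pop, y, covariates = pca, method = method,
                          tau = if (is.na(tau)) 0.5 else tau,
                          alpha = spec$alpha)
        rows[[length(rows) + 1]] <- tibble(
          architecture = spec$architecture, h2 = spec$h2,
          population_size = n_target, replicate = r,
          method = method, tau = tau,
          power = detection_power(scan, assoc),
          fpr = false_positive_rate(scan, assoc),
          window_cM = w, n_significant = sum(scan$significant),
          n_tested = nrow(scan), cum_var_pca = pca$cum_variance
        )
      }
      if (verbose) {
        message("replicate ", r, " size ", n_target, " done")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_result", class(out))
  attr(out, "spec") <- spec
  out
}

# Detection targets per architecture: the major genes, or every QTL.
scenario_targets <- function(map, effects) {
  if (attr(effects, "architecture") == "major3_plus97") {
    dplyr::filter(effects, .data$is_major)
  } else {
    effects
  }
}

#' Summarize a scenario result over replicates
#'
#' Mean and standard error (sample SD over replicates divided by sqrt of the
#' replicate count) of power and false-positive rate for every method and
#' population size.
#'
#' @param result A `scenario_result` (or a row-bound collection of them).
#' @return A tibble with one row per architecture x h2 x method x size.
#' @export
summarize_scenario <- function(result) {
  se <- function(x) sd(x) / sqrt(length(x))
  dplyr::summarise(
    dplyr::group_by(as_tibble(result), .data$architecture, .data$h2,
                    .data$method, .data$tau, .data$population_size),
    n_replicates = dplyr::n(),
    power_mean = mean(.data$power), power_se = se(.data$power),
    fpr_mean = mean(.data$fpr), fpr_se = se(.data$fpr),
    window_mean = mean(.data$window_cM),
    .groups = "drop"
  )
}

#' @export
tidy.scenario_result <- function(x, ...) summarize_scenario(x)

#' @export
glance.scenario_result <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble(
    architecture = spec$architecture, h2 = spec$h2,
    n_sizes = length(spec$population_size),
    n_methods = nrow(spec$methods),
    n_replicates = spec$n_replicates, master_seed = spec$master_seed
  )
}

#' Study summary tables of power and false-positive rate
#'
#' Lays the per-scenario summaries out as the study's two tables: rows are
#' architecture x heritability x method, columns are population sizes, cells
#' are `mean +/- SE` strings; the long machine-readable summary is returned
#' alongside.
#'
#' @param results A `scenario_result` or a list of them.
#' @return List with `power` and `fpr` wide tibbles plus the `long` summary.
#' @export
make_tables <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  long <- dplyr::bind_rows(lapply(results, summarize_scenario))
  if (nrow(long) == 0) {
    stop("no scenario results supplied", call. = FALSE)
  }
  long <- dplyr::mutate(
    long,
    method_label = ifelse(.data$method == "qr",
                          sprintf("QR (%.2f)", .data$tau), "GLM")
  )
  widen <- function(value, se) {
    cells <- dplyr::mutate(
      long,
      cell = sprintf("%.2f ± %.2f", .data[[value]], .data[[se]])
    )
    tidyr::pivot_wider(
      dplyr::select(cells, "architecture", "h2", "method_label",
                    "population_size", "cell"),
      names_from = "population_size", values_from = "cell",
      names_prefix = "N"
    )
  }
  list(power = widen("power_mean", "power_se"),
       fpr = widen("fpr_mean", "fpr_se"),
       long = dplyr::select(long, -"method_label"))
}

#' Write study tables to CSV
#'
#' @param tables Output of [make_tables()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    power = file.path(dir, "table1_power.csv"),
    fpr = file.path(dir, "table2_fpr.csv"),
    long = file.path(dir, "results_long.csv")
  )
  readr::write_csv(tables$power, paths[["power"]])
  readr::write_csv(tables$fpr, paths[["fpr"]])
  readr::write_csv(tables$long, paths[["long"]])
  invisible(paths)
}

#' The full 36-scenario study grid
#'
#' @param h2 Heritability levels.
#' @param sizes Population sizes.
#' @param architectures Architecture tags.
#' @param ... Passed to [scenario_spec()] (methods, replicates, seed, config).
#' @return List of `scenario_spec`s (one per architecture x h2; each spec
#'   carries the nested size series).
#' @export
study_grid <- function(h2 = c(0.30, 0.50), sizes = seq(1000, 200, by = -100),
                       architectures = c("major3_plus97", "infinitesimal_100"),
                       ...) {
  specs <- list()
  for (a in architectures) {
    for (h in h2) {
      specs[[paste(a, h, sep = "_")]] <-
        scenario_spec(architecture = a, h2 = h, population_size = sizes, ...)
    }
  }
  specs
}
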