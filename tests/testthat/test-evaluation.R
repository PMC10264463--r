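test_that("power and false-positive definitions match set-arithmetic oracles", {
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 40,
                          markers_per_chrom = 40, spacing_cM = 1, n_qtl = 5,
                          seed = 71)
  pop <- random_pop(map, n = 80, seed = 71)
  assoc <- qtl_marker_association(map, w = 2.5)
  set.seed(72)
  for (rep in 1:5) {
    y <- rnorm(80)
    scan <- gwas_scan(pop, y, method = "glm")
    # impose an arbitrary significance pattern to exercise the definitions
    scan$significant <- runif(nrow(scan)) < 0.15
    expect_equal(detection_power(scan, assoc), power_oracle(scan, assoc))
    expect_equal(false_positive_rate(scan, assoc), fpr_oracle(scan, assoc))
  }
  scan$significant <- FALSE
  expect_equal(detection_power(scan, assoc), 0)
  expect_equal(false_positive_rate(scan, assoc), 0)
  # saturation: everything significant
  scan$significant <- TRUE
  expect_equal(false_positive_rate(scan, assoc), 1)
  wide <- qtl_marker_association(map, w = 5)  # every window holds markers
  expect_true(all(wide$windows$n_markers >= 1))
  expect_equal(detection_power(scan, wide), 1)
  # hand case: significant markers in 2 of 5 windows
  scan$significant <- FALSE
  two <- c(which(assoc$windows$n_markers > 0)[1:2])
  for (i in two) {
    in_win <- scan$chrom == assoc$windows$chrom[i] &
      scan$pos_cM >= assoc$windows$lo[i] & scan$pos_cM <= assoc$windows$hi[i]
    scan$significant[which(in_win)[1]] <- TRUE
  }
  expect_equal(detection_power(scan, assoc), 2 / 5)
})

test_that("scenario runs are deterministic and their summaries consistent", {
  spec <- scenario_spec("major3_plus97", h2 = 0.5,
                        population_size = c(100, 60),
                        methods = method_grid(taus = 0.5),
                        n_replicates = 2, master_seed = 7,
                        config = small_config())
  r1 <- run_scenario(spec)
  r2 <- run_scenario(spec)
  expect_equal(as_tibble(r1), as_tibble(r2))
  expect_equal(nrow(r1), 2 * 2 * 2)  # replicates x sizes x methods
  expect_true(all(r1$power >= 0 & r1$power <= 1))
  expect_true(all(r1$fpr >= 0 & r1$fpr <= 1))
  s <- summarize_scenario(r1)
  expect_true(all(s$n_replicates == 2))
  expect_true(all(s$power_se >= 0))
  # manual check of one summary cell
  cell <- r1[r1$method == "glm" & r1$population_size == 100, ]
  expect_equal(s$power_mean[s$method == "glm" & s$population_size == 100],
               mean(cell$power))

  tabs <- make_tables(r1)
  expect_equal(nrow(tabs$power), 2)      # QR(0.5) and GLM rows
  expect_true(all(c("N100", "N60") %in% names(tabs$power)))
  # round trip through CSV
  dir <- file.path(tempdir(), "qrgwas-tables")
  paths <- write_tables(tabs, dir)
  back <- readr::read_csv(paths[["long"]], show_col_types = FALSE)
  expect_equal(back$power_mean, tabs$long$power_mean)
})

test_that("windows widen and GLM power falls as the population shrinks", {
  cfg <- sim_config(n_chromosomes = 5, chrom_length_cM = 100,
                    markers_per_chrom = 100, spacing_cM = 1, n_qtl = 40,
                    composite_size = 1200, n_generations = 3,
                    n_families_base = 60, n_families = 20, family_size = 25)
  spec <- scenario_spec("infinitesimal_100", h2 = 0.7,
                        population_size = c(500, 140),
                        methods = method_grid(taus = NULL, glm = TRUE),
                        n_replicates = 5, master_seed = 11, config = cfg)
  res <- run_scenario(spec)
  s <- summarize_scenario(res)
  w_large <- s$window_mean[s$population_size == 500]
  w_small <- s$window_mean[s$population_size == 140]
  expect_gte(w_small, w_large)
  p_large <- s$power_mean[s$population_size == 500]
  p_small <- s$power_mean[s$population_size == 140]
  expect_lte(p_small, p_large)
})
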