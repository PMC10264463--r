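test_that("the GLM scan reproduces per-marker OLS oracles exactly", {
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 40,
                          markers_per_chrom = 20, spacing_cM = 2, n_qtl = 3,
                          seed = 61)
  pop <- random_pop(map, n = 150, seed = 61)
  set.seed(62)
  y <- rnorm(150)
  CP <- matrix(rnorm(150 * 3), 150)
  scan <- gwas_scan(pop, y, covariates = CP, method = "glm")
  M <- genotypes(pop, "marker")
  for (j in sample(nrow(scan), 8)) {
    id <- scan$locus_id[j]
    o <- fit_ols_model(y, cbind(1, CP, M[, id]))
    expect_equal(scan$pvalue[j], o$p.value, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(scan$effect[j], unname(o$coefficients[5]), tolerance = 1e-10)
  }
  expect_equal(scan$qvalue, qvalues(scan$pvalue))
  expect_equal(scan$significant, scan$qvalue <= 0.01)
})

test_that("null scans call almost nothing; a huge QTL is found by both methods", {
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 60,
                          markers_per_chrom = 60, spacing_cM = 1, n_qtl = 1,
                          seed = 63)
  # null: phenotype independent of genotype
  n_sig <- vapply(1:3, function(s) {
    pop <- random_pop(map, n = 100, seed = s)
    y <- qrgwas:::with_seed_maybe(100 + s, rnorm(100))
    sum(gwas_scan(pop, y, method = "glm")$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 1)

  # positive control: one QTL at h2 = 0.9 in an LD-rich population
  cfg <- small_config(n_qtl = 1)
  sim <- simulate_study_population("infinitesimal_100", cfg, seed = 64)
  trait <- simulate_trait(sim$population, sim$map, h2 = 0.9, seed = 64)
  pca <- pca_covariates(grm(sim$population), 5)
  q <- map_qtls(sim$map)
  mk <- map_markers(sim$map)
  near_ids <- mk$locus_id[mk$chrom == q$chrom &
                            abs(mk$pos_cM - q$pos_cM) <= 1.5]
  for (m in c("glm", "qr")) {
    s <- gwas_scan(sim$population, trait$phenotypes$phenotype, pca,
                   method = m, tau = 0.5, qr_effects = FALSE)
    expect_true(any(s$significant[s$locus_id %in% near_ids]))
  }
})

test_that("scan output is invariant to marker order and logs skipped markers", {
  map <- build_genome_map(n_chrom = 1, chrom_length_cM = 30,
                          markers_per_chrom = 30, spacing_cM = 1, n_qtl = 1,
                          seed = 65)
  pop <- random_pop(map, n = 90, seed = 65)
  M <- genotypes(pop, "marker")
  set.seed(66)
  y <- M[, 5] * 0.8 + rnorm(90)
  s1 <- gwas_scan(M, y, method = "glm")
  perm <- sample(ncol(M))
  s2 <- gwas_scan(M[, perm], y, method = "glm")
  s2o <- s2[match(s1$locus_id, s2$locus_id), ]
  expect_equal(s1$pvalue, s2o$pvalue)
  expect_equal(s1$qvalue, s2o$qvalue)
  expect_equal(s1$significant, s2o$significant)

  # monomorphic markers are excluded and reported
  M2 <- M
  M2[, 3] <- 2L
  s3 <- gwas_scan(M2, y, method = "glm")
  expect_equal(nrow(s3), ncol(M) - 1)
  expect_equal(attr(s3, "skipped")$locus_id, colnames(M)[3])
  expect_error(gwas_scan(M2 * 0 + 1, y, method = "glm"), "polymorphic")
  expect_error(gwas_scan(M, y, method = "glm", alpha = 0), "alpha")
  expect_error(gwas_scan(M, y[-1], method = "glm"), "length")
})

test_that("quantile scans agree with the single-marker test functions", {
  map <- build_genome_map(n_chrom = 1, chrom_length_cM = 20,
                          markers_per_chrom = 20, spacing_cM = 1, n_qtl = 1,
                          seed = 67)
  pop <- random_pop(map, n = 120, seed = 67)
  M <- genotypes(pop, "marker")
  set.seed(68)
  y <- 0.5 * M[, 7] + rnorm(120)
  CP <- matrix(rnorm(120 * 2), 120)
  s <- gwas_scan(pop, y, covariates = CP, method = "qr", tau = 0.3)
  for (j in c(3, 7, 15)) {
    single <- qr_rank_score_test(y, cbind(1, CP), M[, s$locus_id[j]], 0.3)
    expect_equal(s$pvalue[j], single$p.value, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # reported effects solve the per-marker check-loss problem at least as well
  # as the reduced model (objective can only improve with the extra column)
  reduced <- fit_quantile_model(y, cbind(1, CP), 0.3)
  j <- 7
  full <- fit_quantile_model(y, cbind(1, CP, M[, s$locus_id[j]]), 0.3)
  expect_equal(s$effect[j], unname(full$coefficients[4]), tolerance = 1e-4)
  expect_lte(full$objective, reduced$objective + 1e-8)
  expect_equal(glance(s)$n_tested, nrow(s))
})
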