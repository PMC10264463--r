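test_that("meiosis transmits parental alleles under the Haldane model", {
  map2 <- build_genome_map(n_chrom = 1, chrom_length_cM = 100,
                           markers_per_chrom = 2, spacing_cM = 10, n_qtl = 1,
                           seed = 1)
  L <- nrow(map2$loci)
  # homozygous parent: gamete equals either haplotype exactly
  h <- rbinom(L, 1, 0.5)
  g <- meiosis(h, h, map2, n = 20, seed = 1)
  expect_true(all(g == matrix(h, 20, L, byrow = TRUE)))
  # unphased input rejected
  expect_error(meiosis(h * 2, h, map2), "phased")
  expect_error(meiosis(h[-1], h, map2), "phased")

  # recombinant fraction between loci d cM apart matches Haldane's closed form
  mk <- function(d) build_genome_map(n_chrom = 1, chrom_length_cM = 200,
                                     markers_per_chrom = 2, spacing_cM = d,
                                     n_qtl = 1, seed = 1)
  rec_frac <- function(map, n) {
    idx <- which(map$loci$type == "marker")
    g <- meiosis(rep(1, nrow(map$loci)), rep(0, nrow(map$loci)), map,
                 n = n, seed = 99)
    mean(g[, idx[1]] != g[, idx[2]])
  }
  n <- 1e5
  for (d in c(10, 50)) {
    theta <- haldane(d)
    se <- sqrt(theta * (1 - theta) / n)
    expect_lt(abs(rec_frac(mk(d), n) - theta), 3 * se)
  }
  # monotone in map distance
  fr <- vapply(c(1, 5, 20, 80), function(d) rec_frac(mk(d), 4e4), numeric(1))
  expect_true(all(diff(fr) > 0))

  # independent assortment across chromosomes
  map_x <- build_genome_map(n_chrom = 2, chrom_length_cM = 100,
                            markers_per_chrom = 2, spacing_cM = 1, n_qtl = 1,
                            seed = 1)
  idx <- which(map_x$loci$type == "marker" & !duplicated(map_x$loci$chrom))
  g <- meiosis(rep(1, nrow(map_x$loci)), rep(0, nrow(map_x$loci)), map_x,
               n = n, seed = 5)
  frac <- mean(g[, idx[1]] != g[, idx[2]])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("generation-0 composite LD matches the closed form over seeds", {
  map <- build_genome_map(n_chrom = 1, chrom_length_cM = 100,
                          markers_per_chrom = 6, spacing_cM = 20, n_qtl = 1,
                          seed = 11)
  freqs <- simulate_parental_pops(map, freq_law("uniform", 0.1, 0.9), seed = 11)
  mk_idx <- which(map$loci$type == "marker")
  pairs <- utils::combn(mk_idx, 2)
  n_seeds <- 12
  dmat <- matrix(NA_real_, n_seeds, ncol(pairs))
  for (s in seq_len(n_seeds)) {
    pop <- simulate_composite(map, freqs, composite_size = 600,
                              n_generations = 0, n_families_base = 60,
                              seed = 100 + s)
    H <- rbind(pop$H1, pop$H2)  # generation-0 gamete pool
    pa <- colMeans(H)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      dmat[s, k] <- mean(H[, i] * H[, j]) - pa[i] * pa[j]
    }
  }
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    theta <- haldane(abs(map$loci$pos_cM[i] - map$loci$pos_cM[j]))
    expected <- expected_composite_ld(theta, freqs$p1[i], freqs$p2[i],
                                      freqs$p1[j], freqs$p2[j])
    mc_se <- sd(dmat[, k]) / sqrt(n_seeds)
    expect_lt(abs(mean(dmat[, k]) - expected), 3 * mc_se + 1e-12)
  }
})

test_that("composite populations conserve alleles and stay in dosage space", {
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 50,
                          markers_per_chrom = 25, spacing_cM = 2, n_qtl = 4,
                          seed = 2)
  # a locus fixed in both parents can never gain the other allele
  L <- nrow(map$loci)
  freqs <- simulate_parental_pops(map, freq_law("fixed", p1 = 1, p2 = 1))
  pop <- simulate_composite(map, freqs, composite_size = 200,
                            n_generations = 2, n_families_base = 20, seed = 1)
  expect_true(all(genotypes(pop, "all") == 2L))

  # dosages always in {0,1,2}; frequencies drift around (p1+p2)/2
  freqs <- simulate_parental_pops(map, freq_law("uniform", 0.2, 0.8), seed = 5)
  means <- replicate(6, {
    pop <- simulate_composite(map, freqs, composite_size = 400,
                              n_generations = 3, n_families_base = 40,
                              seed = sample.int(1e6, 1))
    X <- genotypes(pop, "all")
    expect_true(all(X %in% 0:2))
    colMeans(X) / 2
  })
  target <- (freqs$p1 + freqs$p2) / 2
  expect_lt(mean(abs(rowMeans(means) - target)), 0.05)

  # n_generations = 0 returns the base itself: 100-family structure intact
  base <- simulate_composite(map, freqs, composite_size = 400,
                             n_generations = 0, n_families_base = 40, seed = 3)
  expect_equal(base$generation, 0L)
  expect_equal(as.vector(table(base$family_id)), rep(10L, 40))
})

test_that("full-sib sampling produces the requested family structure", {
  cfg <- small_config()
  sim <- simulate_study_population("major3_plus97", cfg, seed = 4)
  pop <- sim$population
  expect_equal(n_individuals(pop), 100)
  expect_equal(as.vector(table(pop$family_id)), rep(10L, 10))
  # singleton families
  single <- sample_fullsib_families(sim$composite, sim$map, n_families = 5,
                                    family_size = 1, seed = 2)
  expect_equal(n_individuals(single), 5)
  expect_equal(as.vector(table(single$family_id)), rep(1L, 5))
  expect_error(sample_fullsib_families(single, sim$map, n_families = 5,
                                       family_size = 2, seed = 1),
               "at least")

  # within-family mean dosage equals the mid-parent dosage (Mendelian
  # expectation): forced parent pair from a 2-individual composite
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 50,
                          markers_per_chrom = 50, spacing_cM = 1, n_qtl = 2,
                          seed = 9)
  L <- nrow(map$loci)
  # parent A homozygous alt, parent B homozygous ref -> offspring all dosage 1
  duo <- make_pop(rbind(rep(1L, L), rep(0L, L)), rbind(rep(1L, L), rep(0L, L)),
                  family_id = c(1L, 2L), map = map)
  fam <- sample_fullsib_families(duo, map, n_families = 1, family_size = 30,
                                 seed = 3)
  expect_true(all(genotypes(fam, "all") == 1L))
  # heterozygous parent A, homozygous-ref B -> mean dosage 0.5 per locus
  duo2 <- make_pop(rbind(rep(1L, L), rep(0L, L)), rbind(rep(0L, L), rep(0L, L)),
                   family_id = c(1L, 2L), map = map)
  fam2 <- sample_fullsib_families(duo2, map, n_families = 1, family_size = 40,
                                  seed = 3)
  # loci are linked, so the Monte-Carlo SE comes from per-offspring means
  per_off <- rowMeans(genotypes(fam2, "all"))
  expect_lt(abs(mean(per_off) - 0.5), 3 * sd(per_off) / sqrt(length(per_off)))
})

test_that("downsampling removes equally per family and is reproducible", {
  cfg <- small_config()
  pop <- simulate_study_population("major3_plus97", cfg, seed = 6)$population
  d <- downsample(pop, 90, seed = 1)
  expect_equal(as.vector(table(d$family_id)), rep(9L, 10))
  # stepwise reduction keeps exact proportionality at every step
  cur <- pop
  for (n in seq(90, 20, by = -10)) {
    cur <- downsample(cur, n, seed = n)
    expect_equal(as.vector(table(cur$family_id)), rep(n %/% 10, 10))
  }
  # ids stay aligned with the original population
  expect_true(all(cur$id %in% pop$id))
  i <- match(cur$id, pop$id)
  expect_equal(cur$H1, pop$H1[i, ])
  # identity, determinism and error cases
  expect_identical(downsample(pop, n_individuals(pop)), pop)
  expect_equal(downsample(pop, 50, seed = 2)$id, downsample(pop, 50, seed = 2)$id)
  expect_error(downsample(pop, 1000), "exceeds")
  expect_error(downsample(pop, 95), "divisible")
})
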