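test_that("pairwise r2 is the squared dosage correlation on shared chromosomes", {
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 50,
                          markers_per_chrom = 4, spacing_cM = 10, n_qtl = 1,
                          seed = 1)
  set.seed(5)
  pop <- random_pop(map, n = 120, seed = 5)
  # duplicate one marker column into its neighbour
  m_idx <- which(pop$loci$type == "marker")
  pop$H1[, m_idx[2]] <- pop$H1[, m_idx[1]]
  pop$H2[, m_idx[2]] <- pop$H2[, m_idx[1]]
  pr <- pairwise_r2(pop)
  ids <- pop$loci$locus_id[m_idx[1:2]]
  dup <- pr[pr$locus_a == ids[1] & pr$locus_b == ids[2], ]
  expect_equal(dup$r2, 1)
  # only same-chromosome pairs, distances positive, r2 in [0,1]
  ch <- pop$loci$chrom[match(pr$locus_a, pop$loci$locus_id)]
  expect_equal(ch, pr$chrom)
  expect_true(all(pr$dist_cM > 0))
  expect_true(all(pr$r2 >= 0 & pr$r2 <= 1))

  # monomorphic marker skipped with a warning
  pop$H1[, m_idx[3]] <- 1L
  pop$H2[, m_idx[3]] <- 1L
  expect_warning(pr2 <- pairwise_r2(pop), "monomorphic")
  expect_false(pop$loci$locus_id[m_idx[3]] %in% c(pr2$locus_a, pr2$locus_b))

  # independent markers: mean r2 near the 1/n null level
  big <- build_genome_map(n_chrom = 1, chrom_length_cM = 60,
                          markers_per_chrom = 50, spacing_cM = 1, n_qtl = 1,
                          seed = 2)
  n <- 200
  nullpop <- random_pop(big, n = n, seed = 7)
  pr3 <- pairwise_r2(nullpop)
  expect_gt(nrow(pr3), 1000)
  expect_lt(abs(mean(pr3$r2) - 1 / (n - 1)), 0.5 / (n - 1))
})

test_that("decay curve reproduces lines, known decays, and stats::loess", {
  # exact line: local quadratic reproduces it to numerical tolerance
  d <- rep(seq(0.5, 10, by = 0.5), each = 10)
  line <- tibble::tibble(dist_cM = d, r2 = 0.5 - 0.03 * d)
  cl <- fit_decay_curve(line, span = 0.6, degree = 2)
  grid <- seq(1, 9, by = 0.5)
  expect_equal(predict(cl, grid), 0.5 - 0.03 * grid, tolerance = 1e-8)

  # synthetic exponential decay recovered within 0.02 on an interior grid
  set.seed(8)
  d <- rep(seq(0.1, 6, by = 0.05), each = 8)
  dec <- tibble::tibble(dist_cM = d, r2 = 0.4 * exp(-d) + rnorm(length(d), 0, 0.01))
  cd <- fit_decay_curve(dec, span = 0.2, degree = 2)
  grid <- seq(0.5, 5, by = 0.25)
  expect_lt(max(abs(predict(cd, grid) - 0.4 * exp(-grid))), 0.02)

  # agrees with stats::loess (same span/degree, exact surface) inside the range
  lo <- stats::loess(r2 ~ dist_cM, data = dec, span = 0.2, degree = 2,
                     surface = "direct")
  expect_equal(predict(cd, grid),
               unname(predict(lo, data.frame(dist_cM = grid))),
               tolerance = 1e-6)

  # permutation invariance
  perm <- dec[sample(nrow(dec)), ]
  cp <- fit_decay_curve(perm, span = 0.2, degree = 2)
  expect_equal(predict(cp, grid), predict(cd, grid))

  expect_error(fit_decay_curve(tibble::tibble(dist_cM = c(1, 2), r2 = c(1, 1)),
                               degree = 2), "distinct distances")
})

test_that("window distance inverts the decay curve at the threshold", {
  d <- rep(seq(0.05, 4, by = 0.05), each = 10)
  dec <- tibble::tibble(dist_cM = d, r2 = 0.4 * exp(-d))
  cd <- fit_decay_curve(dec, span = 0.15, degree = 2)
  w <- window_distance(cd, threshold = 0.2)
  expect_lt(abs(w - log(2)), 0.02)

  # curve everywhere above the threshold
  flat <- fit_decay_curve(tibble::tibble(dist_cM = d, r2 = 0.5), span = 0.3)
  expect_error(window_distance(flat, threshold = 0.2), "never falls")
  # curve already below at the origin
  low <- fit_decay_curve(tibble::tibble(dist_cM = d, r2 = 0.05), span = 0.3)
  expect_error(window_distance(low, threshold = 0.2), "below")
})

test_that("marker-QTL association matches a brute-force distance check", {
  for (seed in 1:4) {
    map <- build_genome_map(n_chrom = 3, chrom_length_cM = 40,
                            markers_per_chrom = 20, spacing_cM = 2, n_qtl = 6,
                            seed = seed)
    w <- runif(1, 0.5, 10)
    am <- qtl_marker_association(map, w)
    mk <- map_markers(map)
    q <- map_qtls(map)
    brute <- vapply(seq_len(nrow(mk)), function(i) {
      any(q$chrom == mk$chrom[i] & abs(q$pos_cM - mk$pos_cM[i]) <= w)
    }, logical(1))
    expect_equal(am$markers$associated, brute)
    expect_equal(nrow(am$windows), nrow(q))
  }
  map <- build_genome_map(n_chrom = 2, chrom_length_cM = 30,
                          markers_per_chrom = 10, spacing_cM = 3, n_qtl = 2,
                          seed = 1)
  # window spanning the whole chromosome: every same-chromosome marker in
  all_w <- qtl_marker_association(map, w = 100)
  q_chroms <- unique(map_qtls(map)$chrom)
  mk <- map_markers(map)
  expect_equal(all_w$markers$associated, mk$chrom %in% q_chroms)
  # tiny window: a valid map with possibly no associated markers
  tiny <- qtl_marker_association(map, w = 1e-6)
  expect_true(all(tiny$markers$associated[!mk$chrom %in% q_chroms] == FALSE))
  expect_error(qtl_marker_association(map, w = 0), "positive")
  expect_error(qtl_marker_association(map, w = 1, targets = map_qtls(map)[0, ]),
               "empty")
})
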