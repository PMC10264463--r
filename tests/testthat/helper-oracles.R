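# Independent oracles and small fixture builders used across the suite.

# Exhaustive basic-solution oracle for the check-loss LP: every p-subset of
# observations that admits an exact fit is a candidate basis; the optimum of
# the LP is attained at one of them.
rq_oracle_objective <- function(y, X, tau) {
  n <- length(y)
  p <- ncol(X)
  best <- Inf
  for (s in utils::combn(n, p, simplify = FALSE)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-10) next
    b <- solve(Xs, y[s])
    obj <- sum(check_loss(y - X %*% b, tau))
    best <- min(best, obj)
  }
  best
}

# Haldane map function: recombination fraction for a distance in cM
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Set-arithmetic oracles for power and false-positive rate
power_oracle <- function(scan, assoc) {
  hits <- 0
  for (i in seq_len(nrow(assoc$windows))) {
    members <- scan$chrom == assoc$windows$chrom[i] &
      scan$pos_cM >= assoc$windows$lo[i] & scan$pos_cM <= assoc$windows$hi[i]
    if (any(scan$significant[members])) hits <- hits + 1
  }
  hits / nrow(assoc$windows)
}

fpr_oracle <- function(scan, assoc) {
  assoc_ids <- assoc$markers$locus_id[assoc$markers$associated]
  non <- scan[!(scan$locus_id %in% assoc_ids), ]
  sum(non$significant) / nrow(non)
}

# Hand-built phased population over a map (haplotype matrices 0/1)
make_pop <- function(H1, H2, family_id = rep(1L, nrow(H1)), map = NULL,
                     loci = NULL, generation = 0L) {
  if (is.null(loci)) loci <- map$loci
  qrgwas:::new_population(H1, H2, seq_len(nrow(H1)), family_id, generation, loci)
}

# Random HWE population (no structure) on a map
random_pop <- function(map, n, p = NULL, seed = 1) {
  L <- nrow(map$loci)
  withr_seed <- function(expr) qrgwas:::with_seed_maybe(seed, expr)
  withr_seed({
    if (is.null(p)) p <- runif(L, 0.1, 0.9)
    H1 <- matrix(rbinom(n * L, 1, rep(p, each = n)), nrow = n)
    H2 <- matrix(rbinom(n * L, 1, rep(p, each = n)), nrow = n)
    make_pop(H1, H2, map = map)
  })
}

# Small scaled-down study configuration for pipeline tests
small_config <- function(...) {
  args <- list(n_chromosomes = 4, chrom_length_cM = 60, markers_per_chrom = 60,
               spacing_cM = 1, n_qtl = 20, composite_size = 300,
               n_generations = 3, n_families_base = 30, n_families = 10,
               family_size = 10)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
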