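# Populations are stored phased: two haplotype matrices (individuals x loci,
# 0/1 alleles) over the loci of a genome_map, plus individual ids, family
# labels and the generation number. Only dosages are exposed downstream.

new_population <- function(H1, H2, id, family_id, generation, loci) {
  stopifnot(is.matrix(H1), is.matrix(H2), all(dim(H1) == dim(H2)),
            nrow(H1) == length(id), length(family_id) == length(id))
  structure(
    list(H1 = H1, H2 = H2, id = as.integer(id),
         family_id = as.integer(family_id),
         generation = as.integer(generation), loci = loci),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  nf <- length(unique(x$family_id[!is.na(x$family_id)]))
  cat("<population> ", nrow(x$H1), " individuals x ", ncol(x$H1),
      " loci (generation ", x$generation, ", ",
      if (nf > 0) paste0(nf, " families") else "no family labels", ")\n",
      sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @export
n_individuals <- function(pop) {
  stopifnot(inherits(pop, "population"))
  nrow(pop$H1)
}

#' Extract the dosage matrix of a population
#'
#' @param pop A `population`.
#' @param loci Which loci to return: markers, QTLs, or all.
#' @return Integer matrix (individuals x loci) of allele dosages in
#'   `{0, 1, 2}`, with locus ids as column names.
#' @export
genotypes <- function(pop, loci = c("marker", "qtl", "all")) {
  stopifnot(inherits(pop, "population"))
  loci <- match.arg(loci)
  sel <- if (loci == "all") seq_len(ncol(pop$H1)) else which(pop$loci$type == loci)
  X <- pop$H1[, sel, drop = FALSE] + pop$H2[, sel, drop = FALSE]
  colnames(X) <- pop$loci$locus_id[sel]
  X
}

# chromosome layout vectors for the C++ gamete sampler (0-based half-open)
chrom_layout <- function(loci, n_chrom, chrom_length_cM) {
  begin <- integer(n_chrom)
  end <- integer(n_chrom)
  for (c in seq_len(n_chrom)) {
    idx <- which(loci$chrom == c)
    begin[c] <- if (length(idx)) min(idx) - 1L else 0L
    end[c] <- if (length(idx)) max(idx) else 0L
  }
  list(begin = begin, end = end,
       len = rep(chrom_length_cM, n_chrom), pos = loci$pos_cM)
}

# One gamete per entry of `parents` (1-based indices into pop rows).
gametes_from <- function(pop, parents, layout) {
  cpp_gametes(pop$H1, pop$H2, as.integer(parents) - 1L, layout$pos,
              layout$begin, layout$end, layout$len)
}

#' Simulate a single meiosis
#'
#' Produces gamete haplotypes from a phased parent under the Haldane model:
#' crossovers form a Poisson process along the genetic map (one expected
#' crossover per Morgan, no interference) and chromosomes assort
#' independently. Gamete alleles come only from the parent (no mutation).
#'
#' @param h1,h2 The parent's two phased haplotypes: 0/1 vectors over the loci
#'   of `map`, in map order.
#' @param map A `genome_map`.
#' @param n Number of gametes to draw.
#' @param seed Optional integer seed.
#' @return A 0/1 matrix with `n` rows (one gamete per row).
#' @export
meiosis <- function(h1, h2, map, n = 1, seed = NULL) {
  stopifnot(inherits(map, "genome_map"))
  L <- nrow(map$loci)
  if (length(h1) != L || length(h2) != L ||
      !all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1))) {
    stop("parent haplotypes must be phased 0/1 vectors over all ", L,
         " map loci", call. = FALSE)
  }
  lay <- chrom_layout(map$loci, map$n_chrom, map$chrom_length_cM)
  H1 <- matrix(as.integer(h1), nrow = 1)
  H2 <- matrix(as.integer(h2), nrow = 1)
  with_seed_maybe(seed,
    cpp_gametes(H1, H2, rep(0L, n), lay$pos, lay$begin, lay$end, lay$len))
}

#' Simulate the advanced-generation composite population
#'
#' Crosses two parental populations in linkage equilibrium and advances the
#' composite by random mating. The base generation (generation 0) is produced
#' by full-sib families of F1 parents: each F1 carries one haplotype sampled
#' from each parental population, and each base family is the offspring of
#' one F1 x F1 pair. The gamete pool forming generation 0 therefore carries
#' the closed-form composite LD of [expected_composite_ld()]. Subsequent
#' generations are produced by random pairing (no selfing, no mutation, no
#' selection, no migration).
#'
#' @param map A `genome_map`.
#' @param freqs A `parental_freqs` tibble from [simulate_parental_pops()].
#' @param composite_size Number of individuals per generation (default 5000).
#' @param n_generations Rounds of random mating after the base generation
#'   (default 5). `n_generations = 0` returns the composite base itself.
#' @param n_families_base Number of full-sib families in the base generation
#'   (default 100; must divide `composite_size`).
#' @param seed Optional integer seed.
#' @return A `population` (phased internally; generation set to
#'   `n_generations`).
#' @export
simulate_composite <- function(map, freqs, composite_size = 5000,
                               n_generations = 5, n_families_base = 100,
                               seed = NULL) {
  stopifnot(inherits(map, "genome_map"), inherits(freqs, "parental_freqs"))
  if (composite_size %% n_families_base != 0) {
    stop("`composite_size` must be divisible into `n_families_base` families",
         call. = FALSE)
  }
  if (!identical(freqs$locus_id, map$loci$locus_id)) {
    stop("`freqs` does not match the loci of `map`", call. = FALSE)
  }
  lay <- chrom_layout(map$loci, map$n_chrom, map$chrom_length_cM)
  L <- nrow(map$loci)
  with_seed_maybe(seed, {
    # F1 parents: one haplotype from each parental population
    n_par <- 2L * n_families_base
    F1a <- matrix(rbinom(n_par * L, 1L, rep(freqs$p1, each = n_par)),
                  nrow = n_par)
    F1b <- matrix(rbinom(n_par * L, 1L, rep(freqs$p2, each = n_par)),
                  nrow = n_par)
    f1 <- new_population(F1a, F1b, seq_len(n_par), rep(NA_integer_, n_par),
                         -1L, map$loci)
    fam_size <- composite_size %/% n_families_base
    pa <- rep(seq(1L, n_par, by = 2L), each = fam_size)
    pb <- pa + 1L
    pop <- new_population(
      gametes_from(f1, pa, lay), gametes_from(f1, pb, lay),
      seq_len(composite_size), rep(seq_len(n_families_base), each = fam_size),
      0L, map$loci
    )
    if (n_generations > 0) {
      for (g in seq_len(n_generations)) {
        n <- nrow(pop$H1)
        pa <- sample.int(n, composite_size, replace = TRUE)
        pb <- sample.int(n, composite_size, replace = TRUE)
        while (any(bad <- pa == pb)) {
          pb[bad] <- sample.int(n, sum(bad), replace = TRUE)
        }
        pop <- new_population(
          gametes_from(pop, pa, lay), gametes_from(pop, pb, lay),
          seq_len(composite_size), rep(NA_integer_, composite_size),
          g, map$loci
        )
      }
    }
    pop
  })
}

#' Sample full-sib families from a composite population
#'
#' Draws `2 * n_families` distinct parents at random from the composite,
#' pairs them, and generates `family_size` full-sib offspring per pair (the
#' study population: by default 20 families of 50, i.e. 1000 individuals of
#' the same generation).
#'
#' @param pop A `population` (the advanced composite).
#' @param map The `genome_map` the population was simulated on.
#' @param n_families Number of full-sib families (default 20).
#' @param family_size Offspring per family (default 50).
#' @param seed Optional integer seed.
#' @return A `population` with `family_id` set.
#' @export
sample_fullsib_families <- function(pop, map, n_families = 20, family_size = 50,
                                    seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(map, "genome_map"))
  n <- n_individuals(pop)
  if (n < 2 * n_families) {
    stop("composite has ", n, " individuals; need at least ", 2 * n_families,
         " to supply ", n_families, " parent pairs", call. = FALSE)
  }
  lay <- chrom_layout(map$loci, map$n_chrom, map$chrom_length_cM)
  with_seed_maybe(seed, {
    parents <- sample.int(n, 2L * n_families)
    pa <- rep(parents[seq(1L, length(parents), by = 2L)], each = family_size)
    pb <- rep(parents[seq(2L, length(parents), by = 2L)], each = family_size)
    n_off <- n_families * family_size
    new_population(
      gametes_from(pop, pa, lay), gametes_from(pop, pb, lay),
      seq_len(n_off), rep(seq_len(n_families), each = family_size),
      pop$generation + 1L, map$loci
    )
  })
}

#' Downsample a population proportionally to family
#'
#' Randomly removes the same number of individuals from every family so the
#' family proportions are preserved exactly (the stepwise
#' 1000 -> 900 -> ... -> 200 reductions of the study design remove 5 per
#' family per step). Individual ids and family labels are preserved, so
#' phenotypes indexed by id remain aligned.
#'
#' @param pop A `population` with family labels.
#' @param target_n Number of individuals to keep; the per-family removal
#'   count `(n - target_n) / n_families` must be a whole number.
#' @param seed Optional integer seed.
#' @return The downsampled `population`.
#' @export
downsample <- function(pop, target_n, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  n <- n_individuals(pop)
  if (target_n > n) {
    stop("`target_n` (", target_n, ") exceeds the population size (", n, ")",
         call. = FALSE)
  }
  if (target_n == n) {
    return(pop)
  }
  fam <- pop$family_id
  if (anyNA(fam)) {
    stop("population has no family labels; proportional downsampling needs them",
         call. = FALSE)
  }
  fams <- unique(fam)
  remove_per_fam <- (n - target_n) / length(fams)
  if (remove_per_fam != round(remove_per_fam)) {
    stop("(n - target_n) = ", n - target_n, " is not divisible by the ",
         length(fams), " families; proportional removal impossible",
         call. = FALSE)
  }
  with_seed_maybe(seed, {
    drop_idx <- unlist(lapply(fams, function(f) {
      idx <- which(fam == f)
      if (length(idx) < remove_per_fam) {
        stop("family ", f, " has fewer members than the per-family removal",
             call. = FALSE)
      }
      sample(idx, remove_per_fam)
    }))
    keep <- sort(setdiff(seq_len(n), drop_idx))
    new_population(pop$H1[keep, , drop = FALSE], pop$H2[keep, , drop = FALSE],
                   pop$id[keep], fam[keep], pop$generation, pop$loci)
  })
}
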