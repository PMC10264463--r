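#' Expected linkage disequilibrium in a composite population
#'
#' Closed-form signed LD between two loci in the gamete pool of a composite
#' population formed by crossing two source populations that are each in
#' linkage equilibrium:
#' \deqn{\Delta_{ab} = \frac{1 - 2\theta_{ab}}{4}\,(p_a^1 - p_a^2)(p_b^1 - p_b^2),}
#' where \eqn{\theta_{ab}} is the recombination fraction between the loci and
#' \eqn{p^1}, \eqn{p^2} are allele frequencies in the two parental
#' populations. The LD is maximal (\eqn{|\Delta| = 0.25}) for completely
#' linked loci fixed for alternative alleles, zero whenever the parental
#' frequencies agree at either locus, and zero for unlinked loci
#' (\eqn{\theta = 0.5}). Coupling-phase differences give positive values,
#' repulsion negative ones.
#'
#' @param theta Recombination fraction(s) in `[0, 0.5]`.
#' @param pa1,pa2 Allele frequency of locus `a` in parental populations 1 and 2.
#' @param pb1,pb2 Allele frequency of locus `b` in parental populations 1 and 2.
#' @return Numeric vector of signed LD values, all in `[-0.25, 0.25]`.
#' @export
#' @examples
#' expected_composite_ld(0, 1, 0, 1, 0)      # 0.25, maximal coupling LD
#' expected_composite_ld(0.25, 0.8, 0.3, 0.7, 0.3)
expected_composite_ld <- function(theta, pa1, pa2, pb1, pb2) {
  if (any(theta < 0 | theta > 0.5)) {
    stop("`theta` must lie in [0, 0.5]", call. = FALSE)
  }
  freqs <- cbind(pa1, pa2, pb1, pb2)
  if (any(freqs < 0 | freqs > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  (1 - 2 * theta) / 4 * (pa1 - pa2) * (pb1 - pb2)
}

#' Build a genome map of markers and QTLs
#'
#' Lays out a deterministic grid of biallelic SNP markers per chromosome and
#' places QTLs uniformly at random within the marker-covered region of a
#' uniformly chosen chromosome. The default configuration is 10 chromosomes
#' of 200 cM carrying 200 markers each (2000 SNPs genome wide, one marker per
#' cM) and 100 QTLs.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_cM Chromosome genetic length in centimorgans.
#' @param markers_per_chrom Number of evenly spaced markers per chromosome.
#' @param spacing_cM Distance between adjacent markers in cM.
#' @param n_qtl Number of QTLs to place.
#' @param architecture Genetic architecture tag: `"major3_plus97"` (three
#'   major genes plus minor loci) or `"infinitesimal_100"` (all loci of small
#'   effect).
#' @param seed Optional integer seed for the QTL placement.
#' @return A `genome_map` object: a list with a `loci` tibble (`locus_id`,
#'   `chrom`, `pos_cM`, `type`) sorted by position, plus the configuration
#'   fields.
#' @export
#' @examples
#' map <- build_genome_map(n_chrom = 2, markers_per_chrom = 50, n_qtl = 5, seed = 1)
#' map
build_genome_map <- function(n_chrom = 10, chrom_length_cM = 200,
                             markers_per_chrom = 200, spacing_cM = 1,
                             n_qtl = 100,
                             architecture = c("major3_plus97", "infinitesimal_100"),
                             seed = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2, spacing_cM > 0, n_qtl >= 1)
  span <- (markers_per_chrom - 1) * spacing_cM
  if (span > chrom_length_cM) {
    stop("marker grid (", span, " cM) exceeds the chromosome length (",
         chrom_length_cM, " cM)", call. = FALSE)
  }
  marker_pos <- seq(0, by = spacing_cM, length.out = markers_per_chrom)
  markers <- tibble(
    locus_id = sprintf("M%d_%d", rep(seq_len(n_chrom), each = markers_per_chrom),
                       rep(seq_len(markers_per_chrom), n_chrom)),
    chrom = rep(seq_len(n_chrom), each = markers_per_chrom),
    pos_cM = rep(marker_pos, n_chrom),
    type = "marker"
  )
  qtls <- with_seed_maybe(seed, {
    tibble(
      locus_id = sprintf("Q%d", seq_len(n_qtl)),
      chrom = sample.int(n_chrom, n_qtl, replace = TRUE),
      pos_cM = runif(n_qtl, 0, span),
      type = "qtl"
    )
  })
  loci <- dplyr::arrange(dplyr::bind_rows(markers, qtls), .data$chrom, .data$pos_cM)
  structure(
    list(
      loci = loci,
      n_chrom = n_chrom,
      chrom_length_cM = chrom_length_cM,
      markers_per_chrom = markers_per_chrom,
      spacing_cM = spacing_cM,
      n_qtl = n_qtl,
      architecture = architecture
    ),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$n_chrom, " chromosomes x ", x$chrom_length_cM,
      " cM; ", sum(x$loci$type == "marker"), " markers (", x$spacing_cM,
      " cM spacing), ", sum(x$loci$type == "qtl"), " QTLs; architecture: ",
      x$architecture, "\n", sep = "")
  invisible(x)
}

#' Marker and QTL subsets of a genome map
#'
#' @param map A `genome_map`.
#' @return A tibble of marker (or QTL) loci.
#' @export
map_markers <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  dplyr::filter(map$loci, .data$type == "marker")
}

#' @rdname map_markers
#' @export
map_qtls <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  dplyr::filter(map$loci, .data$type == "qtl")
}

#' Parental allele-frequency laws
#'
#' Constructor for the per-locus allele-frequency sampler of the two parental
#' populations. Laws:
#' \describe{
#'   \item{`divergent`}{Strongly diverged parents: one population receives a
#'     frequency in `U(1 - delta, 1)`, the other in `U(0, delta)`, with the
#'     orientation randomized per locus. This is the default because the
#'     composite design derives all of its linkage disequilibrium from
#'     parental allele-frequency differences, which is maximal when the
#'     parents are fixed for alternative alleles; `delta = 0.05` keeps the
#'     per-locus `|p1 - p2|` near 0.95.}
#'   \item{`uniform`}{Independent `U(min, max)` frequencies in both
#'     populations.}
#'   \item{`fixed`}{Deterministic frequencies (recycled to the number of
#'     loci), useful for degenerate maximal-LD designs.}
#' }
#'
#' @param type Law name.
#' @param delta Divergence parameter of the `divergent` law.
#' @param min,max Range of the `uniform` law.
#' @param p1,p2 Frequencies of the `fixed` law.
#' @return A `freq_law` object with a `sample(n)` function and the analytic
#'   per-population mean frequency.
#' @export
#' @examples
#' law <- freq_law("divergent", delta = 0.05)
#' law$mean  # 0.5 in both populations
freq_law <- function(type = c("divergent", "uniform", "fixed"),
                     delta = 0.05, min = 0.05, max = 0.95, p1 = 1, p2 = 0) {
  type <- match.arg(type)
  law <- switch(type,
    divergent = {
      stopifnot(delta > 0, delta <= 0.5)
      list(
        params = list(delta = delta),
        mean = c(p1 = 0.5, p2 = 0.5),
        sample = function(n) {
          hi <- runif(n, 1 - delta, 1)
          lo <- runif(n, 0, delta)
          swap <- runif(n) < 0.5
          tibble(p1 = ifelse(swap, lo, hi), p2 = ifelse(swap, hi, lo))
        }
      )
    },
    uniform = {
      stopifnot(min >= 0, max <= 1, min < max)
      list(
        params = list(min = min, max = max),
        mean = c(p1 = (min + max) / 2, p2 = (min + max) / 2),
        sample = function(n) tibble(p1 = runif(n, min, max), p2 = runif(n, min, max))
      )
    },
    fixed = {
      stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
      list(
        params = list(p1 = p1, p2 = p2),
        mean = c(p1 = mean(p1), p2 = mean(p2)),
        sample = function(n) tibble(p1 = rep_len(p1, n), p2 = rep_len(p2, n))
      )
    }
  )
  structure(c(list(type = type), law), class = "freq_law")
}

#' @export
print.freq_law <- function(x, ...) {
  cat("<freq_law> ", x$type, " (",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Simulate parental population allele frequencies
#'
#' Draws per-locus allele frequencies independently for the two random-mating
#' parental populations (each population is in linkage equilibrium, so a
#' frequency vector fully characterizes it).
#'
#' @param map A `genome_map`.
#' @param law A [freq_law()] object.
#' @param seed Optional integer seed.
#' @return A `parental_freqs` tibble: `locus_id`, `chrom`, `pos_cM`, `type`,
#'   `p1`, `p2`.
#' @export
simulate_parental_pops <- function(map, law = freq_law("divergent"), seed = NULL) {
  stopifnot(inherits(map, "genome_map"), inherits(law, "freq_law"))
  n <- nrow(map$loci)
  pq <- with_seed_maybe(seed, law$sample(n))
  if (any(pq$p1 < 0 | pq$p1 > 1 | pq$p2 < 0 | pq$p2 > 1)) {
    stop("frequency law produced values outside [0, 1]", call. = FALSE)
  }
  out <- dplyr::bind_cols(map$loci, pq)
  class(out) <- c("parental_freqs", class(out))
  out
}
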