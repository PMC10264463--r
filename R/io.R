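# Import/export of the study's plain-text formats: dosage TSV + PLINK-style
# map, phenotype/covariate/effect TSVs, LD-pair TSV, scan CSV, VCF export,
# YAML study configuration.

#' Export / import a genotype dosage matrix
#'
#' Tab-separated individuals x markers dosage table; first columns are the
#' individual id and family id, then one column per marker (header row of
#' marker ids).
#'
#' @param pop A `population`.
#' @param path Output file.
#' @return Invisibly, `path` (writer) or a list with `genotypes`, `id`,
#'   `family_id` (reader).
#' @export
write_genotypes <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  X <- genotypes(pop, "marker")
  df <- dplyr::bind_cols(tibble(id = pop$id, family_id = pop$family_id),
                         as_tibble(X))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("id", "family_id")), drop = FALSE])
  storage.mode(X) <- "integer"
  list(genotypes = X, id = df$id, family_id = df$family_id)
}

#' Export a marker map in PLINK .map column order
#'
#' Four columns: chromosome, marker id, genetic position (cM), physical
#' position (left 0, unknown).
#'
#' @param map A `genome_map`.
#' @param path Output file.
#' @export
write_plink_map <- function(map, path) {
  m <- map_markers(map)
  readr::write_tsv(
    tibble(chrom = m$chrom, id = m$locus_id, cM = m$pos_cM, bp = 0L),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Export / import phenotypes
#'
#' Two-column TSV: individual id and phenotype.
#'
#' @param phenotypes Tibble with `id` and `phenotype` columns (e.g.
#'   `trait$phenotypes`).
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(dplyr::select(phenotypes, "id", "phenotype"), path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export the QTL effect table
#'
#' TSV of QTL id, chromosome, position, additive effect and the major/minor
#' flag.
#'
#' @param effects An `effect_set`.
#' @param path Output file.
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(as_tibble(effects), path)
  invisible(path)
}

#' Export structure covariates
#'
#' TSV of individual id and PC scores; [write_scree()] writes the
#' per-component variance-explained table.
#'
#' @param pca A `structure_pca`.
#' @param id Individual ids (defaults to row numbers).
#' @param path Output file.
#' @export
write_covariates <- function(pca, path, id = seq_len(nrow(pca$scores))) {
  readr::write_tsv(dplyr::bind_cols(tibble(id = id), as_tibble(pca$scores)),
                   path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
}

#' @rdname write_covariates
#' @export
write_scree <- function(pca, path) {
  readr::write_tsv(tidy(pca), path)
  invisible(path)
}

#' Export LD pairs
#'
#' @param pairs An `ld_pairs` tibble.
#' @param path Output file.
#' @export
write_ld_pairs <- function(pairs, path) {
  readr::write_tsv(as_tibble(pairs), path)
  invisible(path)
}

#' Export / import scan results
#'
#' CSV with marker id, chromosome, position, method, tau (empty for the
#' GLM), effect, statistic, p-value, q-value and the 0/1 significance call.
#'
#' @param scan A `gwas_scan`.
#' @param path Output file.
#' @export
write_scan <- function(scan, path) {
  out <- dplyr::mutate(tidy(scan), significant = as.integer(.data$significant))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$significant <- as.logical(df$significant)
  df
}

#' Export a population as VCF v4.2
#'
#' Phased genotypes (`GT` field, `a|b`) from the internal haplotypes; marker
#' positions are encoded as integer basepairs at 10 kb per 0.01 cM so the
#' ordering is preserved.
#'
#' @param pop A `population`.
#' @param path Output file.
#' @export
write_vcf <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  sel <- which(pop$loci$type == "marker")
  loci <- pop$loci[sel, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=qrgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  samples <- paste0("ind", pop$id)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  H1 <- t(pop$H1[, sel, drop = FALSE])
  H2 <- t(pop$H2[, sel, drop = FALSE])
  gt <- matrix(paste0(H1, "|", H2), nrow = nrow(H1))
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chrom[i], as.integer(round(loci$pos_cM[i] * 1e6)) + 1L,
            loci$locus_id[i], "A", "T", ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a study configuration in YAML
#'
#' Serializes a [sim_config()] plus scenario settings; `read_study_config`
#' restores the `sim_config` (the frequency law is rebuilt from its type and
#' parameters).
#'
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$law <- c(list(type = config$law$type), config$law$params)
  lst$K <- lst$K %||% "auto"
  lst$max_pairs <- lst$max_pairs %||% "all"
  yaml::write_yaml(lst[setdiff(names(lst), "sample")], path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  law <- do.call(freq_law, lst$law)
  lst$law <- NULL
  if (identical(lst$K, "auto")) lst$K <- NULL
  if (identical(lst$max_pairs, "all")) lst$max_pairs <- NULL
  do.call(sim_config, c(lst, list(law = law)))
}
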