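#' Derive a child seed from a master seed
#'
#' Deterministic hierarchical seed derivation: every simulation stage of a
#' scenario replicate (genome map, parental frequencies, composite, families,
#' downsampling, effects, phenotypes) receives its own stream so stages are
#' independently reproducible. Uses a Lehmer-style integer recurrence carried
#' out in doubles (all intermediates < 2^53, result < 2^31).
#'
#' @param master Integer master seed.
#' @param ... Further integer tags (replicate number, stage code, ...).
#' @return A single integer seed in `[0, 2147483646]`.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  tags <- c(...)
  s <- abs(as.double(master)) %% 2147483647
  for (x in c(tags, 17L)) {
    s <- (s * 48271 + abs(as.double(x)) + 1) %% 2147483647
  }
  as.integer(s)
}

# Internal stage codes for derive_seed()
.stage <- c(
  map = 1L, parents = 2L, composite = 3L, families = 4L, downsample = 5L,
  effects = 6L, phenotype = 7L, ld = 8L, scan = 9L
)

# Evaluate expr under a temporary seed (global RNG state restored afterwards);
# with seed = NULL the current RNG stream is used.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}
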