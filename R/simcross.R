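#' Simulate genotypes for a two-genotype cross
#'
#' Genotypes are generated chromosome by chromosome as a two-state Markov
#' chain per individual: the chromosome-initial marker is 0 or 1 with
#' probability 1/2 each, and each subsequent marker flips state with
#' probability equal to the recombination fraction of the interval.
#' Chromosomes assort independently.  Backcross and doubled-haploid
#' populations share this genotype process: both have two equifrequent
#' genotype classes per marker, coded 0/1.
#'
#' @param map A [genetic_map()].
#' @param n_obs Number of individuals (>= 1).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return Integer matrix `n_obs x n_m` with entries in `{0, 1}`; columns
#'   named by marker.
#' @examples
#' map <- genetic_map(paste0("m", 1:3), chr = 1, pos = c(0, 10, 20))
#' g <- sim_geno(map, n_obs = 5, seed = 1)
#' @export
sim_geno <- function(map, n_obs, seed) {
  stopifnot(inherits(map, "genetic_map"))
  n_obs <- check_count(n_obs, "n_obs")
  n_m <- nrow(map)
  r <- map_transition_r(map)
  withr::with_seed(seed, {
    g <- matrix(0L, n_obs, n_m, dimnames = list(NULL, map$marker))
    g[, 1] <- as.integer(stats::runif(n_obs) < 0.5)
    for (j in seq_len(n_m)[-1]) {
      flip <- stats::runif(n_obs) < r[j]
      g[, j] <- ifelse(flip, 1L - g[, j - 1L], g[, j - 1L])
    }
    g
  })
}

#' Simulate phenotypes with no genetic effect
#'
#' Draws i.i.d. standard-normal phenotypes, the null model of a genome
#' scan: the trait is independent of every marker genotype.
#'
#' @param n_obs Number of individuals.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_obs`.
#' @export
sim_null_pheno <- function(n_obs, seed) {
  n_obs <- check_count(n_obs, "n_obs")
  withr::with_seed(seed, stats::rnorm(n_obs))
}

#' Simulate phenotypes with a single additive QTL
#'
#' Phenotype = `effect` times the genotype indicator at `qtl_marker`
#' plus standard-normal noise.  With `effect = 0` this reduces to
#' [sim_null_pheno()] in distribution.
#'
#' @param geno Genotype matrix as produced by [sim_geno()].
#' @param qtl_marker Column index (1-based) of the marker carrying the QTL.
#' @param effect Additive effect size in phenotype SD units.
#' @param seed Integer seed.
#' @return Numeric phenotype vector.
#' @export
sim_qtl_pheno <- function(geno, qtl_marker, effect, seed) {
  stopifnot(is.matrix(geno))
  qtl_marker <- check_count(qtl_marker, "qtl_marker")
  if (qtl_marker > ncol(geno))
    stop(sprintf("'qtl_marker' (%d) outside 1..%d", qtl_marker, ncol(geno)),
         call. = FALSE)
  withr::with_seed(seed,
    effect * geno[, qtl_marker] + stats::rnorm(nrow(geno)))
}

#' Assemble a cross population
#'
#' Bundles a complete genotype matrix, a phenotype vector and a marker map
#' into a `cross_pop` object, the input to [genome_scan()] and
#' [sample_max_lod()].  Genotype data must be complete: missing genotypes
#' or phenotypes are rejected.
#'
#' @param geno Matrix `n_obs x n_m` with entries in `{0, 1}`, no missing
#'   values.
#' @param pheno Numeric vector of length `n_obs`, all finite.
#' @param map A [genetic_map()] with `ncol(geno)` markers.
#' @param cross_type `"doubled_haploid"` or `"backcross"`.  The two designs
#'   are analysed identically (two genotype classes); the tag is metadata.
#' @return An object of class `cross_pop`.
#' @export
cross_pop <- function(geno, pheno, map,
                      cross_type = c("doubled_haploid", "backcross")) {
  cross_type <- match.arg(cross_type)
  stopifnot(inherits(map, "genetic_map"), is.matrix(geno))
  if (anyNA(geno) || anyNA(pheno) || any(!is.finite(pheno)))
    stop("genotype and phenotype data must be complete (no missing values)",
         call. = FALSE)
  if (!all(geno %in% c(0L, 1L)))
    stop("genotypes must be coded 0/1 (two genotype classes)", call. = FALSE)
  if (nrow(geno) < 3)
    stop("need at least 3 individuals for marker regression", call. = FALSE)
  if (ncol(geno) != nrow(map))
    stop(sprintf("genotype matrix has %d columns but map has %d markers",
                 ncol(geno), nrow(map)), call. = FALSE)
  if (length(pheno) != nrow(geno))
    stop("phenotype length must equal the number of individuals", call. = FALSE)
  structure(list(geno = geno, pheno = as.numeric(pheno), map = map,
                 cross_type = cross_type),
            class = "cross_pop")
}

#' @export
print.cross_pop <- function(x, ...) {
  cat(sprintf("%s population: %d individuals, %d markers on %d chromosome(s)\n",
              gsub("_", " ", x$cross_type), nrow(x$geno), ncol(x$geno),
              length(unique(x$map$chr))))
  invisible(x)
}

#' Simulate a complete cross population
#'
#' Convenience wrapper: simulates genotypes from a map, then a null or
#' single-QTL phenotype, and returns a [cross_pop()].  Genotype and
#' phenotype streams use seeds derived from the one root `seed`.
#'
#' @inheritParams sim_geno
#' @param cross_type `"doubled_haploid"` or `"backcross"`.
#' @param qtl_marker Optional marker index carrying a QTL.
#' @param effect Additive QTL effect (ignored unless `qtl_marker` is set).
#' @return A `cross_pop`.
#' @examples
#' pop <- sim_cross(example_map_34(), n_obs = 200, seed = 7)
#' @export
sim_cross <- function(map, n_obs, seed,
                      cross_type = c("doubled_haploid", "backcross"),
                      qtl_marker = NULL, effect = 0) {
  cross_type <- match.arg(cross_type)
  geno <- sim_geno(map, n_obs, derive_seed(seed, 1L))
  pheno <- if (is.null(qtl_marker))
    sim_null_pheno(n_obs, derive_seed(seed, 2L))
  else
    sim_qtl_pheno(geno, qtl_marker, effect, derive_seed(seed, 2L))
  cross_pop(geno, pheno, map, cross_type)
}
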