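#' Permutation sample of the max-LOD pair (delta, lambda)
#'
#' Builds the empirical null distribution of the genome-scan maximum
#' \eqn{M = (\delta, \lambda)} by repeatedly permuting the phenotype
#' vector (a uniform random shuffle, genotypes untouched), rescanning the
#' genome, and recording the magnitude and marker index of the maximum
#' LOD.  This is the raw material for both the constant genome-wide
#' threshold and the location-dependent threshold: the latter needs the
#' full list of pairs, not just the `delta` margin, because it conditions
#' on `lambda`.
#'
#' Permutations are processed in fixed-size chunks; chunk `k` of a run
#' rooted at `seed` draws its randomness from a seed derived as
#' `(seed + 1000003 * (chunk_offset + k)) mod (2^31 - 1)`.  Results are
#' therefore identical however chunks are scheduled, and a run may be
#' split across calls: `sample_max_lod(pop, a, s)` followed by
#' `sample_max_lod(pop, b, s, chunk_offset = a / chunk_size)` reproduces
#' the first `a + b` draws of one big run whenever `a` is a multiple of
#' `chunk_size`.
#'
#' @param pop A [cross_pop()].
#' @param n_p Number of permutation samples (>= 1).  See
#'   [required_permutations()] for how many are enough to resolve the
#'   location distribution.
#' @param seed Integer root seed.
#' @param tie_rule Tie-breaking for the argmax, see [max_lod()].
#' @param chunk_size Permutations per internal chunk (default 1000).
#'   Affects the random stream, so it is recorded in the result; two runs
#'   agree only if their `chunk_size` agrees.
#' @param chunk_offset Chunk index offset for split runs (default 0).
#' @return A `maxlod_sample`: list with `delta` (numeric, length `n_p`),
#'   `lambda` (integer marker indices), `n_m`, `n_p`, `seed`, `tie_rule`,
#'   `chunk_size`, `chunk_offset`.
#' @examples
#' pop <- sim_cross(example_map_34(), n_obs = 100, seed = 3)
#' smp <- sample_max_lod(pop, n_p = 500, seed = 11)
#' table(smp$lambda)[1:5]
#' @export
sample_max_lod <- function(pop, n_p, seed, tie_rule = c("random", "first"),
                           chunk_size = 1000L, chunk_offset = 0L) {
  stopifnot(inherits(pop, "cross_pop"))
  n_p <- check_count(n_p, "n_p")
  chunk_size <- check_count(chunk_size, "chunk_size")
  tie_rule <- match.arg(tie_rule)
  n_obs <- nrow(pop$geno)
  n_chunks <- ceiling(n_p / chunk_size)

  delta <- numeric(n_p)
  lambda <- integer(n_p)
  y <- pop$pheno
  for (k in seq_len(n_chunks)) {
    lo <- (k - 1L) * chunk_size + 1L
    keep <- min(chunk_size, n_p - lo + 1L)
    chunk <- withr::with_seed(derive_seed(seed, chunk_offset + k), {
      idx <- vapply(seq_len(chunk_size), function(i) sample.int(n_obs),
                    integer(n_obs))
      L <- lod_matrix(pop$geno, matrix(y[idx], nrow = n_obs))
      lam <- max.col(L, ties.method = if (tie_rule == "random") "random"
                                      else "first")
      list(lam = lam, d = L[cbind(seq_len(nrow(L)), lam)])
    })
    delta[lo:(lo + keep - 1L)] <- chunk$d[seq_len(keep)]
    lambda[lo:(lo + keep - 1L)] <- chunk$lam[seq_len(keep)]
  }
  structure(list(delta = delta, lambda = lambda, n_m = ncol(pop$geno),
                 n_p = n_p, seed = seed, tie_rule = tie_rule,
                 chunk_size = chunk_size, chunk_offset = chunk_offset),
            class = "maxlod_sample")
}

#' @export
print.maxlod_sample <- function(x, ...) {
  cat(sprintf(
    "Max-LOD permutation sample: n_p = %d draws over %d markers (seed %s)\n",
    x$n_p, x$n_m, format(x$seed)))
  cat(sprintf("  delta: min %.3f, median %.3f, max %.3f\n",
              min(x$delta), stats::median(x$delta), max(x$delta)))
  invisible(x)
}

# internal constructor used by the CSV reader; validates invariants
new_maxlod_sample <- function(delta, lambda, n_m, seed = NA_integer_,
                              tie_rule = "random") {
  lambda <- as.integer(lambda)
  if (length(delta) != length(lambda) || length(delta) < 1L)
    stop("'delta' and 'lambda' must be equal-length, non-empty", call. = FALSE)
  if (any(delta < 0) || anyNA(delta))
    stop("all delta values must be non-negative", call. = FALSE)
  if (any(lambda < 1L) || any(lambda > n_m) || anyNA(lambda))
    stop(sprintf("lambda values must lie in 1..%d", n_m), call. = FALSE)
  structure(list(delta = as.numeric(delta), lambda = lambda,
                 n_m = as.integer(n_m), n_p = length(delta), seed = seed,
                 tie_rule = tie_rule, chunk_size = NA_integer_,
                 chunk_offset = 0L),
            class = "maxlod_sample")
}

#' Permutation sample size needed to resolve the location distribution
#'
#' Estimating the lambda-conditioned max-LOD distributions needs roughly
#' 1000 draws of the maximum *at every marker*.  Given a pilot estimate of
#' the location distribution, the requirement is
#' `ceil(min_count / min_i p_lambda_i)`; without one, the rule of thumb
#' for moderate location bias is `5000 * n_m` samples.
#'
#' @param n_m Number of markers.
#' @param min_count Target number of conditional draws per marker
#'   (default 1000).
#' @param p_lambda Optional pilot location distribution (probabilities per
#'   marker).  A marker with zero probability can never accumulate draws;
#'   the function then returns `Inf` with a warning.
#' @return Required number of permutations (or `Inf`).
#' @examples
#' required_permutations(34)                      # rule of thumb: 170000
#' required_permutations(4, p_lambda = rep(0.25, 4))
#' @export
required_permutations <- function(n_m, min_count = 1000, p_lambda = NULL) {
  n_m <- check_count(n_m, "n_m")
  min_count <- check_count(min_count, "min_count")
  if (is.null(p_lambda)) return(5000 * n_m)
  if (length(p_lambda) != n_m)
    stop("'p_lambda' length must equal 'n_m'", call. = FALSE)
  if (any(p_lambda <= 0)) {
    warning(sprintf(
      "marker(s) %s have zero estimated probability of attaining the maximum; no finite sample size suffices",
      paste(which(p_lambda <= 0), collapse = ", ")), call. = FALSE)
    return(Inf)
  }
  ceiling(min_count / min(p_lambda))
}
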