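#' LOD score of single-marker regression
#'
#' Gaussian-likelihood LOD for regression of a quantitative phenotype on a
#' two-class genotype indicator:
#' \deqn{LOD = (n/2)\,\log_{10}(RSS_0 / RSS_1),}
#' where \eqn{RSS_0} is the residual sum of squares about the grand mean
#' and \eqn{RSS_1} the residual sum of squares of the two-group-mean fit
#' (the least-squares regression on the indicator).  Equivalently
#' \eqn{LOD = -(n/2)\log_{10}(1 - R^2)}.  A monomorphic marker column, or
#' a constant phenotype, scores 0 — permuted data sets must always yield a
#' full scan.
#'
#' Perfect fits (\eqn{RSS_1 = 0}) are floored at machine precision so that
#' the score stays finite; this only matters for pathological inputs.
#'
#' @param geno Genotype column, values in `{0, 1}`, length n >= 3.
#' @param pheno Numeric phenotype vector of the same length, all finite.
#' @return A single non-negative LOD value.
#' @examples
#' marker_lod(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 3, 4, 5))
#' @export
marker_lod <- function(geno, pheno) {
  n <- length(pheno)
  if (length(geno) != n)
    stop("genotype and phenotype lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(geno) || anyNA(pheno) || any(!is.finite(pheno)))
    stop("missing or non-finite values are not allowed", call. = FALSE)
  if (!all(geno %in% c(0, 1)))
    stop("genotypes must be coded 0/1", call. = FALSE)

  one <- geno == 1
  n1 <- sum(one)
  if (n1 == 0L || n1 == n) return(0)          # monomorphic marker
  rss0 <- sum((pheno - mean(pheno))^2)
  if (rss0 == 0) return(0)                    # constant phenotype
  rss1 <- sum((pheno[one] - mean(pheno[one]))^2) +
          sum((pheno[!one] - mean(pheno[!one]))^2)
  (n / 2) * log10(rss0 / max(rss1, rss0 * .Machine$double.eps))
}

# LOD scores for all markers against many phenotype columns at once, via
# the correlation identity LOD = -(n/2) log10(1 - r^2).  G: n x n_m in
# {0,1}; Y: n x k numeric.  Returns k x n_m matrix (rows = phenotype
# columns) so that per-scan maxima are row operations.
lod_matrix <- function(G, Y) {
  n <- nrow(G)
  sg <- apply(G, 2, stats::sd)
  mono <- sg == 0
  Gs <- G
  Gs[, !mono] <- scale(G[, !mono, drop = FALSE])
  Gs[, mono] <- 0
  sy <- apply(Y, 2, stats::sd)
  flat <- sy == 0
  Ys <- Y
  Ys[, !flat] <- scale(Y[, !flat, drop = FALSE])
  Ys[, flat] <- 0
  r <- crossprod(Ys, Gs) / (n - 1)            # k x n_m
  one_minus_r2 <- pmax(1 - r * r, .Machine$double.eps)
  -(n / 2) * log10(one_minus_r2)
}

#' Genome scan by marker regression
#'
#' Computes [marker_lod()] for every marker of a cross population.
#'
#' @param pop A [cross_pop()].
#' @return A `genome_scan`: data frame with columns `marker`, `chr`, `pos`,
#'   `lod`, in map order.
#' @examples
#' pop <- sim_cross(example_map_34(), n_obs = 100, seed = 3)
#' scan <- genome_scan(pop)
#' max_lod(scan, seed = 1)
#' @export
genome_scan <- function(pop) {
  stopifnot(inherits(pop, "cross_pop"))
  lod <- as.numeric(lod_matrix(pop$geno, matrix(pop$pheno, ncol = 1)))
  out <- data.frame(marker = pop$map$marker, chr = pop$map$chr,
                    pos = pop$map$pos, lod = lod, stringsAsFactors = FALSE)
  class(out) <- c("genome_scan", "data.frame")
  out
}

#' @export
print.genome_scan <- function(x, ...) {
  i <- which.max(x$lod)
  cat(sprintf("Genome scan: %d markers; max LOD %.3f at %s (index %d)\n",
              nrow(x), x$lod[i], x$marker[i], i))
  invisible(x)
}

#' Maximum of a genome scan: the pair (delta, lambda)
#'
#' Extracts the joint max statistic of a scan: `delta`, the largest LOD
#' value, and `lambda`, the 1-based index of the marker attaining it.
#' Ties (rare for continuous phenotypes, common in degenerate all-zero
#' scans) are broken per `tie_rule`: `"random"` picks uniformly among the
#' tied markers (seed-reproducible), `"first"` takes the lowest index.
#' The default is random because a deterministic rule would push the
#' location distribution toward low indices — exactly the kind of
#' artificial location bias this package is built to measure.
#'
#' @param scan A `genome_scan` or a bare numeric LOD vector.
#' @param tie_rule `"random"` or `"first"`.
#' @param seed Integer seed for random tie-breaking (required when
#'   `tie_rule = "random"`).
#' @return List with elements `delta` and `lambda`.
#' @export
max_lod <- function(scan, tie_rule = c("random", "first"), seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  lod <- if (inherits(scan, "genome_scan")) scan$lod else as.numeric(scan)
  if (length(lod) == 0) stop("empty scan", call. = FALSE)
  delta <- max(lod)
  ties <- which(lod == delta)
  lam <- if (length(ties) == 1L || tie_rule == "first") {
    ties[1L]
  } else {
    if (is.null(seed))
      stop("random tie-breaking needs a 'seed'", call. = FALSE)
    withr::with_seed(seed, ties[sample.int(length(ties), 1L)])
  }
  list(delta = delta, lambda = lam)
}
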