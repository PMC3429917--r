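#' Empirical location distribution and bias factors
#'
#' From a permutation sample of \eqn{M = (\delta, \lambda)}, estimates
#' \eqn{P\{\lambda = i\}} by the count proportions and derives the
#' location-bias factors \eqn{\alpha_i = [n_m P\{\lambda = i\}]^{-1}}.
#' Under no location bias every \eqn{\alpha_i = 1}; \eqn{\alpha_i > 1}
#' flags a marker that attains the genome-wide maximum less often than its
#' uniform share.
#'
#' Markers with zero counts get `alpha = Inf` and are flagged in
#' `$zero_count`; they are never silently assigned a finite bias factor.
#' Optional Laplace smoothing (`smooth = TRUE`, adds 1 to every count) is
#' available for exploratory use but is off by default: the honest remedy
#' for empty strata is more permutations ([required_permutations()]).
#'
#' @param sample A [sample_max_lod()] result.
#' @param smooth Add-one smoothing of the lambda counts (default `FALSE`).
#' @return A `location_dist`: list with `p_lambda`, `alpha`, `counts`,
#'   `n_m`, `n_p`, `zero_count` (logical), `smoothed`.
#' @examples
#' pop <- sim_cross(example_map_34(), n_obs = 100, seed = 3)
#' ld <- location_distribution(sample_max_lod(pop, 2000, seed = 5))
#' range(ld$alpha)
#' @export
location_distribution <- function(sample, smooth = FALSE) {
  stopifnot(inherits(sample, "maxlod_sample"))
  counts <- tabulate(sample$lambda, nbins = sample$n_m)
  zero <- counts == 0L
  if (smooth) {
    p <- (counts + 1) / (sample$n_p + sample$n_m)
  } else {
    p <- counts / sample$n_p
  }
  alpha <- ifelse(p > 0, 1 / (sample$n_m * p), Inf)
  structure(list(p_lambda = p, alpha = alpha, counts = counts,
                 n_m = sample$n_m, n_p = sample$n_p, zero_count = zero,
                 smoothed = smooth),
            class = "location_dist")
}

#' @export
print.location_dist <- function(x, ...) {
  cat(sprintf("Location distribution over %d markers (n_p = %d%s)\n",
              x$n_m, x$n_p, if (x$smoothed) ", smoothed" else ""))
  cat(sprintf("  p_lambda in [%.4g, %.4g]; alpha in [%.3g, %.3g]\n",
              min(x$p_lambda), max(x$p_lambda), min(x$alpha), max(x$alpha)))
  if (any(x$zero_count))
    cat(sprintf("  WARNING: %d marker(s) with zero counts: %s\n",
                sum(x$zero_count),
                paste(which(x$zero_count), collapse = ", ")))
  cat(sprintf("  validity range for LDT thresholds: (0, %.4g)\n",
              validity_range(x)))
  invisible(x)
}

#' Empirical exceedance probability
#'
#' Fraction of sampled values strictly greater than `t`.
#'
#' @param values Non-empty numeric vector.
#' @param t Cut point(s).
#' @return Probability estimate(s) in `[0, 1]`.
#' @export
empirical_exceedance <- function(values, t) {
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  vapply(t, function(ti) mean(values > ti), numeric(1))
}

#' Empirical threshold at a target exceedance level
#'
#' Returns the smallest sampled value `t*` whose strict exceedance
#' `#{v > t*}/n` does not exceed `target`.  Taking an order statistic of
#' the sample (rather than an interpolated quantile) guarantees the
#' realised error rate never exceeds the nominal one; with heavy ties the
#' realised exceedance can sit strictly below the target, the familiar
#' conservatism of discrete empirical distributions.
#'
#' @param values Non-empty numeric vector of sampled statistics.
#' @param target Target exceedance probability in (0, 1].
#' @return A single threshold value (an element of `values`).
#' @examples
#' quantile_threshold(1:100, 0.20)  # 80: exactly 20 values exceed
#' @export
quantile_threshold <- function(values, target) {
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  target <- check_prob(target, "target", open_upper = FALSE)
  s <- sort(values)
  n <- length(s)
  # strict exceedance just above each order statistic; ties share the
  # exceedance of their last occurrence
  exc <- (n - seq_len(n)) / n
  last_of_tie <- c(s[-1] != s[-n], TRUE)
  ok <- last_of_tie & (exc <= target + 1e-12)
  s[which.max(ok)]
}

new_threshold_result <- function(T, gamma, method, valid_range_upper,
                                 ld = NULL, n_p = NA_integer_) {
  structure(list(T = T, gamma = gamma, method = method,
                 valid_range_upper = valid_range_upper,
                 location = ld, n_p = n_p),
            class = "qtl_threshold")
}

#' @export
print.qtl_threshold <- function(x, ...) {
  cat(sprintf("%s threshold at GWER gamma = %g (n_p = %s)\n",
              x$method, x$gamma, format(x$n_p)))
  if (length(unique(x$T)) == 1L)
    cat(sprintf("  constant T = %.4f across %d markers\n",
                x$T[1], length(x$T)))
  else
    cat(sprintf("  T in [%.4f, %.4f] across %d markers\n",
                min(x$T), max(x$T), length(x$T)))
  if (is.finite(x$valid_range_upper) && x$method == "LDT")
    cat(sprintf("  valid for gamma in (0, %.4g)\n", x$valid_range_upper))
  invisible(x)
}

#' Constant genome-wide permutation threshold
#'
#' The classical permutation threshold: the empirical `(1 - gamma)`
#' quantile of the marginal max-LOD null, replicated across all markers.
#' It satisfies \eqn{P\{\delta > T\} \le \gamma} on the permutation sample
#' but ignores where the maximum lands, so under location bias the local
#' error rate varies along the genome.
#'
#' @param sample A [sample_max_lod()] result.
#' @param gamma Desired genome-wide error rate in (0, 1).
#' @return A `qtl_threshold` with a constant `T` vector, `method = "CD"`.
#' @export
cd_threshold <- function(sample, gamma) {
  stopifnot(inherits(sample, "maxlod_sample"))
  gamma <- check_prob(gamma, "gamma")
  t_cd <- quantile_threshold(sample$delta, gamma)
  ld <- location_distribution(sample)
  new_threshold_result(rep(t_cd, sample$n_m), gamma, "CD",
                       validity_range(ld), ld, sample$n_p)
}

stop_zero_count <- function(ld) {
  bad <- which(ld$zero_count)
  if (length(bad))
    stop(sprintf(
      paste0("marker(s) %s never attain the genome-wide maximum in this ",
             "sample; conditional thresholds are undefined there. Increase ",
             "n_p (aim for >= 1000 conditional draws per marker, see ",
             "required_permutations())."),
      paste(bad, collapse = ", ")), call. = FALSE)
}

#' Location-conditioned threshold at a constant local rate
#'
#' Per-marker thresholds \eqn{T_{\lambda}} with
#' \eqn{P\{\delta > T_{\lambda_i} \mid \lambda = i\} = \gamma}: each
#' marker's threshold is the `(1 - gamma)` empirical quantile of the
#' max-LOD values that occurred *at that marker*.  This holds the local
#' (conditional) error rate constant but does not by itself control the
#' genome-wide rate; it is the starting point the location-dependent
#' threshold adjusts.
#'
#' @inheritParams cd_threshold
#' @return A `qtl_threshold` with `method = "conditional"`.
#' @export
conditional_threshold <- function(sample, gamma) {
  stopifnot(inherits(sample, "maxlod_sample"))
  gamma <- check_prob(gamma, "gamma")
  ld <- location_distribution(sample)
  stop_zero_count(ld)
  T <- vapply(seq_len(sample$n_m), function(i)
    quantile_threshold(sample$delta[sample$lambda == i], gamma), numeric(1))
  new_threshold_result(T, gamma, "conditional", validity_range(ld), ld,
                       sample$n_p)
}

#' Location-dependent threshold preserving the genome-wide error rate
#'
#' The core method of this package.  For a desired genome-wide error rate
#' `gamma`, the location-dependent threshold `T_LDT` satisfies, at every
#' marker,
#' \deqn{P\{\delta > T_{LDT,i},\ \lambda = i\} = \gamma / n_m,}
#' so the genome-wide rate sums to `gamma` while the joint error mass is
#' spread evenly across markers — a constant local error rate.  It is
#' built from the lambda-conditioned empirical distributions: marker `i`'s
#' threshold is the conditional quantile at exceedance level
#' \eqn{\gamma \alpha_i}, where \eqn{\alpha_i = [n_m P\{\lambda=i\}]^{-1}}
#' is the location-bias factor.  Where the maximum lands less often than
#' its uniform share (\eqn{\alpha_i > 1}) the threshold is lowered
#' relative to the constant-local-rate threshold, and raised where it
#' lands more often.
#'
#' The construction exists only for
#' \eqn{\gamma < \min_i\{1/\alpha_i\} = n_m \min_i P\{\lambda = i\}}
#' (beyond that, some conditional exceedance target
#' \eqn{\gamma \alpha_i} would exceed 1); requesting a `gamma` at or above
#' this bound is an error that reports the bound.
#'
#' @inheritParams cd_threshold
#' @param smooth Passed to [location_distribution()].
#' @return A `qtl_threshold` with `method = "LDT"`.
#' @examples
#' pop <- sim_cross(example_map_34(), n_obs = 150, seed = 3)
#' smp <- sample_max_lod(pop, required_permutations(34), seed = 5)
#' thr <- ldt_threshold(smp, gamma = 0.20)
#' range(thr$T)
#' @export
ldt_threshold <- function(sample, gamma, smooth = FALSE) {
  stopifnot(inherits(sample, "maxlod_sample"))
  gamma <- check_prob(gamma, "gamma")
  ld <- location_distribution(sample, smooth = smooth)
  stop_zero_count(ld)
  v <- validity_range(ld)
  if (gamma >= v)
    stop(sprintf(
      paste0("gamma = %g is outside the validity range of the ",
             "location-dependent threshold for this sample: gamma must be ",
             "below min_i{1/alpha_i} = %.6g"), gamma, v), call. = FALSE)
  T <- vapply(seq_len(sample$n_m), function(i)
    quantile_threshold(sample$delta[sample$lambda == i],
                       gamma * ld$alpha[i]), numeric(1))
  new_threshold_result(T, gamma, "LDT", v, ld, sample$n_p)
}

#' Upper end of the validity range for location-dependent thresholds
#'
#' The location-dependent construction preserves the genome-wide error
#' rate only for `gamma` in `(0, min_i{1/alpha_i})`, i.e. below
#' `n_m * min_i p_lambda_i`.  With any zero-count marker the range is
#' empty and 0 is returned (with the flag preserved on the input).
#'
#' @param x A `location_dist` or a `maxlod_sample`.
#' @return The upper bound `min_i{1/alpha_i}`.
#' @export
validity_range <- function(x) {
  if (inherits(x, "maxlod_sample")) x <- location_distribution(x)
  stopifnot(inherits(x, "location_dist"))
  x$n_m * min(x$p_lambda)
}

#' Genome-wide adjusted P-value from the marginal max-LOD null
#'
#' The standard permutation-adjusted P-value: the proportion of sampled
#' genome-wide maxima at least as large as the observed LOD, with the
#' add-one correction `(r + 1)/(n_p + 1)` so the estimate is a valid
#' P-value and never exactly zero.
#'
#' @param sample A [sample_max_lod()] result.
#' @param observed_lod Observed LOD score(s).
#' @return Adjusted P-value(s) in `(0, 1]`.
#' @export
cd_adjusted_p <- function(sample, observed_lod) {
  stopifnot(inherits(sample, "maxlod_sample"))
  vapply(observed_lod, function(t)
    (sum(sample$delta >= t) + 1) / (sample$n_p + 1), numeric(1))
}

#' Location-adjusted P-value from the conditional max-LOD null
#'
#' The location-dependent analogue of [cd_adjusted_p()]: the smallest
#' genome-wide rate `gamma` at which the observed LOD at `marker` would
#' cross its location-dependent threshold.  It is a linear transform of
#' the location-conditioned permutation P-value,
#' \deqn{p = n_m \cdot \frac{\#\{j : \lambda_j = i,\ \delta_j \ge
#'   \mathrm{obs}\} + 1}{n_p + 1}
#'     = \frac{1}{\alpha_i}\, p_{\mathrm{cond}},}
#' capped at 1 for reporting.  The smallest value the *uncapped* transform
#' can approach at marker `i` as the observed LOD grows is
#' `n_m/(n_p + 1)`; its largest is about \eqn{1/\alpha_i} — beyond the
#' validity range of the method, P-values are driven by the location
#' alone.  Use `cap = FALSE` to obtain the raw transform, and
#' [adjust_scan()] for a per-marker table that also reports the
#' attainable maximum.
#'
#' @param sample A [sample_max_lod()] result.
#' @param observed_lod Observed LOD score(s).
#' @param marker Marker index (1-based) at which the LOD was observed;
#'   recycled against `observed_lod`.
#' @param cap Cap the reported value at 1 (default `TRUE`).
#' @return Adjusted P-value(s).
#' @export
ldt_adjusted_p <- function(sample, observed_lod, marker, cap = TRUE) {
  stopifnot(inherits(sample, "maxlod_sample"))
  if (any(marker < 1L) || any(marker > sample$n_m) || anyNA(marker))
    stop(sprintf("'marker' must lie in 1..%d", sample$n_m), call. = FALSE)
  k <- max(length(observed_lod), length(marker))
  observed_lod <- rep_len(observed_lod, k)
  marker <- rep_len(as.integer(marker), k)
  p <- vapply(seq_len(k), function(j) {
    r <- sum(sample$lambda == marker[j] & sample$delta >= observed_lod[j])
    sample$n_m * (r + 1) / (sample$n_p + 1)
  }, numeric(1))
  if (cap) pmin(p, 1) else p
}

#' Adjusted P-values for a whole genome scan
#'
#' Convenience table: for every marker of a scan, the observed LOD, the
#' genome-wide (marginal) adjusted P-value, the location-adjusted
#' P-value, its uncapped value, and the largest location-adjusted P-value
#' attainable at that marker (about `1/alpha_i`; values pinned near this
#' ceiling carry location information only).
#'
#' @param sample A [sample_max_lod()] result.
#' @param scan A [genome_scan()] of the same population.
#' @return Data frame with columns `marker`, `chr`, `pos`, `lod`, `p_cd`,
#'   `p_ldt`, `p_ldt_uncapped`, `p_ldt_max_attainable`.
#' @export
adjust_scan <- function(sample, scan) {
  stopifnot(inherits(scan, "genome_scan"))
  if (nrow(scan) != sample$n_m)
    stop("scan and sample disagree on the number of markers", call. = FALSE)
  idx <- seq_len(sample$n_m)
  counts <- tabulate(sample$lambda, nbins = sample$n_m)
  raw <- ldt_adjusted_p(sample, scan$lod, idx, cap = FALSE)
  data.frame(marker = scan$marker, chr = scan$chr, pos = scan$pos,
             lod = scan$lod,
             p_cd = cd_adjusted_p(sample, scan$lod),
             p_ldt = pmin(raw, 1),
             p_ldt_uncapped = raw,
             p_ldt_max_attainable =
               sample$n_m * (counts + 1) / (sample$n_p + 1),
             stringsAsFactors = FALSE)
}

#' Realised exceedance of a threshold on a permutation sample
#'
#' Measures how often sampled maxima cross a (possibly location-dependent)
#' threshold: per marker, the joint exceedance
#' `#{j : delta_j > T_i, lambda_j = i} / n_p`, and their genome-wide sum
#' `P{delta > T_lambda}`.  Evaluating a threshold on a *fresh* sample
#' (different seed, same population) gives an out-of-sample estimate of
#' the genome-wide error rate it actually delivers.
#'
#' @param sample A [sample_max_lod()] result.
#' @param threshold A `qtl_threshold`, or a bare numeric vector of
#'   per-marker thresholds (length `n_m` or 1).
#' @return List with `per_marker` (length `n_m`) and `genome_wide`.
#' @export
threshold_exceedance <- function(sample, threshold) {
  stopifnot(inherits(sample, "maxlod_sample"))
  T <- if (inherits(threshold, "qtl_threshold")) threshold$T else threshold
  T <- rep_len(as.numeric(T), sample$n_m)
  per <- vapply(seq_len(sample$n_m), function(i)
    sum(sample$delta > T[i] & sample$lambda == i) / sample$n_p, numeric(1))
  list(per_marker = per, genome_wide = sum(per))
}
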