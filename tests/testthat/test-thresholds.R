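test_that("location_distribution computes p_lambda and alpha by definition", {
  smp <- make_sample(runif(1000), rep(1:4, c(500, 250, 125, 125)), 4)
  ld <- location_distribution(smp)
  expect_equal(ld$p_lambda, c(0.5, 0.25, 0.125, 0.125))
  expect_equal(ld$alpha, c(0.5, 1, 2, 2))
  expect_equal(sum(ld$p_lambda), 1, tolerance = 1e-12)
  expect_false(any(ld$zero_count))

  uni <- location_distribution(make_sample(runif(400), rep(1:4, 100), 4))
  expect_equal(uni$alpha, rep(1, 4))
})

test_that("zero-count markers are flagged, never silently finite", {
  smp <- make_sample(runif(100), rep(c(1L, 2L), 50), 3)
  ld <- location_distribution(smp)
  expect_true(ld$zero_count[3])
  expect_identical(ld$alpha[3], Inf)
  expect_equal(validity_range(ld), 0)
  sm <- location_distribution(smp, smooth = TRUE)
  expect_true(is.finite(sm$alpha[3]))
  expect_true(sm$zero_count[3])  # flag survives smoothing
})

test_that("empirical_exceedance counts strictly and matches brute force", {
  expect_equal(empirical_exceedance(1:100, 80), 0.20)
  expect_equal(empirical_exceedance(1:10, 0), 1.0)
  expect_equal(empirical_exceedance(1:10, 10), 0.0)
  withr::with_seed(1, {
    v <- sample(round(rnorm(50), 2))
    for (t in c(-2, v[7], 0, v[30], 2))
      expect_equal(empirical_exceedance(v, t), bf_exceedance(v, t))
  })
})

test_that("quantile_threshold satisfies its defining post-condition", {
  expect_equal(quantile_threshold(1:100, 0.20), 80)
  expect_equal(quantile_threshold(1:100, 1.0), 1)
  expect_error(quantile_threshold(numeric(0), 0.5), "empty")

  withr::with_seed(2, {
    for (i in 1:50) {
      v <- sample(1:8, 40, replace = TRUE)     # heavy ties
      target <- runif(1, 0.02, 1)
      t_star <- quantile_threshold(v, target)
      expect_equal(t_star, bf_threshold(v, target))
      expect_lte(bf_exceedance(v, t_star), target)
      # smallest such sampled value: anything smaller over-exceeds
      smaller <- v[v < t_star]
      if (length(smaller))
        expect_gt(bf_exceedance(v, max(smaller)), target)
    }
  })
})

test_that("cd_threshold is the constant marginal quantile, blind to lambda", {
  smp <- make_sample(1:100, rep(1:4, 25), 4)
  thr <- cd_threshold(smp, 0.20)
  expect_equal(thr$T, rep(80, 4))
  expect_equal(thr$method, "CD")

  shuffled <- make_sample(1:100, sample(rep(1:4, 25)), 4)
  expect_equal(cd_threshold(shuffled, 0.20)$T, thr$T)

  # gamma below 1/n_p pins the threshold at the sample maximum
  expect_equal(cd_threshold(smp, 0.005)$T, rep(100, 4))
})

test_that("conditional_threshold takes per-stratum quantiles", {
  smp <- make_sample(c(1:10, 11:20), rep(1:2, each = 10), 2)
  expect_equal(conditional_threshold(smp, 0.2)$T, c(8, 18))

  single <- make_sample(c(1:10, 5), c(rep(1L, 10), 2L), 2)
  expect_equal(conditional_threshold(single, 0.5)$T[2], 5)

  holes <- make_sample(1:10, rep(1L, 10), 2)
  expect_error(conditional_threshold(holes, 0.2), "marker.*2")
  expect_error(conditional_threshold(holes, 0.2), "n_p|permutations|1000")
})

test_that("ldt_threshold enforces its validity range with an informative error", {
  smp <- toy60_sample()                      # p = (.5, .25, .25), v = 0.75
  v <- validity_range(location_distribution(smp))
  expect_equal(v, 0.75)
  expect_error(ldt_threshold(smp, v), "validity|min_i")
  expect_error(ldt_threshold(smp, v + 0.1), "0.75")
  expect_s3_class(ldt_threshold(smp, v - 0.01), "qtl_threshold")
})

test_that("ldt_threshold equalises the joint error mass at gamma/n_m", {
  smp <- toy60_sample()
  gamma <- 0.2
  thr <- ldt_threshold(smp, gamma)
  # exhaustive enumeration at every marker: joint exceedance == gamma/n_m
  for (i in 1:3) {
    expect_equal(bf_joint_exceedance(smp$delta, smp$lambda, thr$T, i),
                 gamma / 3, tolerance = 1e-12)
    # conditional target gamma * alpha_i, verified against brute force
    ld <- location_distribution(smp)
    expect_equal(thr$T[i],
                 bf_threshold(smp$delta[smp$lambda == i],
                              gamma * ld$alpha[i]))
  }
})

test_that("under-represented locations get lowered thresholds", {
  smp <- toy60_sample()
  thr_ldt <- ldt_threshold(smp, 0.2)
  thr_cond <- conditional_threshold(smp, 0.2)
  ld <- location_distribution(smp)
  # markers 2 and 3 have alpha > 1 (positive bias away from them)
  for (i in which(ld$alpha > 1))
    expect_lt(thr_ldt$T[i], thr_cond$T[i])
  for (i in which(ld$alpha < 1))
    expect_gt(thr_ldt$T[i], thr_cond$T[i])
})

test_that("uniform lambda with identical conditionals collapses LDT to CD", {
  delta <- rep(seq(0.5, 5, by = 0.5), 4)     # same 10 values per marker
  smp <- make_sample(delta, rep(1:4, each = 10), 4)
  expect_equal(ldt_threshold(smp, 0.2)$T, cd_threshold(smp, 0.2)$T)
})

test_that("adjusted P-values follow the (r+1)/(n+1) permutation convention", {
  smp <- make_sample(1:99, rep(1L, 99), 1)
  expect_equal(cd_adjusted_p(smp, 90), 0.11)
  expect_equal(cd_adjusted_p(smp, 1000), 1 / 100)
  expect_equal(cd_adjusted_p(smp, 0), 1)
  expect_equal(cd_adjusted_p(smp, c(90, 0)), c(0.11, 1))
})

test_that("ldt_adjusted_p matches exhaustive enumeration on the toy sample", {
  smp <- toy60_sample()
  for (obs in c(0.05, 1.55, 10.45, 20.75, 99))
    for (i in 1:3)
      expect_equal(ldt_adjusted_p(smp, obs, i),
                   bf_ldt_p(smp$delta, smp$lambda, obs, i, 3))
  # extreme observation: floor n_m/(n_p + 1)
  expect_equal(ldt_adjusted_p(smp, 1e6, 2), 3 / 61)
  expect_error(ldt_adjusted_p(smp, 1, 4), "1..3")
})

test_that("location-adjusted P is a linear transform of the conditional P", {
  smp <- toy60_sample()
  ld <- location_distribution(smp)
  for (i in 1:3) {
    m_i <- sum(smp$lambda == i)
    obs <- 0.95 * max(smp$delta[smp$lambda == i])
    p_cond <- (sum(smp$lambda == i & smp$delta >= obs) + 1) / (m_i + 1)
    p_ldt <- ldt_adjusted_p(smp, obs, i, cap = FALSE)
    expect_equal(p_ldt * ld$alpha[i] / p_cond, 1, tolerance = 2 / m_i)
  }
})

test_that("no location bias makes CD and LDT adjusted P-values agree", {
  delta <- rep(seq(0.1, 5, by = 0.1), 2)
  smp <- make_sample(delta, rep(1:2, each = 50), 2)
  for (obs in c(0.5, 2.05, 4.9)) {
    expect_lt(abs(ldt_adjusted_p(smp, obs, 1) - cd_adjusted_p(smp, obs)),
              2 / (smp$n_p + 1) + 1e-12)
  }
})

test_that("thresholds and adjusted P-values are monotone", {
  pop <- sim_cross(example_map_20(), 80, seed = 14)
  smp <- sample_max_lod(pop, 4000, seed = 15)
  gammas <- c(0.02, 0.05, 0.1, 0.2)
  cd <- vapply(gammas, function(g) cd_threshold(smp, g)$T[1], numeric(1))
  expect_true(all(diff(cd) <= 0))
  ldt <- vapply(gammas, function(g) ldt_threshold(smp, g)$T, numeric(20))
  expect_true(all(apply(ldt, 1, function(x) all(diff(x) <= 0))))
  obs_grid <- seq(0, 4, by = 0.25)
  expect_true(all(diff(cd_adjusted_p(smp, obs_grid)) <= 0))
  expect_true(all(diff(ldt_adjusted_p(smp, obs_grid, 3)) <= 0))
})

test_that("in-sample GWER identity holds for the LDT construction", {
  pop <- sim_cross(example_map_20(), 100, seed = 16)
  smp <- sample_max_lod(pop, 5000, seed = 18)
  gamma <- 0.25
  thr <- ldt_threshold(smp, gamma)
  ex <- threshold_exceedance(smp, thr)
  expect_true(all(ex$per_marker <= gamma / 20 + 1e-12))
  expect_lte(ex$genome_wide, gamma + 1e-12)
  expect_gte(ex$genome_wide, gamma - 20 / 5000)
})

test_that("LDT flattens the local error rate where CD cannot", {
  pop <- sim_cross(example_map_34(), 150, seed = 20)
  smp <- sample_max_lod(pop, 20000, seed = 22)
  gamma <- 0.2
  ldt_ex <- threshold_exceedance(smp, ldt_threshold(smp, gamma))
  cd_ex <- threshold_exceedance(smp, cd_threshold(smp, gamma))
  spread <- function(x) max(x) - min(x)
  # per-marker joint error of LDT is constant up to quantile discreteness;
  # CD inherits the full location bias
  expect_lt(spread(ldt_ex$per_marker), 1 / 34 * 0.02)
  expect_gt(spread(cd_ex$per_marker), 3 * spread(ldt_ex$per_marker))
})

test_that("threshold_exceedance matches brute-force joint counting", {
  smp <- toy60_sample()
  T <- c(1.05, 10.75, 20.15)
  ex <- threshold_exceedance(smp, T)
  for (i in 1:3)
    expect_equal(ex$per_marker[i],
                 bf_joint_exceedance(smp$delta, smp$lambda, T, i))
  expect_equal(ex$genome_wide, sum(ex$per_marker))
})

test_that("validity_range reports n_m * min p_lambda", {
  smp <- make_sample(runif(1000), rep(1:4, c(500, 250, 125, 125)), 4)
  expect_equal(validity_range(location_distribution(smp)), 0.5)
  uni <- make_sample(runif(400), rep(1:4, 100), 4)
  expect_equal(validity_range(uni), 1.0)
})

test_that("adjust_scan assembles consistent per-marker columns", {
  pop <- sim_cross(example_map_20(), 80, seed = 24)
  smp <- sample_max_lod(pop, 3000, seed = 26)
  scan <- genome_scan(pop)
  tab <- adjust_scan(smp, scan)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$p_cd, cd_adjusted_p(smp, scan$lod))
  expect_equal(tab$p_ldt, pmin(tab$p_ldt_uncapped, 1))
  expect_true(all(tab$p_ldt_max_attainable >= tab$p_ldt - 1e-12))
})
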