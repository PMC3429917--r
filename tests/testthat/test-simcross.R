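test_that("genotype simulation is seed-deterministic and 0/1 coded", {
  map <- example_map_20()
  g1 <- sim_geno(map, 50, seed = 9)
  g2 <- sim_geno(map, 50, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, sim_geno(map, 50, seed = 10)))
  expect_true(all(g1 %in% 0:1))
  expect_equal(colnames(g1), map$marker)
})

test_that("adjacent-marker disagreement matches the interval r (binomial oracle)", {
  n <- 10000
  map <- genetic_map(c("a", "b", "c"), chr = rep(1, 3),
                     r_prev = c(NA, 0.01, 0.5))
  g <- sim_geno(map, n, seed = 21)
  dis01 <- mean(g[, 1] != g[, 2])
  expect_lt(abs(dis01 - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  dis05 <- mean(g[, 2] != g[, 3])
  expect_lt(abs(dis05 - 0.5), 3 * sqrt(0.25 / n))
})

test_that("marker genotype frequencies are balanced and chromosomes independent", {
  n <- 10000
  map <- genetic_map(c("a", "b", "c", "d"), chr = c(1, 1, 2, 2),
                     r_prev = c(NA, 0.02, NA, 0.02))
  g <- sim_geno(map, n, seed = 4)
  for (j in 1:4)
    expect_lt(abs(mean(g[, j]) - 0.5), 3 * sqrt(0.25 / n))
  # across the chromosome boundary: independent assortment
  expect_lt(abs(mean(g[, 2] != g[, 3]) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("null phenotypes are reproducible standard normals", {
  expect_identical(sim_null_pheno(5, 3), sim_null_pheno(5, 3))
  y <- sim_null_pheno(100000, 8)
  expect_lt(abs(mean(y)), 3 / sqrt(100000))
  expect_true(is.finite(sim_null_pheno(1, 2)))
})

test_that("QTL phenotypes put the scan maximum at the QTL for large effects", {
  map <- unlinked_map(5)
  hits <- vapply(1:40, function(s) {
    g <- sim_geno(map, 200, seed = s)
    y <- sim_qtl_pheno(g, qtl_marker = 2, effect = 10, seed = s + 1000)
    scan <- genome_scan(cross_pop(g, y, map))
    scan$lod[2] > scan$lod[5]
  }, logical(1))
  expect_true(all(hits))
  g <- sim_geno(map, 20, seed = 1)
  expect_identical(sim_qtl_pheno(g, 1, 2, seed = 7),
                   sim_qtl_pheno(g, 1, 2, seed = 7))
  expect_error(sim_qtl_pheno(g, 6, 1, seed = 1), "outside")
})

test_that("cross_pop enforces completeness and dimensions", {
  map <- unlinked_map(3)
  g <- sim_geno(map, 10, seed = 1)
  y <- sim_null_pheno(10, 2)
  expect_s3_class(cross_pop(g, y, map), "cross_pop")
  gna <- g; gna[1, 1] <- NA
  expect_error(cross_pop(gna, y, map), "complete")
  expect_error(cross_pop(g, c(y[-1], NA), map), "complete")
  expect_error(cross_pop(g, y[1:5], map), "length")
  expect_error(cross_pop(g[, 1:2], y, map), "map")
  expect_error(cross_pop(g[1:2, ], y[1:2], map), "3 individuals")
  g2 <- g; g2[2, 2] <- 2L
  expect_error(cross_pop(g2, y, map), "0/1")
})

test_that("sim_cross derives its streams from one root seed", {
  map <- unlinked_map(4)
  p1 <- sim_cross(map, 30, seed = 5)
  p2 <- sim_cross(map, 30, seed = 5)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$pheno, p2$pheno)
  pq <- sim_cross(map, 30, seed = 5, qtl_marker = 1, effect = 3)
  expect_identical(pq$geno, p1$geno)  # genotype stream unaffected
})
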