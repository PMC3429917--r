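# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

bf_exceedance <- function(values, t) sum(values > t) / length(values)

# smallest sampled value whose strict exceedance is <= target, by
# scanning every candidate order statistic
bf_threshold <- function(values, target) {
  for (v in sort(unique(values))) {
    if (bf_exceedance(values, v) <= target + 1e-12) return(v)
  }
  stop("unreachable")
}

bf_joint_exceedance <- function(delta, lambda, T, i)
  sum(delta > T[i] & lambda == i) / length(delta)

bf_cd_p <- function(delta, obs) (sum(delta >= obs) + 1) / (length(delta) + 1)

bf_ldt_p <- function(delta, lambda, obs, i, n_m)
  min(1, n_m * (sum(lambda == i & delta >= obs) + 1) / (length(delta) + 1))

# independent LOD route: correlation identity, via stats::cor
bf_lod <- function(g, y) {
  r <- suppressWarnings(stats::cor(g, y))
  if (is.na(r)) return(0)
  -(length(y) / 2) * log10(1 - r^2)
}

# hand-built max-LOD sample object for toy cases
make_sample <- function(delta, lambda, n_m) {
  ldtqtl:::new_maxlod_sample(delta, lambda, n_m)
}

# map of mutually unlinked markers (r = 0.5 everywhere)
unlinked_map <- function(n_m) {
  genetic_map(paste0("u", seq_len(n_m)), chr = rep("1", n_m),
              r_prev = c(NA, rep(0.5, n_m - 1)))
}

# 3-marker toy with 60 (delta, lambda) pairs and p_lambda = (.5, .25, .25):
# distinct delta values so ties never blur the enumeration
toy60_sample <- function() {
  delta1 <- seq(0.1, 3.0, by = 0.1)        # 30 draws at marker 1
  delta2 <- seq(10.1, 11.5, by = 0.1)      # 15 draws at marker 2
  delta3 <- seq(20.1, 21.5, by = 0.1)      # 15 draws at marker 3
  make_sample(c(delta1, delta2, delta3),
              rep(1:3, c(30, 15, 15)), n_m = 3)
}
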