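mu <- standard_band("mu")

test_that("cross-spectral coherence hits its limits and closed form", {
  set.seed(1)
  s <- rnorm(20000)
  ident <- mc_series(rbind(s, s), rate = 100)
  csd <- compute_csd(ident, band_def("b", 10, 30))
  expect_true(all(abs(csd_coherence(csd, 1, 2) - 1) < 1e-9))
  indep <- mc_series(matrix(rnorm(2 * 20000), 2), rate = 100)
  expect_lt(mean(csd_coherence(compute_csd(indep, band_def("b", 10, 30)),
                               1, 2)), 0.1)
  # shared white source with independent unit noise on both channels:
  # coherence = vs^2 / ((vs + v1)(vs + v2)) = 1/4 at every bin
  mix <- mc_series(rbind(s + rnorm(20000), s + rnorm(20000)), rate = 100)
  coh <- csd_coherence(compute_csd(mix, band_def("b", 10, 30)), 1, 2)
  expect_lt(abs(mean(coh) - 0.25), 0.04)
})

test_that("CSD matrices are Hermitian with real non-negative diagonals", {
  set.seed(2)
  x <- mc_series(matrix(rnorm(4 * 3000), 4), rate = 100)
  csd <- compute_csd(x, band_def("b", 8, 20))
  for (k in seq_len(dim(csd$values)[3])) {
    C <- csd$values[, , k]
    expect_lt(max(Mod(C - Conj(t(C)))), 1e-10)
    expect_true(all(Re(diag(C)) >= 0))
    expect_lt(max(abs(Im(diag(C)))), 1e-12)
  }
})

test_that("DICS filters satisfy unit gain and reduce to L' in the whitened case", {
  # identity CSD with orthonormal lead-field columns
  q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  lf <- list(gain = q)
  flt <- dics_filter(lf, diag(6), regularization = 0)
  expect_lt(max(abs(flt$weights - t(q))), 1e-10)
  # unit-gain property across random PSD CSDs and random lead fields
  for (sd in 1:5) {
    set.seed(sd)
    R <- matrix(rnorm(64), 8)
    C <- crossprod(R) + diag(8)
    lf2 <- list(gain = matrix(rnorm(8 * 4), 8))
    flt2 <- dics_filter(lf2, C, regularization = 0.05)
    gains <- vapply(1:4, function(s)
      sum(flt2$weights[s, ] * lf2$gain[, s]), numeric(1))
    expect_lt(max(abs(gains - 1)), 1e-8)
  }
})

test_that("power maps localize a single simulated source and decay with distance", {
  grid <- as.matrix(expand.grid(x = c(-40, 0, 40), y = c(-60, 0, 60),
                                z = c(0, 40)))
  lf <- make_leadfield(grid, n_sensors = 32)
  truth <- 8
  osc <- simulate_mvar(mvar_spec(array(c(2 * 0.95 * cos(2 * pi * 10 / 250),
                                         -0.9025), c(2, 1, 1))),
                       2000, rate = 250, seed = 5)
  full <- matrix(0, nrow(grid), 2000)
  full[truth, ] <- osc$data
  sens <- project_to_sensors(mc_series(full, 250), lf,
                             sensor_noise_sd = 0.05, seed = 6)
  csd <- compute_csd(sens, mu)
  flt <- dics_filter(lf, csd)
  pw <- source_power_map(flt, csd)
  expect_equal(which.max(pw), truth)
  d <- sqrt(rowSums((grid - matrix(grid[truth, ], nrow(grid), 3,
                                   byrow = TRUE))^2))
  expect_lt(cor(rank(d[-truth]), rank(pw[-truth])), 0)   # decay with distance
  expect_true(all(source_power_map(flt, matrix(0, 32, 32)) == 0))
})

test_that("two uncorrelated sources appear as two local power maxima", {
  grid <- as.matrix(expand.grid(x = c(-50, 50), y = c(-70, 0, 70), z = 10))
  lf <- make_leadfield(grid, n_sensors = 32)
  t1 <- 1; t2 <- 6
  o1 <- simulate_mvar(mvar_spec(array(c(2 * 0.9 * cos(2 * pi * 9 / 250),
                                        -0.81), c(2, 1, 1))),
                      3000, rate = 250, seed = 7)
  o2 <- simulate_mvar(mvar_spec(array(c(2 * 0.9 * cos(2 * pi * 11 / 250),
                                        -0.81), c(2, 1, 1))),
                      3000, rate = 250, seed = 8)
  full <- matrix(0, nrow(grid), 3000)
  full[t1, ] <- o1$data; full[t2, ] <- o2$data
  sens <- project_to_sensors(mc_series(full, 250), lf, 0.05, seed = 9)
  csd <- compute_csd(sens, mu)
  pw <- source_power_map(dics_filter(lf, csd), csd)
  expect_setequal(order(pw, decreasing = TRUE)[1:2], c(t1, t2))
})

test_that("coherence maps are bounded, maximal at the reference, small when independent", {
  grid <- rbind(c(-40, -60, 10), c(40, 60, 10))
  lf <- make_leadfield(grid, n_sensors = 16)
  o1 <- simulate_mvar(mvar_spec(array(c(2 * 0.9 * cos(2 * pi * 10 / 250),
                                        -0.81), c(2, 1, 1))),
                      5000, rate = 250, seed = 10)
  o2 <- simulate_mvar(mvar_spec(array(c(2 * 0.9 * cos(2 * pi * 10 / 250),
                                        -0.81), c(2, 1, 1))),
                      5000, rate = 250, seed = 11)
  sens <- project_to_sensors(mc_series(rbind(o1$data, o2$data), 250), lf,
                             0.2, seed = 12)
  csd <- compute_csd(sens, mu)
  flt <- dics_filter(lf, csd)
  coh <- source_coherence_map(flt, csd, reference = list(source = 1))
  expect_true(all(coh >= 0 & coh <= 1))
  expect_gt(coh[1], 0.99)                        # the reference itself
  expect_lt(coh[2], 0.35)                        # independent oscillator
})

test_that("source extraction is the linear projection it claims to be", {
  flt <- list(weights = diag(3))
  class(flt) <- "dics_filters"
  x <- mc_series(matrix(rnorm(3 * 100), 3), rate = 100)
  expect_equal(extract_source_series(flt, x)$data, x$data)
  zero <- mc_series(matrix(0, 3, 50), rate = 100)
  expect_true(all(extract_source_series(flt, zero)$data == 0))
  # noiseless single-source forward model: estimate ~ truth
  lf <- make_leadfield(rbind(c(0, -60, 10), c(0, 60, 10)), n_sensors = 12)
  src <- simulate_mvar(bivar_spec(0.5, 0), 2000, rate = 250, seed = 13)
  sens <- project_to_sensors(src, lf, 0)
  flt2 <- dics_filter(lf, compute_csd(sens, mu))
  est <- extract_source_series(flt2, sens)
  expect_gt(abs(cor(est$data[1, ], src$data[1, ])), 0.99)
})

test_that("pooled source signals use band-power-proportional weights", {
  set.seed(14)
  v1 <- sin(2 * pi * 10 * seq_len(1000) / 250) * sqrt(6)   # band power 3
  v2 <- sin(2 * pi * 10 * seq_len(1000) / 250) * sqrt(2)   # band power 1
  vox <- mc_series(rbind(v1, v2), rate = 250)
  pooled <- pool_source_signal(vox, mu)
  expect_equal(sum(pooled$weights), 1)
  expect_lt(max(abs(pooled$weights - c(0.75, 0.25))), 0.02)
  single <- pool_source_signal(mc_series(matrix(v1, 1), 250), mu)
  expect_equal(single$weights, 1)
  expect_equal(single$series$data[1, ], v1)
  eq <- pool_source_signal(mc_series(rbind(v1, v1), 250), mu)
  expect_equal(unname(eq$weights), c(0.5, 0.5))
  expect_error(pool_source_signal(mc_series(matrix(0, 2, 500), 250), mu),
               "zero band power")
})

test_that("segment permutation p-values obey the add-one bounds", {
  rate <- 100
  ramp <- mc_series(matrix(seq_len(10 * rate), 1), rate = rate)
  align <- function(s) sum(s$data[1, ] * seq_len(n_samples(s)))
  # identity ordering maximizes the alignment statistic (rearrangement):
  # observed above all 100 permutations -> p = 1/101
  res <- source_significance(align, ramp, n_perm = 100, seed = 1)
  expect_equal(res$p_value, 1 / 101)
  expect_true(res$significant)
  # negated statistic: observed below every permutation -> p = 1
  res2 <- source_significance(function(s) -align(s), ramp, n_perm = 100,
                              seed = 2)
  expect_equal(res2$p_value, 1)
  expect_error(source_significance(align, ramp, n_perm = 0), "positive")
})

test_that("permutation p-values are uniform under a stationary null", {
  rate <- 100
  stat <- function(s) band_power(s, mu)[1]
  ps <- vapply(1:200, function(r) {
    set.seed(r)
    x <- mc_series(matrix(rnorm(4 * rate), 1), rate = rate)
    source_significance(stat, x, n_perm = 100,
                        seed = 10000 + r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
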