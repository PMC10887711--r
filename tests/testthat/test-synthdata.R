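mu <- standard_band("mu")

test_that("dense profile realizes the requested edge count with a long-range edge", {
  prof <- group_network_profile("dense_longrange", n_nodes = 5, n_edges = 10)
  net <- make_group_network(prof, mu, rate = 250, seed = 1)
  expect_equal(nrow(net$truth), 10)
  expect_gte(max(net$truth$length_mm), 80)
  expect_true(mvar_stable(net))
})

test_that("sparse profile keeps every edge under the length cap", {
  prof <- group_network_profile("sparse_local", n_nodes = 5, n_edges = 4)
  net <- make_group_network(prof, mu, rate = 250, seed = 2)
  expect_equal(nrow(net$truth), 4)
  expect_true(all(net$truth$length_mm <= prof$length_cap))
})

test_that("ground-truth edges and nonzero cross-coefficients coincide exactly", {
  for (sd in 1:5) {
    prof <- group_network_profile("dense_longrange", n_nodes = 5,
                                  n_edges = 7)
    net <- make_group_network(prof, mu, rate = 250, seed = sd)
    nz <- which(net$coeffs[1, , ] != 0 & row(diag(5)) != col(diag(5)),
                arr.ind = TRUE)
    expect_setequal(paste(nz[, 2], nz[, 1]),
                    paste(net$truth$src, net$truth$dst))
  }
})

test_that("an empty network is diagonal-only with zero off-diagonal PDC", {
  prof <- group_network_profile("dense_longrange", n_nodes = 4, n_edges = 0)
  net <- make_group_network(prof, mu, rate = 250, seed = 3)
  expect_equal(nrow(net$truth), 0)
  pdc <- pdc_spectrum(net$coeffs, band_freqs(mu), 250)
  off <- array(rep(row(diag(4)) != col(diag(4)), length(band_freqs(mu))),
               dim(pdc))
  expect_true(all(pdc[off] == 0))
})

test_that("infeasible edge requests fail naming the constraint", {
  prof <- group_network_profile("sparse_local", n_nodes = 3, n_edges = 6,
                                length_cap = 10)
  expect_error(make_group_network(prof, mu, seed = 1), "length cap")
})

test_that("node spectral peaks fall inside the requested band", {
  rate <- 250
  f_grid <- seq(0.5, 60, by = 0.05)
  ar2_spectrum <- function(a1, a2) {
    w <- 2 * pi * f_grid / rate
    1 / Mod(1 - a1 * exp(-1i * w) - a2 * exp(-2i * w))^2
  }
  for (bn in c("mu", "beta")) {
    band <- standard_band(bn)
    prof <- group_network_profile("dense_longrange", n_nodes = 4,
                                  n_edges = 0)
    net <- make_group_network(prof, band, rate = rate, seed = 4)
    # exact check on each oscillator's theoretical spectrum
    for (ch in 1:4) {
      peak <- f_grid[which.max(ar2_spectrum(net$coeffs[1, ch, ch],
                                            net$coeffs[2, ch, ch]))]
      expect_gte(peak, band$f_lo)
      expect_lte(peak, band$f_hi)
    }
    # empirical check: Welch argmax, tolerance set by the estimator
    # variance at this resonance width (pole radius 0.8 is broad)
    x <- simulate_mvar(net, 20000, rate = rate, seed = 5)
    psd <- welch_psd(x$data, rate, seg_len = 2)
    for (ch in 1:4) {
      peak <- psd$freqs[which.max(psd$psd[ch, ])]
      expect_gte(peak, band$f_lo - 3)
      expect_lte(peak, band$f_hi + 3)
    }
  }
})

test_that("noise-free projection is exactly linear in the gain", {
  lf <- make_leadfield(matrix(c(0, -50, 20), 1), n_sensors = 16)
  src <- mc_series(matrix(sin(1:200 / 5), 1), rate = 100)
  sens <- project_to_sensors(src, lf, sensor_noise_sd = 0)
  expect_equal(sens$data, lf$gain %*% src$data)
  expect_equal(n_channels(sens), 16)
})

test_that("sensor covariance equals L Cov(sources) L' for orthogonal sources", {
  coords <- rbind(c(0, -60, 10), c(0, 40, 10))
  lf <- make_leadfield(coords, n_sensors = 8)
  set.seed(6)
  s <- matrix(rnorm(2 * 5000), 2)
  sens <- project_to_sensors(mc_series(s, 100), lf, 0)
  emp <- tcrossprod(sens$data) / 5000
  expect_lt(max(abs(emp - lf$gain %*% (tcrossprod(s) / 5000) %*%
                      t(lf$gain))), 1e-10)
  expect_error(project_to_sensors(mc_series(matrix(0.0, 3, 10) + rnorm(30),
                                            100), lf),
               "expects 2 sources")
})

test_that("noise-dominated projection destroys sensor-source coherence", {
  lf <- make_leadfield(matrix(c(0, -60, 10), 1), n_sensors = 4)
  osc <- simulate_mvar(mvar_spec(array(c(2 * 0.9 * cos(2 * pi * 10 / 100),
                                         -0.81), c(2, 1, 1))),
                       4000, rate = 100, seed = 7)
  sens <- project_to_sensors(osc, lf, sensor_noise_sd = 200, seed = 8)
  both <- mc_series(rbind(osc$data, sens$data[1, ]), 100)
  csd <- compute_csd(both, mu)
  expect_lt(mean(csd_coherence(csd, 1, 2)), 0.1)
})

test_that("behavioural simulation matches the signal-detection model", {
  s <- simulate_behavior(10000, dprime_true = 0, criterion = 0, seed = 1)
  expect_lt(abs(s$hits / s$n_signal_trials - 0.5), 3 * 0.005)
  expect_lt(abs(s$false_alarms / s$n_noise_trials - 0.5), 3 * 0.005)
  s2 <- simulate_behavior(10000, dprime_true = 2, criterion = 1, seed = 2)
  expect_lt(abs(dprime(s2) - 2), 0.1)
  s3 <- simulate_behavior(1, dprime_true = 1, seed = 3)
  expect_true(s3$hits %in% 0:1 && s3$false_alarms %in% 0:1)
})

test_that("scramble transform preserves dot count, cycle length and path shape", {
  w <- make_walker(n_dots = 15, cycle_length = 120, n_cycles = 2)
  s <- scramble_transform(w, seed = 1)
  expect_equal(s$n_dots, 15)
  expect_equal(s$cycle_length, 120)
  expect_equal(dim(s$positions), dim(w$positions))
  expect_true(all(is.finite(s$positions)))
})

test_that("a constant-speed trajectory is a fixed point of the scramble", {
  # single dot on a circle at uniform speed: permutation is the identity
  L <- 100
  th <- 2 * pi * seq_len(2 * L) / L
  pos <- array(0, c(1, 2 * L, 2))
  pos[1, , 1] <- cos(th); pos[1, , 2] <- sin(th)
  w <- structure(list(positions = pos, cycle_length = L, n_dots = 1),
                 class = "dot_trajectories")
  s <- scramble_transform(w, seed = 1)
  expect_lt(max(abs(s$positions - pos)), 1e-6)
})

test_that("variable-speed trajectories are re-timed to their cycle-mean speed", {
  # dot on a circle with sinusoidally varying angular speed
  L <- 200
  u <- seq_len(L) / L
  th <- 2 * pi * (u + 0.15 * sin(2 * pi * u))       # one full warped cycle
  pos <- array(0, c(1, L, 2))
  pos[1, , 1] <- cos(th); pos[1, , 2] <- sin(th)
  w <- structure(list(positions = pos, cycle_length = L, n_dots = 1),
                 class = "dot_trajectories")
  s <- scramble_transform(w, seed = 1)
  sp <- sqrt(rowSums(diff(cbind(s$positions[1, , 1],
                                s$positions[1, , 2]))^2))
  # numeric arc-length oracle: constant speed = path length / samples
  target <- sum(sqrt(rowSums(diff(cbind(cos(th), sin(th)))^2))) / L
  expect_lt(max(abs(sp - target)) / target, 0.05)
  expect_gt(max(abs(sqrt(rowSums(diff(cbind(cos(th), sin(th)))^2)) -
                      target)) / target, 0.5)   # input speed truly varied
})

test_that("a stationary dot makes the scramble fail loudly", {
  pos <- array(1, c(1, 100, 2))
  w <- structure(list(positions = pos, cycle_length = 100, n_dots = 1),
                 class = "dot_trajectories")
  expect_error(scramble_transform(w, seed = 1), "zero-length")
})
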