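mu <- standard_band("mu")

test_that("PDC matches the hand-evaluated closed form and the defining formula", {
  a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(0.5, 2); a[1, 2, 1] <- 0.5
  # independent numeric oracle: evaluate Abar and the normalization directly
  Abar <- diag(2) - matrix(a[1, , ], 2, 2) * exp(-2i * pi * 0 * 1 / 1)
  oracle <- Mod(Abar[2, 1]) / sqrt(sum(Mod(Abar[, 1])^2))
  expect_equal(oracle, 0.5 / sqrt(0.5))
  expect_equal(pdc_spectrum(a, freqs = 0, rate = 1)[2, 1, 1], oracle)
  # a frequency-dependent probe against the same oracle
  f <- 0.2
  Abar_f <- diag(2) - matrix(a[1, , ], 2, 2) * exp(-2i * pi * f)
  expect_equal(pdc_spectrum(a, f, 1)[2, 1, 1],
               Mod(Abar_f[2, 1]) / sqrt(sum(Mod(Abar_f[, 1])^2)))
})

test_that("PDC columns are normalized and diagonal models decouple", {
  d <- array(0, c(2, 3, 3))
  d[1, , ] <- diag(0.4, 3); d[2, , ] <- diag(-0.3, 3)
  pdc <- pdc_spectrum(d, c(2, 10, 40), 100)
  for (k in 1:3) {
    expect_true(all(abs(diag(pdc[, , k]) - 1) < 1e-12))
    expect_true(all(pdc[, , k][row(diag(3)) != col(diag(3))] == 0))
  }
  for (sd in 1:8) {
    a <- random_stable_coeffs(m = 3, p = 2, seed = sd)
    pdc <- pdc_spectrum(a, seq(1, 40, by = 7), 100)
    cn <- apply(pdc^2, c(2, 3), sum)
    expect_lt(max(abs(cn - 1)), 1e-6)
  }
})

test_that("DEKF recovers stationary coefficients and the white-noise null", {
  x <- simulate_mvar(bivar_spec(0.5, 0.4), 8000, rate = 250, seed = 1)
  fit <- dekf_fit(x, order = 1)
  est <- apply(fit$coeff_trajectory, c(2, 3, 4), mean)
  truth <- bivar_spec(0.5, 0.4)$coeffs
  expect_lt(max(abs(est - truth)), 0.05)
  # least-squares reference agrees
  ls <- mvar_fit_ls(x, 1)
  expect_lt(max(abs(est - ls$coeffs)), 0.05)
  wn <- simulate_mvar(mvar_spec(array(0, c(1, 2, 2))), 6000, rate = 250,
                      seed = 2)
  fit0 <- dekf_fit(wn, order = 1)
  expect_lt(max(abs(apply(fit0$coeff_trajectory, c(2, 3, 4), mean))), 0.05)
})

test_that("DEKF tracks a coefficient step within 500 samples", {
  T <- 4000
  coef <- array(0, c(T, 1, 2, 2))
  coef[, 1, 1, 1] <- 0.5; coef[, 1, 2, 2] <- 0.5
  coef[(T / 2):T, 1, 2, 1] <- 0.5
  x <- simulate_mvar(mvar_spec(coef), T, rate = 250, seed = 3)
  fit <- dekf_fit(x, order = 1)
  tr <- fit$coeff_trajectory[, 1, 2, 1]
  samp <- seq_along(tr) + 1 + fit$warmup
  crossing <- samp[which(samp > T / 2 & tr > 0.25)[1]]
  expect_lt(crossing - T / 2, 500)
})

test_that("DEKF rejects non-finite input and guards against divergence", {
  bad <- mc_series(matrix(rnorm(2 * 1000), 2), rate = 250)
  bad$data[1, 5] <- Inf
  expect_error(dekf_fit(bad, order = 1), "non-finite")
  short <- mc_series(matrix(rnorm(2 * 15), 2), rate = 250)
  expect_error(dekf_fit(short, order = 1), "samples")
})

test_that("tPDC tensors keep normalization, stationarity and step contrast", {
  x <- simulate_mvar(bivar_spec(0.5, 0.4), 6000, rate = 250, seed = 4)
  fit <- dekf_fit(x, order = 1)
  tens <- tpdc_compute(fit, band_freqs(mu))
  cn <- apply(tens$values^2, c(2, 3, 4), sum)
  expect_lt(max(abs(cn - 1)), 1e-6)
  expect_true(all(tens$values >= 0 & tens$values <= 1))
  # stationary input: low temporal variation of the coupled edge
  tr21 <- apply(tens$values[2, 1, , ], 2, mean)
  expect_lt(sd(tr21) / mean(tr21), 0.2)
  # step input: band-mean strength differs between halves
  T <- 6000
  coef <- array(0, c(T, 1, 2, 2))
  coef[, 1, 1, 1] <- 0.5; coef[, 1, 2, 2] <- 0.5
  coef[(T / 2):T, 1, 2, 1] <- 0.5
  xs <- simulate_mvar(mvar_spec(coef), T, rate = 250, seed = 5)
  fs <- dekf_fit(xs, order = 1)
  ts <- tpdc_compute(fs, band_freqs(mu))
  half <- length(ts$times) %/% 2
  m1 <- mean(ts$values[2, 1, , seq_len(half - 30)])
  m2 <- mean(ts$values[2, 1, , seq.int(half + 30, length(ts$times))])
  expect_gt(m2 - m1, 0.1)
  # memory guard
  expect_error(tpdc_compute(fit, seq(8, 12, by = 0.01), decimate = 1,
                            max_cells = 1e5), "decimate")
})

test_that("diagonal models give near-zero off-diagonal tPDC throughout", {
  d <- array(0, c(1, 3, 3)); d[1, , ] <- diag(0.5, 3)
  x <- simulate_mvar(mvar_spec(d), 6000, rate = 250, seed = 6)
  s <- tpdcnet:::tpdc_strengths_of(x, 1, band_freqs(mu))
  expect_lt(max(s[row(s) != col(s)]), 0.2)
})

test_that("DEKF and sliding-window least squares agree on band-mean tPDC", {
  prof <- group_network_profile("dense_longrange", n_nodes = 4, n_edges = 6)
  net <- make_group_network(prof, mu, rate = 250, seed = 7)
  x <- simulate_mvar(net, 7500, rate = 250, seed = 8)
  freqs <- band_freqs(mu)
  s_dekf <- tpdcnet:::tpdc_strengths_of(x, 2, freqs)
  # oracle: sliding-window least-squares MVAR, PDC per window, averaged
  win <- 750
  acc <- matrix(0, 4, 4); nwin <- 0
  for (st in seq(1, 7500 - win + 1, by = win)) {
    f <- mvar_fit_ls(x$data[, st:(st + win - 1)], 2)
    acc <- acc + apply(pdc_spectrum(f$coeffs, freqs, 250), c(1, 2), mean)
    nwin <- nwin + 1
  }
  s_ls <- acc / nwin; diag(s_ls) <- 0
  off <- row(s_ls) != col(s_ls)
  expect_gt(cor(s_dekf[off], s_ls[off]), 0.9)
})
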