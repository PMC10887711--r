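# Shared fixtures: small model builders used across the suite.

# Bivariate AR(1) with a single directed cross term src 1 -> 2.
bivar_spec <- function(diag_coef = 0.5, a21 = 0.4) {
  a <- array(0, c(1, 2, 2))
  a[1, , ] <- diag(diag_coef, 2)
  a[1, 2, 1] <- a21
  mvar_spec(a)
}

# Three-node MVAR(2) with two directed edges (1 -> 2, 2 -> 3).
trivar_spec <- function() {
  a <- array(0, c(2, 3, 3))
  a[1, , ] <- diag(0.5, 3)
  a[1, 2, 1] <- 0.3
  a[1, 3, 2] <- 0.25
  a[2, , ] <- diag(-0.2, 3)
  mvar_spec(a)
}

# Random stable coefficient array: shrink a random draw under the unit
# spectral radius.
random_stable_coeffs <- function(m, p, seed) {
  set.seed(seed)
  repeat {
    a <- array(rnorm(p * m * m, sd = 0.3), c(p, m, m))
    rho <- attr(mvar_stable(mvar_spec(a)), "spectral_radius")
    if (rho < 0.95) return(a)
  }
}

# Two-channel zero-lag mixture of one oscillatory latent source plus
# independent sensor noise: the volume-conduction analogue.
mixing_series <- function(n, seed, rate = 250) {
  osc <- array(c(2 * 0.8 * cos(2 * pi * 10 / rate), -0.64), c(2, 1, 1))
  lat <- simulate_mvar(mvar_spec(osc), n, rate = rate, seed = seed)$data[1, ]
  set.seed(seed + 5000)
  mc_series(rbind(lat + 0.3 * rnorm(n), 0.8 * lat + 0.3 * rnorm(n)), rate)
}
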