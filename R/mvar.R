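## Multivariate autoregressive (MVAR) models: specification, stability,
## and simulation. These are both the ground truth of the synthetic-data
## generator and the estimand of the dual Kalman filter.

#' MVAR model specification
#'
#' A (possibly time-varying) multivariate autoregressive model
#' \eqn{y_t = \sum_{r=1}^{p} A_r y_{t-r} + e_t}, \eqn{e_t \sim N(0, \Sigma)}.
#'
#' @param coeffs coefficient array. Static model: `(p, m, m)` array where
#'   `coeffs[r, i, j]` is the influence of channel `j` at lag `r` on channel
#'   `i`. Time-varying model: `(T, p, m, m)` array of per-sample
#'   coefficients.
#' @param innovation_cov `m x m` symmetric positive-semidefinite innovation
#'   covariance (default identity).
#' @param labels optional `m` node names.
#' @param coords optional `m x 3` matrix of node coordinates in mm.
#' @return an `mvar_spec` list with `order`, `m`, `coeffs`,
#'   `innovation_cov`, `labels`, `coords`, `time_varying`.
#' @export
#' @examples
#' a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(0.5, 2); a[1, 2, 1] <- 0.4
#' spec <- mvar_spec(a)
#' mvar_stable(spec)
mvar_spec <- function(coeffs, innovation_cov = NULL, labels = NULL,
                     coords = NULL) {
  nd <- length(dim(coeffs))
  stop_if_not(nd %in% c(3L, 4L),
              "`coeffs` must be a (p, m, m) or (T, p, m, m) array")
  time_varying <- nd == 4L
  d <- dim(coeffs)
  m <- d[nd]
  stop_if_not(d[nd - 1L] == m, "coefficient array must be square in nodes")
  p <- if (time_varying) d[2] else d[1]
  if (is.null(innovation_cov)) innovation_cov <- diag(m)
  innovation_cov <- as.matrix(innovation_cov)
  stop_if_not(all(dim(innovation_cov) == c(m, m)),
              "`innovation_cov` must be m x m")
  stop_if_not(isSymmetric(innovation_cov, tol = 1e-8),
              "`innovation_cov` must be symmetric")
  ev <- eigen(innovation_cov, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > -1e-10,
              "`innovation_cov` must be positive semi-definite")
  if (is.null(labels)) labels <- paste0("node", seq_len(m))
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stop_if_not(all(dim(coords) == c(m, 3)), "`coords` must be m x 3 (mm)")
  }
  structure(list(order = p, m = m, coeffs = coeffs,
                 innovation_cov = innovation_cov,
                 labels = as.character(labels), coords = coords,
                 time_varying = time_varying),
            class = "mvar_spec")
}

# Companion-form matrix (mp x mp) of a static coefficient array (p, m, m).
companion_matrix <- function(coeffs) {
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  Fm <- matrix(0, m * p, m * p)
  for (r in seq_len(p))
    Fm[seq_len(m), (r - 1L) * m + seq_len(m)] <- coeffs[r, , ]
  if (p > 1)
    Fm[m + seq_len(m * (p - 1L)), seq_len(m * (p - 1L))] <-
      diag(m * (p - 1L))
  Fm
}

#' Stability of a static MVAR specification
#'
#' A static model is stable iff all eigenvalues of its companion matrix lie
#' strictly inside the unit circle.
#'
#' @param spec an [mvar_spec()] (static).
#' @return `TRUE`/`FALSE`, with attribute `spectral_radius`.
#' @export
mvar_stable <- function(spec) {
  stop_if_not(inherits(spec, "mvar_spec"), "`spec` must be an mvar_spec")
  stop_if_not(!spec$time_varying, "stability check applies to static specs")
  rho <- max(Mod(eigen(companion_matrix(spec$coeffs),
                       only.values = TRUE)$values))
  structure(rho < 1, spectral_radius = rho)
}

# Stationary covariance of a stable static MVAR: solves the discrete
# Lyapunov equation P = F P F' + Q in companion form.
mvar_stationary_cov <- function(coeffs, innovation_cov) {
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  Fm <- companion_matrix(coeffs)
  Q <- matrix(0, m * p, m * p)
  Q[seq_len(m), seq_len(m)] <- innovation_cov
  n <- m * p
  P <- solve(diag(n * n) - kronecker(Fm, Fm), as.numeric(Q))
  matrix(P, n, n)[seq_len(m), seq_len(m), drop = FALSE]
}

# Draw n iid N(0, Sigma) vectors (columns) via the symmetric square root.
rmvnorm_cols <- function(n, sigma) {
  m <- nrow(sigma)
  es <- eigen(sigma, symmetric = TRUE)
  rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  rt %*% matrix(rnorm(m * n), m, n)
}

#' Simulate an MVAR process
#'
#' Drives the model with Gaussian innovations and discards a burn-in of
#' `10 * p` samples so the returned series is (for stable static models)
#' approximately stationary.
#'
#' @param spec a stable [mvar_spec()] (static, or time-varying with
#'   trajectory length `n_samples`).
#' @param n_samples number of samples to return (must exceed the order).
#' @param rate sampling rate attached to the output (Hz, default 500).
#' @param seed integer seed for reproducibility (optional).
#' @param burn_in samples discarded at the start (default `10 * p`; the
#'   burn-in uses the first coefficient slice for time-varying specs).
#' @return an [mc_series()] with `m` channels and `n_samples` samples.
#' @export
#' @examples
#' a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(0.5, 2)
#' x <- simulate_mvar(mvar_spec(a), 500, seed = 1)
simulate_mvar <- function(spec, n_samples, rate = 500, seed = NULL,
                          burn_in = NULL) {
  stop_if_not(inherits(spec, "mvar_spec"), "`spec` must be an mvar_spec")
  p <- spec$order; m <- spec$m
  stop_if_not(is_count(n_samples) && n_samples > p,
              "`n_samples` must exceed the model order")
  if (!spec$time_varying) {
    st <- mvar_stable(spec)
    if (!st)
      stop(sprintf(
        "unstable MVAR spec: companion spectral radius %.4f >= 1",
        attr(st, "spectral_radius")), call. = FALSE)
  } else {
    stop_if_not(dim(spec$coeffs)[1] == n_samples,
                "time-varying trajectory length must equal `n_samples`")
  }
  if (is.null(burn_in)) burn_in <- 10L * p
  n_tot <- n_samples + burn_in
  coef_at <- function(t_out) {
    if (!spec$time_varying) return(spec$coeffs)
    array(spec$coeffs[max(1L, t_out - burn_in), , , , drop = FALSE],
          dim(spec$coeffs)[-1])
  }
  y <- with_seed(seed, {
    e <- rmvnorm_cols(n_tot, spec$innovation_cov)
    out <- matrix(0, m, n_tot)
    out[, seq_len(p)] <- e[, seq_len(p), drop = FALSE]
    for (t in (p + 1L):n_tot) {
      A <- coef_at(t)
      if (p == 1L) A <- array(A, c(1, m, m))
      acc <- e[, t]
      for (r in seq_len(p))
        acc <- acc + matrix(A[r, , ], m, m) %*% out[, t - r]
      out[, t] <- acc
    }
    out
  })
  mc_series(y[, burn_in + seq_len(n_samples), drop = FALSE], rate = rate,
            labels = spec$labels)
}
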