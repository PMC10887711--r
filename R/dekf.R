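## DEKF wrapper and the ordinary least-squares MVAR fit used for the warm
## start (and, in tests, as an independent stationary-fit reference).

#' Least-squares MVAR fit
#'
#' Ordinary multivariate least squares of `y_t` on its `p` lags; the
#' stationary counterpart of the time-varying Kalman estimate, used to warm
#' start the DEKF.
#'
#' @param series an [mc_series()] or channels x samples matrix.
#' @param order model order `p`.
#' @return list with `coeffs` (`(p, m, m)` array), `innovation_cov`
#'   (residual covariance), `residuals`.
#' @export
mvar_fit_ls <- function(series, order) {
  y <- if (inherits(series, "mc_series")) series$data else as.matrix(series)
  m <- nrow(y); T <- ncol(y); p <- order
  stop_if_not(is_count(p) && T > p * m + p,
              "series too short for the requested order")
  Y <- t(y[, (p + 1):T, drop = FALSE])                 # (T-p) x m
  X <- do.call(cbind, lapply(seq_len(p), function(r)
    t(y[, (p + 1 - r):(T - r), drop = FALSE])))        # (T-p) x (m p)
  B <- qr.solve(X, Y)                                  # (m p) x m
  coeffs <- array(0, c(p, m, m))
  for (r in seq_len(p))
    coeffs[r, , ] <- t(B[(r - 1L) * m + seq_len(m), , drop = FALSE])
  res <- Y - X %*% B
  list(coeffs = coeffs, innovation_cov = crossprod(res) / (nrow(res) - 1),
       residuals = res)
}

#' Dual-EKF estimation of time-varying MVAR coefficients
#'
#' Two Kalman filters run in parallel: one estimates the (lagged-signal)
#' states given the current coefficients, and feeds them to the second,
#' which estimates the coefficients under a random-walk parameter model and
#' passes them back. The result is a per-sample coefficient trajectory; on
#' stationary stable inputs its time average estimates the true
#' coefficients.
#'
#' @param series an [mc_series()] with at least `10 * p * m` samples.
#' @param order MVAR model order `p` (default 5).
#' @param q_param random-walk (process-noise) variance of the parameter
#'   filter (default 1e-4).
#' @param r_obs observation-noise scale of the state filter, multiplying the
#'   mean least-squares residual variance (default 0.1).
#' @param init `"ls"` (least-squares warm start, default) or `"zero"`.
#' @param init_window seconds of data used for the warm start and the
#'   noise-covariance estimates; `NULL` (default) uses the whole series.
#'   A full-series estimate matters for the surrogate refits: a noise
#'   variance taken from a short leading window underestimates the
#'   innovation scale of channels whose predictability the surrogate
#'   destroyed, which makes the parameter filter over-confident and
#'   inflates spurious cross-coefficients.
#' @param warmup samples dropped from the front of the trajectory (default
#'   `max(10 * p, 100)`).
#' @param diverge_bound error out when the coefficient-vector norm exceeds
#'   this bound (default 1e3).
#' @return a `tv_mvar` object: `coeff_trajectory` (`(T_kept, p, m, m)`),
#'   `order`, `m`, `rate`, `innovation_cov` (warm-start residual
#'   covariance), `warmup`, `times`, `pred_error`.
#' @export
#' @examples
#' a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(0.5, 2); a[1, 2, 1] <- 0.4
#' x <- simulate_mvar(mvar_spec(a), 2000, rate = 100, seed = 1)
#' fit <- dekf_fit(x, order = 1)
#' apply(fit$coeff_trajectory, c(2, 3, 4), mean)
dekf_fit <- function(series, order = 5, q_param = 1e-4, r_obs = 0.1,
                     init = c("ls", "zero"), init_window = NULL,
                     warmup = NULL, diverge_bound = 1e3) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  init <- match.arg(init)
  y <- series$data
  stop_if_not(all(is.finite(y)), "series contains non-finite values")
  m <- nrow(y); T <- ncol(y); p <- order
  stop_if_not(is_count(p), "`order` must be a positive integer")
  stop_if_not(T >= 10 * p * m,
              sprintf("need at least 10*p*m = %d samples, got %d",
                      10 * p * m, T))
  if (is.null(warmup)) warmup <- max(10L * p, 100L)

  n_init <- if (is.null(init_window)) T else
    min(T, max(round(init_window * series$rate), p * m + 2 * p + 10))
  ls <- mvar_fit_ls(y[, seq_len(n_init), drop = FALSE], p)
  # vec([A1..Ap]) column-major: entry ((r-1)m + j)*m + i  ->  A_r[i, j]
  a0 <- numeric(m * m * p)
  if (init == "ls")
    for (r in seq_len(p))
      a0[(r - 1L) * m * m + seq_len(m * m)] <- as.numeric(ls$coeffs[r, , ])
  R_param <- diag(pmax(diag(ls$innovation_cov), 1e-8), m)
  Q_state_top <- ls$innovation_cov +
    diag(1e-8, m)                      # keep PD for degenerate inputs
  res <- dekf_core(y, p, a0, R_param, q_param, Q_state_top,
                   r_obs * mean(diag(R_param)), 0.1, 0.1, diverge_bound)
  if (isTRUE(res$diverged))
    stop(paste0("DEKF diverged (coefficient norm exceeded the bound); ",
                "reduce `q_param` or check the input scale"), call. = FALSE)
  a_traj <- res$a_traj                               # na x (T - p)
  keep <- seq.int(warmup + 1L, ncol(a_traj))
  stop_if_not(length(keep) > 0, "series shorter than the DEKF warm-up")
  Tk <- length(keep)
  coeff <- array(0, c(Tk, p, m, m))
  for (r in seq_len(p)) {
    block <- a_traj[(r - 1L) * m * m + seq_len(m * m), keep, drop = FALSE]
    coeff[, r, , ] <- aperm(array(block, c(m, m, Tk)), c(3, 1, 2))
  }
  structure(list(coeff_trajectory = coeff, order = p, m = m,
                 rate = series$rate,
                 innovation_cov = ls$innovation_cov, warmup = warmup,
                 times = series$t0 + (p + keep - 1L) / series$rate,
                 pred_error = res$pred_error[keep],
                 labels = series$labels),
            class = "tv_mvar")
}

#' @export
print.tv_mvar <- function(x, ...) {
  cat(sprintf("<tv_mvar> order %d, %d nodes, %d time steps @ %g Hz\n",
              x$order, x$m, dim(x$coeff_trajectory)[1], x$rate))
  invisible(x)
}
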