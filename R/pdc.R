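## Partial directed coherence from MVAR coefficients, time-resolved over a
## DEKF coefficient trajectory.

#' Partial directed coherence spectrum of one coefficient set
#'
#' For coefficients \eqn{A_1..A_p} the frequency response is
#' \eqn{\bar{A}(f) = I - \sum_r A_r e^{-i 2 \pi f r / rate}} and
#' \eqn{\pi_{ij}(f) = |\bar{A}_{ij}(f)| / \sqrt{\sum_k |\bar{A}_{kj}(f)|^2}}.
#' The off-diagonal entry \eqn{\pi_{ij}} measures the directed influence of
#' node `j` on node `i`; each column satisfies
#' \eqn{\sum_i \pi_{ij}(f)^2 = 1}.
#'
#' @param coeffs `(p, m, m)` coefficient array at one time point.
#' @param freqs frequencies in Hz.
#' @param rate sampling rate in Hz.
#' @return array `(m, m, length(freqs))` of PDC values in `[0, 1]`.
#' @export
#' @examples
#' a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(0.5, 2); a[1, 2, 1] <- 0.5
#' pdc_spectrum(a, freqs = 0, rate = 1)[2, 1, 1]   # 0.5 / sqrt(0.5)
pdc_spectrum <- function(coeffs, freqs, rate) {
  stop_if_not(length(dim(coeffs)) == 3 && dim(coeffs)[2] == dim(coeffs)[3],
              "`coeffs` must be a (p, m, m) array")
  stop_if_not(all(is.finite(coeffs)), "`coeffs` contains non-finite values")
  p <- dim(coeffs)[1]; m <- dim(coeffs)[2]
  out <- array(0, c(m, m, length(freqs)))
  for (k in seq_along(freqs)) {
    Abar <- diag(m) + 0i
    for (r in seq_len(p))
      Abar <- Abar - matrix(coeffs[r, , ], m, m) *
        exp(-2i * pi * freqs[k] * r / rate)
    denom <- sqrt(colSums(Mod(Abar)^2))
    out[, , k] <- sweep(Mod(Abar), 2, denom, "/")
  }
  out
}

#' Time-resolved PDC tensor
#'
#' Applies [pdc_spectrum()] at every retained step of a DEKF coefficient
#' trajectory, optionally decimated in time.
#'
#' @param model a `tv_mvar` from [dekf_fit()].
#' @param freqs frequencies in Hz (e.g. 1-Hz steps across a band).
#' @param decimate keep every `decimate`-th time step (default 10).
#' @param max_cells guard on `m * m * F * T` of the result (default 5e7);
#'   exceeded sizes error with advice to decimate.
#' @return a `tpdc_tensor`: `values` (`(m, m, F, T)` in `[0, 1]`), `freqs`,
#'   `times`, `labels`.
#' @export
tpdc_compute <- function(model, freqs, decimate = 10, max_cells = 5e7) {
  stop_if_not(inherits(model, "tv_mvar"), "`model` must come from dekf_fit()")
  m <- model$m; p <- model$order
  idx <- seq.int(1L, dim(model$coeff_trajectory)[1], by = decimate)
  n_cells <- as.double(m) * m * length(freqs) * length(idx)
  if (n_cells > max_cells)
    stop(sprintf(paste0("tPDC tensor would hold %.3g cells (cap %.3g); ",
                        "increase `decimate`"), n_cells, max_cells),
         call. = FALSE)
  Tk <- length(idx)
  values <- array(0, c(m, m, length(freqs), Tk))
  # vectorized over time: complex response per (time, i, j) for each f
  A <- model$coeff_trajectory[idx, , , , drop = FALSE]  # (Tk, p, m, m)
  for (k in seq_along(freqs)) {
    ph <- exp(-2i * pi * freqs[k] * seq_len(p) / model$rate)
    Abar <- array(0i, c(Tk, m, m))                     # (time, i, j)
    for (i in seq_len(m)) Abar[, i, i] <- 1 + 0i
    for (r in seq_len(p))
      Abar <- Abar - array(A[, r, , ], c(Tk, m, m)) * ph[r]
    denom <- sqrt(apply(Mod(Abar)^2, c(1, 3), sum))    # (time, j)
    pi_k <- Mod(Abar) / aperm(array(denom, c(Tk, m, m)), c(1, 3, 2))
    values[, , k, ] <- aperm(pi_k, c(2, 3, 1))
  }
  structure(list(values = values, freqs = freqs,
                 times = model$times[idx], labels = model$labels),
            class = "tpdc_tensor")
}

#' @export
print.tpdc_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tpdc_tensor> %d x %d nodes, %d freqs, %d time steps\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Band-and-time mean edge strengths
#'
#' Collapses a [tpdc_compute()] tensor to an `m x m` matrix of mean directed
#' strengths (rows = target, columns = source); the diagonal is set to zero.
#'
#' @param tensor a `tpdc_tensor`.
#' @return `m x m` numeric matrix.
#' @export
tpdc_edge_strengths <- function(tensor) {
  stop_if_not(inherits(tensor, "tpdc_tensor"), "`tensor` must be a tpdc_tensor")
  s <- apply(tensor$values, c(1, 2), mean)
  diag(s) <- 0
  s
}

# One-call pipeline used by the surrogate machinery: series -> strengths.
tpdc_strengths_of <- function(series, order, freqs, q_param = 1e-4,
                              r_obs = 0.1, decimate = 10) {
  fit <- dekf_fit(series, order = order, q_param = q_param, r_obs = r_obs)
  tpdc_edge_strengths(tpdc_compute(fit, freqs, decimate = decimate))
}

#' Frequency grid covering a band
#'
#' @param band a [band_def()].
#' @param by grid step in Hz (default 1).
#' @return numeric vector of frequencies.
#' @export
band_freqs <- function(band, by = 1) seq(band$f_lo, band$f_hi, by = by)
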