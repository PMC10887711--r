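#' Multichannel time series
#'
#' The unit of all signal processing in the package: a channels-by-samples
#' matrix with a sampling rate, channel labels and a time offset.
#'
#' @param data numeric matrix, channels x samples (microvolts or a.u.).
#' @param rate sampling rate in Hz.
#' @param labels character vector of channel names; defaults to `ch1..chm`.
#' @param t0 time (seconds) of the first sample.
#'
#' @return an object of class `mc_series` with elements `data`, `rate`,
#'   `labels`, `t0`.
#' @export
#' @examples
#' x <- mc_series(matrix(rnorm(200), 2), rate = 100)
#' n_channels(x); n_samples(x); duration(x)
mc_series <- function(data, rate, labels = NULL, t0 = 0) {
  data <- as.matrix(data)
  stop_if_not(is.numeric(data), "`data` must be a numeric matrix")
  stop_if_not(is.numeric(rate) && length(rate) == 1L && rate > 0,
              "`rate` must be a single positive number (Hz)")
  stop_if_not(all(is.finite(data)), "`data` contains non-finite values")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stop_if_not(length(labels) == nrow(data),
              "`labels` length must equal the channel count")
  structure(list(data = data, rate = rate, labels = as.character(labels),
                 t0 = t0),
            class = "mc_series")
}

#' @rdname mc_series
#' @param x an `mc_series`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname mc_series
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname mc_series
#' @export
duration <- function(x) n_samples(x) / x$rate

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("<mc_series> %d channels x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              n_channels(x), n_samples(x), x$rate, duration(x), x$t0))
  invisible(x)
}

# Index helper: seconds (relative to t0) -> sample indices, clipped check left
# to callers.
sample_index <- function(x, t) round((t - x$t0) * x$rate) + 1L

#' Frequency band definition
#'
#' @param name band name, e.g. `"mu"` or `"beta"`.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return a `band_def` list.
#' @export
#' @examples
#' band_def("mu", 8, 12)
band_def <- function(name, f_lo, f_hi) {
  stop_if_not(is.numeric(f_lo) && is.numeric(f_hi) && f_lo > 0 && f_hi > f_lo,
              "band edges must satisfy 0 < f_lo < f_hi")
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_def")
}

#' Canonical analysis bands
#'
#' The mu (8-12 Hz) and low-beta (13-20 Hz) bands used throughout the
#' sensorimotor-oscillation analyses.
#' @param name `"mu"` or `"beta"`.
#' @return a [band_def()].
#' @export
standard_band <- function(name = c("mu", "beta")) {
  switch(match.arg(name),
         mu   = band_def("mu", 8, 12),
         beta = band_def("beta", 13, 20))
}
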