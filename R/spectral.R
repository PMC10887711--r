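## Welch spectral estimation: per-channel PSDs and sensor cross-spectral
## density matrices. One-sided density normalization: sum(psd * df) over all
## bins recovers the signal variance; a unit-amplitude sinusoid integrates
## to amplitude^2 / 2 = 0.5 over its band.

# Segment start indices for 50% overlapping segments of n_seg samples.
welch_segments <- function(n_total, n_seg, overlap = 0.5) {
  step <- max(1L, round(n_seg * (1 - overlap)))
  starts <- seq.int(1L, n_total - n_seg + 1L, by = step)
  starts
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed segments with 50% overlap.
#'
#' @param x numeric matrix, channels x samples (a plain vector is treated as
#'   one channel).
#' @param rate sampling rate in Hz.
#' @param seg_len segment length in seconds (default 1).
#' @return list with `psd` (channels x bins, one-sided density in
#'   units^2/Hz), `freqs` (Hz) and `n_segments`.
#' @export
welch_psd <- function(x, rate, seg_len = 1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_seg <- round(seg_len * rate)
  stop_if_not(ncol(x) >= n_seg,
              "series shorter than one spectral segment")
  w <- hann_window(n_seg)
  starts <- welch_segments(ncol(x), n_seg)
  scale <- 1 / (rate * sum(w^2))
  n_bins <- floor(n_seg / 2) + 1L
  acc <- matrix(0, nrow(x), n_bins)
  for (s in starts) {
    seg <- x[, s:(s + n_seg - 1L), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))            # detrend (mean removal)
    X <- t(stats::mvfft(t(seg * rep(w, each = nrow(seg)))))
    acc <- acc + Mod(X[, seq_len(n_bins), drop = FALSE])^2 * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even n_seg) Nyquist
  dbl <- rep(2, n_bins); dbl[1] <- 1
  if (n_seg %% 2 == 0) dbl[n_bins] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  list(psd = psd, freqs = (seq_len(n_bins) - 1L) * rate / n_seg,
       n_segments = length(starts))
}

#' Sensor cross-spectral density over a frequency band
#'
#' Welch-style averaged cross-spectra between all channel pairs, restricted
#' to the bins inside `band`. Each per-bin matrix is Hermitian with a real
#' non-negative diagonal.
#'
#' @param series an [mc_series()].
#' @param band a [band_def()] inside the Nyquist range.
#' @param seg_len segment length in seconds (default 1).
#' @return a `csd_matrix` list: `values` (complex array sensors x sensors x
#'   bins), `freqs` (Hz), `n_segments`, `rate`.
#' @export
compute_csd <- function(series, band, seg_len = 1) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  stop_if_not(inherits(band, "band_def"), "`band` must be a band_def")
  stop_if_not(band$f_hi < series$rate / 2, "band exceeds the Nyquist rate")
  x <- series$data
  n_seg <- round(seg_len * series$rate)
  stop_if_not(ncol(x) >= n_seg, "series shorter than one spectral segment")
  w <- hann_window(n_seg)
  starts <- welch_segments(ncol(x), n_seg)
  n_bins <- floor(n_seg / 2) + 1L
  freqs <- (seq_len(n_bins) - 1L) * series$rate / n_seg
  sel <- which(freqs >= band$f_lo & freqs <= band$f_hi)
  stop_if_not(length(sel) > 0, "no spectral bins fall inside the band")
  m <- nrow(x)
  values <- array(0i, dim = c(m, m, length(sel)))
  scale <- 2 / (series$rate * sum(w^2))   # one-sided (band excludes DC/Nyq)
  for (s in starts) {
    seg <- x[, s:(s + n_seg - 1L), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))
    X <- t(stats::mvfft(t(seg * rep(w, each = m))))  # m x n_seg
    for (k in seq_along(sel)) {
      v <- X[, sel[k]]
      values[, , k] <- values[, , k] + (v %*% Conj(t(v))) * scale
    }
  }
  values <- values / length(starts)
  # enforce exact Hermitian symmetry (guards against rounding drift)
  for (k in seq_along(sel))
    values[, , k] <- (values[, , k] + Conj(t(values[, , k]))) / 2
  structure(list(values = values, freqs = freqs[sel],
                 n_segments = length(starts), rate = series$rate,
                 labels = series$labels, band = band),
            class = "csd_matrix")
}

# Band-averaged real CSD used by the beamformer.
csd_band_average <- function(csd) {
  stop_if_not(inherits(csd, "csd_matrix"), "`csd` must be a csd_matrix")
  apply(csd$values, c(1, 2), mean)
}

#' Magnitude-squared coherence from a CSD
#'
#' @param csd a `csd_matrix` from [compute_csd()].
#' @param i,j channel indices.
#' @return coherence per band bin, each in `[0, 1]`.
#' @export
csd_coherence <- function(csd, i, j) {
  sxy <- csd$values[i, j, ]
  sxx <- Re(csd$values[i, i, ])
  syy <- Re(csd$values[j, j, ])
  as.numeric(Mod(sxy)^2 / (sxx * syy))
}
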