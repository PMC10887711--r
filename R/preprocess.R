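## Preprocessing: re-referencing, block trimming, epoching, band power,
## the desynchronization index, and amplitude-based artifact rejection.

#' Average re-referencing
#'
#' Subtracts the across-channel mean at every sample, the common offline
#' average reference for multichannel EEG.
#'
#' @param series an [mc_series()] with at least two channels.
#' @return the re-referenced `mc_series`; at every sample the channel mean is
#'   numerically zero.
#' @export
#' @examples
#' x <- mc_series(rbind(1:5, 2:6, 6:10), rate = 10)
#' colMeans(average_rereference(x)$data)
average_rereference <- function(series) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  stop_if_not(n_channels(series) >= 2,
              "average re-referencing needs at least 2 channels")
  out <- series
  out$data <- sweep(series$data, 2, colMeans(series$data))
  out
}

#' Trim the edges of a stimulation block
#'
#' Returns the central portion of a block, dropping `trim` seconds from each
#' end to avoid attention transients at stimulus onset/offset (e.g. an 80 s
#' block trimmed by 10 s yields the central 60 s).
#'
#' @param series an [mc_series()] at least `block_len` seconds long.
#' @param block_len block length in seconds (default 80).
#' @param trim seconds removed from each end (default 10).
#' @return the trimmed `mc_series`, `round((block_len - 2*trim) * rate)`
#'   samples long, with `t0` advanced by `trim`.
#' @export
trim_block <- function(series, block_len = 80, trim = 10) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  stop_if_not(trim >= 0 && trim < block_len / 2,
              "`trim` must satisfy 0 <= trim < block_len/2")
  stop_if_not(duration(series) >= block_len - 1e-9,
              "series shorter than `block_len`")
  i0 <- round(trim * series$rate) + 1L
  n_keep <- round((block_len - 2 * trim) * series$rate)
  out <- series
  out$data <- series$data[, seq.int(i0, i0 + n_keep - 1L), drop = FALSE]
  out$t0 <- series$t0 + trim
  out
}

#' Epoch a continuous recording around trial onsets
#'
#' Cuts fixed-length windows around each onset; the default window of
#' -1.5 to +3.5 s matches a trial analysis with a -500 to 0 ms reference and
#' a 500-2500 ms active period. Onsets whose window does not fit inside the
#' recording are skipped with a warning.
#'
#' @param series an [mc_series()].
#' @param onsets trial onset times in seconds (same clock as `t0`).
#' @param window length-2 numeric, window start/end in seconds relative to
#'   each onset.
#' @return a list of `mc_series` epochs (attribute `n_skipped` records how
#'   many onsets were dropped); each epoch's `t0` is the window start
#'   relative to its onset.
#' @export
epoch_trials <- function(series, onsets, window = c(-1.5, 3.5)) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  stop_if_not(length(window) == 2L && window[2] > window[1],
              "`window` must be (start, end) with end > start")
  n_win <- round(diff(window) * series$rate)
  epochs <- list()
  skipped <- 0L
  for (on in onsets) {
    i0 <- sample_index(series, on + window[1])
    i1 <- i0 + n_win - 1L
    if (i0 < 1L || i1 > n_samples(series)) {
      skipped <- skipped + 1L
      next
    }
    ep <- series
    ep$data <- series$data[, i0:i1, drop = FALSE]
    ep$t0 <- window[1]
    epochs[[length(epochs) + 1L]] <- ep
  }
  if (skipped > 0L)
    warning(sprintf("%d onset(s) too close to the recording edge; skipped",
                    skipped))
  attr(epochs, "n_skipped") <- skipped
  epochs
}

#' Band-limited power in a time window
#'
#' Mean band power per channel over a window, computed by integrating a
#' Welch periodogram (Hann segments, 50% overlap) over `[f_lo, f_hi]`.
#'
#' @param series an [mc_series()].
#' @param band a [band_def()].
#' @param window optional (start, end) in seconds relative to `t0` of the
#'   series; default uses the whole series.
#' @param seg_len Welch segment length in seconds (default 1).
#' @return numeric vector of non-negative per-channel powers (input units
#'   squared).
#' @export
band_power <- function(series, band, window = NULL, seg_len = 1) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  stop_if_not(inherits(band, "band_def"), "`band` must be a band_def")
  stop_if_not(band$f_hi < series$rate / 2, "band exceeds the Nyquist rate")
  x <- series$data
  if (!is.null(window)) {
    i0 <- sample_index(series, window[1])
    i1 <- sample_index(series, window[2]) - 1L
    stop_if_not(i0 >= 1 && i1 <= n_samples(series) && i1 >= i0,
                "`window` falls outside the series (or is empty)")
    x <- x[, i0:i1, drop = FALSE]
  }
  # windows shorter than one Welch segment fall back to a single
  # full-window periodogram (e.g. a 500 ms reference interval)
  seg_len <- min(seg_len, ncol(x) / series$rate)
  psd <- welch_psd(x, series$rate, seg_len = seg_len)
  sel <- psd$freqs >= band$f_lo & psd$freqs <= band$f_hi
  stop_if_not(any(sel), "no spectral bins fall inside the band")
  df <- psd$freqs[2] - psd$freqs[1]
  as.numeric(rowSums(psd$psd[, sel, drop = FALSE]) * df)
}

#' Desynchronization index
#'
#' Percent power change of the active period relative to a reference
#' interval, `(p_ref - p_act) / p_ref * 100`. Positive values mean
#' desynchronization (power suppression relative to the reference), negative
#' values synchronization.
#'
#' @param p_active power in the active window (per channel or scalar).
#' @param p_reference power in the reference window, strictly positive.
#' @param band optional [band_def()] carried along for bookkeeping.
#' @param reference_window,active_window optional (start, end) second pairs
#'   recorded in the result.
#' @return a `desync_index` list with `value` (percent), `band` and the two
#'   windows.
#' @export
#' @examples
#' desync_index(1, 4)$value   # 75% suppression
desync_index <- function(p_active, p_reference, band = NULL,
                         reference_window = c(-0.5, 0),
                         active_window = c(0.5, 2.5)) {
  stop_if_not(all(p_reference > 0), "`p_reference` must be positive")
  stop_if_not(length(p_active) == length(p_reference),
              "power vectors must have equal length")
  value <- (p_reference - p_active) / p_reference * 100
  structure(list(value = value, band = band,
                 reference_window = reference_window,
                 active_window = active_window),
            class = "desync_index")
}

#' Reject artifact-contaminated epochs
#'
#' Drops epochs whose peak absolute amplitude is an outlier across epochs:
#' for each channel the peak amplitudes are z-scored over epochs, and an
#' epoch is rejected when any channel's z-score exceeds `z_threshold`.
#' A simple amplitude rejector standing in for template-based artifact
#' removal.
#'
#' @param epochs list of [mc_series()] epochs.
#' @param z_threshold rejection threshold in SD units (default 5).
#' @return list with `kept` (epochs), `report` (data.frame of dropped epoch
#'   index, worst channel and its z-score).
#' @export
reject_artifacts <- function(epochs, z_threshold = 5) {
  stop_if_not(length(epochs) >= 1, "need at least one epoch")
  peaks <- vapply(epochs, function(e) apply(abs(e$data), 1, max),
                  numeric(n_channels(epochs[[1]])))
  peaks <- matrix(peaks, ncol = length(epochs))      # channels x epochs
  mu <- rowMeans(peaks)
  s <- apply(peaks, 1, sd)
  s[s == 0] <- Inf                                   # constant channel: keep
  z <- abs(sweep(sweep(peaks, 1, mu), 1, s, "/"))
  bad <- which(apply(z, 2, max) > z_threshold)
  if (length(bad) == length(epochs))
    stop("all epochs rejected; review `z_threshold`", call. = FALSE)
  report <- if (length(bad)) {
    data.frame(epoch = bad,
               channel = apply(z[, bad, drop = FALSE], 2, which.max),
               z = apply(z[, bad, drop = FALSE], 2, max),
               reason = "peak amplitude z-score above threshold")
  } else {
    data.frame(epoch = integer(), channel = integer(), z = numeric(),
               reason = character())
  }
  keep <- setdiff(seq_along(epochs), bad)
  list(kept = epochs[keep], report = report)
}
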