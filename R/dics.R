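## DICS-style frequency-domain beamforming: spatial filters from a
## band-averaged sensor cross-spectral density and a lead field, source
## power and coherence maps, source time-series extraction, pooled source
## signals, and segment-permutation significance.

#' DICS spatial filters
#'
#' For each source column \eqn{L_s} of the lead field, the unit-gain
#' minimum-variance filter
#' \eqn{w_s = (L_s^T C_r^{-1} L_s)^{-1} L_s^T C_r^{-1}} where
#' \eqn{C_r = Re(C) + \lambda \, \overline{diag(Re(C))} I} is the
#' regularized real part of the band-averaged CSD.
#'
#' @param leadfield a [make_leadfield()] object (or list with `gain`).
#' @param csd a `csd_matrix` from [compute_csd()] (band-averaged
#'   internally), or an already-averaged numeric/complex sensor matrix.
#' @param regularization Tikhonov loading as a fraction of the mean sensor
#'   power (default 0.05).
#' @return a `dics_filters` list: `weights` (sources x sensors), `leadfield`,
#'   `lambda`.
#' @export
dics_filter <- function(leadfield, csd, regularization = 0.05) {
  gain <- leadfield$gain
  C <- if (inherits(csd, "csd_matrix")) csd_band_average(csd) else csd
  stop_if_not(all(dim(C) == nrow(gain)),
              "CSD dimension must equal the lead-field sensor count")
  Cr <- Re(C) + regularization * mean(diag(Re(C))) * diag(nrow(C))
  Cinv <- tryCatch(solve(Cr), error = function(e)
    stop("regularized CSD is singular; increase `regularization`",
         call. = FALSE))
  W <- matrix(0, ncol(gain), nrow(gain))
  for (s in seq_len(ncol(gain))) {
    L <- gain[, s]
    ctl <- Cinv %*% L
    W[s, ] <- as.numeric(ctl / sum(L * ctl))
  }
  structure(list(weights = W, leadfield = leadfield,
                 lambda = regularization),
            class = "dics_filters")
}

#' Source power map
#'
#' Beamformer output power \eqn{Re(w_s C w_s^*)} per source at the
#' band-averaged CSD.
#'
#' @param filters a [dics_filter()] result.
#' @param csd a `csd_matrix` or an averaged sensor matrix.
#' @return non-negative numeric vector, one power per source.
#' @export
source_power_map <- function(filters, csd) {
  C <- if (inherits(csd, "csd_matrix")) csd_band_average(csd) else csd
  W <- filters$weights
  pw <- Re(diag(W %*% C %*% Conj(t(W))))
  pmax(as.numeric(pw), 0)
}

#' Source coherence map
#'
#' Magnitude-squared coherence between a reference signal and each source
#' estimate, computed per band bin from the sensor CSD and averaged over the
#' band. The reference is either a source index (its own beamformer
#' estimate) or a sensor index.
#'
#' @param filters a [dics_filter()] result.
#' @param csd a `csd_matrix` from [compute_csd()].
#' @param reference list-like with `source = i` or `sensor = k`.
#' @return numeric vector of band-mean coherences in `[0, 1]` per source.
#' @export
source_coherence_map <- function(filters, csd, reference) {
  stop_if_not(inherits(csd, "csd_matrix"),
              "`csd` must be a csd_matrix (per-bin values needed)")
  W <- filters$weights
  n_src <- nrow(W)
  n_bins <- dim(csd$values)[3]
  wr <- if (!is.null(reference$source)) W[reference$source, ]
        else if (!is.null(reference$sensor)) {
          v <- numeric(ncol(W)); v[reference$sensor] <- 1; v
        } else stop("`reference` must name a source or a sensor",
                    call. = FALSE)
  coh <- matrix(0, n_src, n_bins)
  for (k in seq_len(n_bins)) {
    C <- csd$values[, , k]
    Cw <- C %*% wr
    p_ref <- Re(sum(Conj(wr) * Cw))
    if (p_ref <= 0) stop("zero-power reference", call. = FALSE)
    for (s in seq_len(n_src)) {
      ws <- W[s, ]
      cross <- sum(Conj(ws) * Cw)
      p_s <- Re(sum(Conj(ws) * (C %*% ws)))
      coh[s, k] <- if (p_s > 0) Mod(cross)^2 / (p_s * p_ref) else 0
    }
  }
  pmin(pmax(rowMeans(coh), 0), 1)
}

#' Project sensor data through the spatial filters
#'
#' Source estimate time series `W %*% sensors`; length preserved.
#'
#' @param filters a [dics_filter()] result.
#' @param series an [mc_series()] of sensor data.
#' @return an [mc_series()] with one channel per source.
#' @export
extract_source_series <- function(filters, series) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  W <- filters$weights
  stop_if_not(ncol(W) == n_channels(series),
              "filter sensor count must match the series")
  mc_series(W %*% series$data, rate = series$rate,
            labels = paste0("src", seq_len(nrow(W))), t0 = series$t0)
}

#' Pool voxel series into a single source signal
#'
#' Weighted sum of the voxel time series belonging to one source cluster,
#' with weights proportional to each voxel's band power (second-order
#' spectrum) and normalized to sum to one.
#'
#' @param voxel_series an [mc_series()] whose channels are the voxels of one
#'   source cluster (or a list of single-channel `mc_series`).
#' @param band a [band_def()].
#' @return a `pooled_source` list: `series` (single-channel [mc_series()]),
#'   `weights` (summing to 1).
#' @export
pool_source_signal <- function(voxel_series, band) {
  if (is.list(voxel_series) && !inherits(voxel_series, "mc_series")) {
    stop_if_not(length(voxel_series) >= 1, "need at least one voxel series")
    dat <- do.call(rbind, lapply(voxel_series, function(v) v$data))
    voxel_series <- mc_series(dat, rate = voxel_series[[1]]$rate,
                              t0 = voxel_series[[1]]$t0)
  }
  pw <- band_power(voxel_series, band)
  if (sum(pw) <= 0)
    stop("all voxel series have zero band power; cannot pool", call. = FALSE)
  wts <- pw / sum(pw)
  pooled <- matrix(colSums(voxel_series$data * wts), nrow = 1)
  structure(list(series = mc_series(pooled, rate = voxel_series$rate,
                                    labels = "pooled",
                                    t0 = voxel_series$t0),
                 weights = wts),
            class = "pooled_source")
}

#' Segment-permutation significance of a source statistic
#'
#' Within-subject Monte-Carlo test: the series is cut into one-second
#' segments whose order is randomly permuted; the statistic is recomputed on
#' each surrogate. The p-value uses the add-one permutation estimator
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param statistic function mapping an [mc_series()] to a single number
#'   (e.g. band power of a source estimate).
#' @param series the [mc_series()] the observed statistic was computed from.
#' @param n_perm number of permutations (default 100).
#' @param seg_len segment length in seconds (default 1).
#' @param seed integer seed.
#' @return list with `p_value`, `observed`, `null` (permutation values),
#'   `significant` at the 99th-percentile criterion (`p <= 0.01`).
#' @export
source_significance <- function(statistic, series, n_perm = 100,
                                seg_len = 1, seed = NULL) {
  stop_if_not(is_count(n_perm), "`n_perm` must be a positive integer")
  n_seg_samp <- round(seg_len * series$rate)
  n_segs <- floor(n_samples(series) / n_seg_samp)
  stop_if_not(n_segs >= 2, "need at least two one-second segments")
  observed <- statistic(series)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    ord <- sample.int(n_segs)
    idx <- unlist(lapply(ord, function(s)
      (s - 1L) * n_seg_samp + seq_len(n_seg_samp)))
    statistic(mc_series(series$data[, idx, drop = FALSE],
                        rate = series$rate, labels = series$labels))
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, null = null,
       significant = p <= 0.01)
}

#' Coherent source record
#'
#' Bundles a localized band-specific generator: grid index, coordinate,
#' band, power, coherence and significance.
#'
#' @param grid_index index into the source grid.
#' @param coord length-3 coordinate (mm).
#' @param band a [band_def()].
#' @param power source power (a.u., non-negative).
#' @param coherence band-mean coherence in `[0, 1]`.
#' @param p_value significance in `[0, 1]` (optional).
#' @return a `coherent_source` list.
#' @export
coherent_source <- function(grid_index, coord, band, power,
                            coherence = NA_real_, p_value = NA_real_) {
  stop_if_not(length(coord) == 3, "`coord` must be (x, y, z) in mm")
  stop_if_not(power >= 0, "`power` must be non-negative")
  stop_if_not(is.na(coherence) || (coherence >= 0 && coherence <= 1),
              "`coherence` must lie in [0, 1]")
  stop_if_not(is.na(p_value) || (p_value >= 0 && p_value <= 1),
              "`p_value` must lie in [0, 1]")
  structure(list(grid_index = grid_index, coord = as.numeric(coord),
                 band = band, power = power, coherence = coherence,
                 p_value = p_value),
            class = "coherent_source")
}
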