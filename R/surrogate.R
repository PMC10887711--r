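## Significance machinery for directed connectivity: window-shuffling
## bootstrap thresholds and the time-reversal validation test.

# Shuffle non-overlapping windows of a series. "perchannel" permutes each
# channel's windows independently: cross-channel coupling (lagged and
# instantaneous) is destroyed while each channel's within-window
# autocorrelation survives, which is the null a directed-coupling test
# needs. "joint" applies one permutation to all channels; it preserves the
# within-window cross structure and is kept only for comparison.
shuffle_windows <- function(series, window_samples,
                            mode = c("perchannel", "joint")) {
  mode <- match.arg(mode)
  n_win <- floor(n_samples(series) / window_samples)
  win_idx <- function(ord) unlist(lapply(ord, function(w)
    (w - 1L) * window_samples + seq_len(window_samples)))
  out <- series
  if (mode == "joint") {
    out$data <- series$data[, win_idx(sample.int(n_win)), drop = FALSE]
  } else {
    n_keep <- n_win * window_samples
    dat <- series$data[, seq_len(n_keep), drop = FALSE]
    for (ch in seq_len(nrow(dat)))
      dat[ch, ] <- dat[ch, win_idx(sample.int(n_win))]
    out$data <- dat
  }
  out
}

#' Surrogate significance thresholds for tPDC edges
#'
#' Divides the series into non-overlapping windows, shuffles their order to
#' destroy time-lagged structure, refits the time-varying MVAR and recomputes
#' the band-and-time-mean tPDC; repeated `n_boot` times. The per-edge
#' threshold is a summary of the surrogate distribution: the 95th percentile
#' by default, or the surrogate mean (`threshold_mode = "mean"`, the
#' literal averaged-surrogate rule, which flags roughly half of null edges
#' and is kept for fidelity only — a warning is emitted). `scope = "global"`
#' pools all off-diagonal surrogate values into one threshold.
#'
#' @param series an [mc_series()] of (pooled) source signals.
#' @param order MVAR order for the refits.
#' @param band a [band_def()].
#' @param n_boot number of surrogates (default 100).
#' @param window_len shuffle window length in seconds (default 1).
#' @param threshold_mode `"percentile"` (default) or `"mean"`.
#' @param probs percentile used in percentile mode (default 0.95).
#' @param scope `"edge"` (per-edge thresholds, default) or `"global"`.
#' @param shuffle `"perchannel"` (default; windows permuted independently
#'   per channel, destroying cross-channel coupling while keeping each
#'   channel's within-window autocorrelation) or `"joint"` (one permutation
#'   for all channels; note that a joint shuffle leaves the within-window
#'   cross-lag structure intact, so supra-threshold detections are then
#'   essentially impossible — the mode exists for comparison only).
#' @param seed integer seed.
#' @param decimate,q_param,r_obs forwarded to the tPDC pipeline.
#' @return list with `threshold` (`m x m` matrix, diagonal `NA`),
#'   `surrogate` (`n_boot x m x m` array), `mode`, `scope`.
#' @export
bootstrap_threshold <- function(series, order, band, n_boot = 100,
                                window_len = 1,
                                threshold_mode = c("percentile", "mean"),
                                probs = 0.95, scope = c("edge", "global"),
                                shuffle = c("perchannel", "joint"),
                                seed = NULL, decimate = 10,
                                q_param = 1e-4, r_obs = 0.1) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  threshold_mode <- match.arg(threshold_mode)
  scope <- match.arg(scope)
  shuffle <- match.arg(shuffle)
  w_samp <- round(window_len * series$rate)
  stop_if_not(w_samp < n_samples(series),
              "`window_len` must be shorter than the series")
  stop_if_not(floor(n_samples(series) / w_samp) >= 2,
              "need at least two shuffle windows")
  if (threshold_mode == "mean")
    warning(paste("threshold_mode = 'mean' reproduces the averaged-surrogate",
                  "rule; it flags about half of null edges. The 95th",
                  "percentile is the calibrated default."))
  freqs <- band_freqs(band)
  m <- n_channels(series)
  surr <- array(NA_real_, c(n_boot, m, m))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      sh <- shuffle_windows(series, w_samp, mode = shuffle)
      surr[b, , ] <- tpdc_strengths_of(sh, order, freqs,
                                       q_param = q_param, r_obs = r_obs,
                                       decimate = decimate)
    }
  })
  off <- row(diag(m)) != col(diag(m))
  thr <- matrix(NA_real_, m, m)
  if (scope == "global") {
    pool <- as.numeric(apply(surr, 1, function(s) s[off]))
    v <- if (threshold_mode == "mean") mean(pool)
         else as.numeric(quantile(pool, probs))
    thr[off] <- v
  } else {
    summ <- apply(surr, c(2, 3), function(v)
      if (threshold_mode == "mean") mean(v)
      else as.numeric(quantile(v, probs)))
    thr[off] <- summ[off]
  }
  list(threshold = thr, surrogate = surr, mode = threshold_mode,
       scope = scope)
}

#' Time-reversal validation of candidate edges
#'
#' A true time-lagged (causal) interaction produces a directed tPDC
#' asymmetry that inverts when the series is played backwards, while
#' zero-lag (volume-conduction-like) mixing produces weak asymmetries that
#' do not. The test is applied per connection on the channel pair it links:
#' for each candidate edge the pair's bivariate asymmetry
#' `D = strength(src -> dst) - strength(dst -> src)` is computed on the
#' original and on the time-reversed pair series, and the edge passes when
#' the sign inverts and the reversed magnitude is at least `gamma` times
#' the original. (The pairwise form is used because the time-reversed
#' process of a correlated multivariate system is not the
#' coefficient-transposed one — its backward coefficients are
#' `Cov(y) A' Cov(y)^{-1}` — so full-system per-edge asymmetries need not
#' invert even for genuinely lagged coupling, while the two-channel
#' subsystem's asymmetry does.)
#'
#' @param series an [mc_series()] of source signals.
#' @param candidate_edges data.frame with integer columns `src`, `dst`.
#' @param order MVAR order.
#' @param band a [band_def()].
#' @param gamma magnitude-retention factor (default 0.5).
#' @param delta_min asymmetry floor (default 0.1): an original asymmetry
#'   below this — the scale of the tPDC estimation noise — is inconclusive
#'   and fails regardless of sign behaviour, because weak (noise- or
#'   mixing-driven) asymmetries can change sign by estimation variance
#'   alone.
#' @param trt_order MVAR order for the bivariate forward/reversed fits
#'   (default `max(order, 10)`): the two-channel margin of a network
#'   process carries longer dependencies than the full system, so the pair
#'   fits need a higher order than the network fit.
#' @param decimate,q_param,r_obs forwarded to the tPDC pipeline.
#' @return the `candidate_edges` data.frame with columns `delta_orig`,
#'   `delta_rev`, `trt_pass`.
#' @export
time_reversal_test <- function(series, candidate_edges, order, band,
                               gamma = 0.5, delta_min = 0.1,
                               trt_order = max(order, 10),
                               decimate = 10, q_param = 1e-4, r_obs = 0.1) {
  stop_if_not(all(c("src", "dst") %in% names(candidate_edges)),
              "`candidate_edges` needs `src` and `dst` columns")
  freqs <- band_freqs(band)
  out <- candidate_edges
  out$delta_orig <- rep(NA_real_, nrow(out))
  out$delta_rev <- rep(NA_real_, nrow(out))
  out$trt_pass <- rep(FALSE, nrow(out))
  if (nrow(out) == 0) return(out)
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(out))) {
    i <- out$src[k]; j <- out$dst[k]
    key <- pair_key(i, j)
    if (is.null(cache[[key]])) {
      pair <- mc_series(series$data[c(min(i, j), max(i, j)), , drop = FALSE],
                        rate = series$rate)
      rev_pair <- pair
      rev_pair$data <- pair$data[, rev(seq_len(ncol(pair$data))),
                                 drop = FALSE]
      cache[[key]] <- list(
        fwd = tpdc_strengths_of(pair, trt_order, freqs, q_param = q_param,
                                r_obs = r_obs, decimate = decimate),
        rev = tpdc_strengths_of(rev_pair, trt_order, freqs,
                                q_param = q_param, r_obs = r_obs,
                                decimate = decimate))
    }
    s <- cache[[key]]
    # index of src/dst inside the sorted pair
    a <- if (i < j) 1L else 2L; b <- 3L - a
    d0 <- s$fwd[b, a] - s$fwd[a, b]      # strength src->dst minus dst->src
    d1 <- s$rev[b, a] - s$rev[a, b]
    out$delta_orig[k] <- d0
    out$delta_rev[k] <- d1
    out$trt_pass[k] <- abs(d0) >= delta_min && sign(d1) == -sign(d0) &&
      abs(d1) >= gamma * abs(d0)
  }
  out
}

#' Assemble a directed connectivity graph
#'
#' Combines nodes (coherent sources), edge strengths, surrogate thresholds
#' and time-reversal flags into an annotated directed graph. An edge is
#' significant when its strength exceeds its threshold and it passed the
#' time-reversal test; edge lengths are Euclidean distances between node
#' coordinates (mm).
#'
#' @param sources list of [coherent_source()] objects, or a matrix of node
#'   coordinates (rows = nodes).
#' @param strengths `m x m` strength matrix (rows = target).
#' @param thresholds `m x m` matrix or single number.
#' @param trt data.frame from [time_reversal_test()] (matched by src/dst),
#'   an `m x m` logical matrix, or `NULL` to skip the TRT requirement.
#' @param band a [band_def()] recorded with the edges.
#' @return a `conn_graph`: `nodes`, `edges` (data.frame with src, dst, band,
#'   strength, threshold, significant, trt_pass, length_mm).
#' @export
#' @examples
#' s <- matrix(c(0.0, 0.4, 0.0, 0.0), 2, 2)
#' g <- build_graph(rbind(c(0, 0, 0), c(30, 40, 0)), s, 0.2, NULL)
#' g$edges
build_graph <- function(sources, strengths, thresholds, trt = NULL,
                        band = NULL) {
  m <- nrow(strengths)
  stop_if_not(ncol(strengths) == m, "`strengths` must be square")
  coords <- if (is.matrix(sources)) sources
            else do.call(rbind, lapply(sources, function(s) s$coord))
  if (!is.null(coords)) {
    stop_if_not(nrow(coords) == m, "one coordinate row per node required")
  } else {
    warning("node coordinates missing; edge lengths omitted")
  }
  if (length(thresholds) == 1) thresholds <- matrix(thresholds, m, m)
  trt_mat <- matrix(TRUE, m, m)
  if (is.matrix(trt)) {
    trt_mat <- trt
  } else if (is.data.frame(trt)) {
    trt_mat <- matrix(FALSE, m, m)
    for (k in seq_len(nrow(trt)))
      trt_mat[trt$dst[k], trt$src[k]] <- isTRUE(trt$trt_pass[k])
  }
  edges <- expand.grid(dst = seq_len(m), src = seq_len(m))[, c("src", "dst")]
  edges <- edges[edges$src != edges$dst, ]
  edges$band <- if (is.null(band)) NA_character_ else band$name
  edges$strength <- strengths[cbind(edges$dst, edges$src)]
  edges$threshold <- thresholds[cbind(edges$dst, edges$src)]
  edges$trt_pass <- trt_mat[cbind(edges$dst, edges$src)]
  edges$significant <- edges$strength > edges$threshold & edges$trt_pass
  edges$length_mm <- if (is.null(coords)) NA_real_ else
    sqrt(rowSums((coords[edges$src, , drop = FALSE] -
                    coords[edges$dst, , drop = FALSE])^2))
  rownames(edges) <- NULL
  structure(list(nodes = sources, edges = edges), class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf("<conn_graph> %d nodes, %d/%d significant directed edges\n",
              if (is.matrix(x$nodes)) nrow(x$nodes) else length(x$nodes),
              sum(x$edges$significant), nrow(x$edges)))
  invisible(x)
}

#' Per-subject mean directional coherence
#'
#' Summary of a subject's significant directed coherence values. The
#' default (`normalize = "all"`) averages the significant strengths over
#' all possible directed connections — non-significant connections
#' contribute zero — so the index reflects the total directed interaction
#' strength of the network and grows with both edge strength and edge
#' count. `normalize = "significant"` averages over the significant edges
#' only. Subjects without significant edges score 0 and are flagged.
#'
#' @param graph a `conn_graph` from [build_graph()].
#' @param normalize `"all"` (default) or `"significant"`.
#' @return single number with attribute `no_significant_edges`.
#' @export
mean_directional_coherence <- function(graph,
                                       normalize = c("all", "significant")) {
  stop_if_not(inherits(graph, "conn_graph"), "`graph` must be a conn_graph")
  normalize <- match.arg(normalize)
  sig <- graph$edges[graph$edges$significant, "strength"]
  if (length(sig) == 0)
    return(structure(0, no_significant_edges = TRUE))
  denom <- if (normalize == "all") nrow(graph$edges) else length(sig)
  structure(sum(sig) / denom, no_significant_edges = FALSE)
}

#' Group-wise mean directional coherence
#'
#' @param graphs list of `conn_graph` objects (one per subject).
#' @param normalize passed to [mean_directional_coherence()].
#' @return numeric vector of per-subject means.
#' @export
group_mean_directional_coherence <- function(graphs, normalize = "all") {
  stop_if_not(length(graphs) >= 1, "need at least one subject")
  vapply(graphs, function(g)
    as.numeric(mean_directional_coherence(g, normalize = normalize)),
    numeric(1))
}
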