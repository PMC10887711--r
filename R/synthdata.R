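## Synthetic-data generation: ground-truth directed oscillatory source
## networks, a toy spherical lead field, sensor projection, and
## signal-detection behaviour. These emulate the study conditions of a
## two-group (dense long-range vs sparse local connectivity) EEG experiment
## so every downstream stage is testable without recorded data.

#' Template node coordinates on an occipital-to-frontal axis
#'
#' Fixed pseudo-MNI positions (mm) spanning the posterior-anterior axis with
#' alternating lateralization, so that "long-range" (anterior-posterior) and
#' "local" edges are geometrically meaningful.
#'
#' @param n_nodes number of nodes.
#' @return `n_nodes x 3` matrix of (x, y, z) in mm; y runs from -95
#'   (occipital) to +55 (frontal).
#' @export
node_template <- function(n_nodes) {
  stop_if_not(is_count(n_nodes), "`n_nodes` must be a positive integer")
  y <- if (n_nodes == 1) 0 else seq(-95, 55, length.out = n_nodes)
  x <- 20 * (-1)^(seq_len(n_nodes))
  cbind(x = x, y = y, z = rep(10, n_nodes))
}

#' Group connectivity profile
#'
#' Describes the two simulated cohorts: `dense_longrange` (control-like:
#' many edges including at least one long anterior-posterior connection) and
#' `sparse_local` (many fewer edges, all short-range).
#'
#' @param name `"dense_longrange"` or `"sparse_local"`.
#' @param n_nodes number of network nodes.
#' @param n_edges number of directed edges (`<= n_nodes * (n_nodes - 1)`).
#' @param min_edge_length dense profile: at least one edge at least this
#'   long (mm, default 80).
#' @param length_cap sparse profile: all edges at most this long (mm,
#'   default 60).
#' @param edge_strength_range range of cross-coefficient magnitudes.
#'   Defaults differ by profile — `c(0.05, 0.10)` for `dense_longrange`,
#'   `c(0.04, 0.08)` for `sparse_local` — encoding the hypoconnectivity
#'   contrast the cohorts emulate (the sparse group has fewer *and weaker*
#'   directed connections) while keeping the driven-resonance variance
#'   amplification across the network within a physiological factor
#'   (stationary node variances within roughly an order of magnitude).
#' @return a `group_profile` list.
#' @export
group_network_profile <- function(name = c("dense_longrange", "sparse_local"),
                                  n_nodes = 5, n_edges = 10,
                                  min_edge_length = 80, length_cap = 60,
                                  edge_strength_range = NULL) {
  name <- match.arg(name)
  if (is.null(edge_strength_range))
    edge_strength_range <- if (name == "dense_longrange") c(0.05, 0.10)
                           else c(0.04, 0.08)
  stop_if_not(is_count(n_nodes) && n_nodes >= 2, "need at least 2 nodes")
  stop_if_not(n_edges >= 0 && n_edges <= n_nodes * (n_nodes - 1),
              "`n_edges` must be at most n_nodes * (n_nodes - 1)")
  structure(list(name = name, n_nodes = n_nodes, n_edges = n_edges,
                 min_edge_length = min_edge_length, length_cap = length_cap,
                 edge_strength_range = edge_strength_range),
            class = "group_profile")
}

#' Generate a ground-truth directed source network
#'
#' Builds a stable MVAR(2) specification whose nodes oscillate inside the
#' requested band (damped-oscillator AR(2) diagonal blocks with poles at the
#' band centre) and whose lag-1 cross-coefficients realize exactly
#' `profile$n_edges` directed edges honouring the profile's length
#' constraints. The ground-truth edge list is attached as `$truth`.
#'
#' @param profile a [group_network_profile()].
#' @param band a [band_def()].
#' @param rate sampling rate the poles are tuned for (Hz, default 500).
#' @param pole_radius diagonal oscillator pole radius (default 0.8). The
#'   network coupling itself pushes the coupled system's poles toward the
#'   unit circle (the generator rescales couplings until the companion
#'   spectral radius is below 0.995), so the diagonal radius mainly sets how
#'   much stable coupling the network can carry: values near 1 leave no
#'   stability headroom and force near-zero couplings.
#' @param coords optional `n_nodes x 3` coordinates; default [node_template()].
#' @param seed integer seed.
#' @return an [mvar_spec()] with extra fields `truth` (data.frame: src, dst,
#'   lag, coeff, length_mm), `band`, `rate`, `f0`.
#' @export
#' @examples
#' prof <- group_network_profile("sparse_local", n_nodes = 4, n_edges = 3)
#' net <- make_group_network(prof, standard_band("mu"), seed = 1)
#' net$truth
make_group_network <- function(profile, band, rate = 500, pole_radius = 0.8,
                               coords = NULL, seed = NULL) {
  stop_if_not(inherits(profile, "group_profile"),
              "`profile` must be a group_network_profile()")
  stop_if_not(inherits(band, "band_def"), "`band` must be a band_def")
  m <- profile$n_nodes
  if (is.null(coords)) coords <- node_template(m)
  pairs <- expand.grid(dst = seq_len(m), src = seq_len(m))[, c("src", "dst")]
  pairs <- pairs[pairs$src != pairs$dst, ]
  pairs$length_mm <- sqrt(rowSums(
    (coords[pairs$src, , drop = FALSE] - coords[pairs$dst, , drop = FALSE])^2))

  # Edges are oriented along a random topological order of the nodes, so
  # the network is acyclic whenever the requested count does not exceed the
  # number of eligible node pairs. Acyclic ground truth keeps the coupled
  # oscillator system stable at full coupling strength (cycles through
  # resonant nodes would force the stability rescaling below to crush the
  # couplings) and gives every connection the dominant direction that the
  # downstream time-reversal validation measures. Reverse-direction edges
  # are drawn only when the count exceeds the pair count (then the
  # rescaling loop guards stability).
  sel <- with_seed(seed, {
    ord <- sample.int(m)
    pos <- order(ord)
    forward <- pos[pairs$src] < pos[pairs$dst]
    eligible <- if (profile$name == "sparse_local")
      which(pairs$length_mm <= profile$length_cap)
    else seq_len(nrow(pairs))
    if (profile$name == "sparse_local" &&
        length(eligible) < profile$n_edges)
      stop(sprintf(paste0("length cap %g mm admits only %d directed pairs",
                          " but %d edges requested"),
                   profile$length_cap, length(eligible), profile$n_edges),
           call. = FALSE)
    if (profile$name == "dense_longrange" && profile$n_edges > 0 &&
        !any(pairs$length_mm >= profile$min_edge_length))
      stop(sprintf("no directed pair reaches min_edge_length %g mm",
                   profile$min_edge_length), call. = FALSE)
    primary <- intersect(eligible, which(forward))
    sel <- integer(0)
    if (profile$n_edges > 0) {
      if (profile$name == "dense_longrange") {
        # guarantee at least one long-range (anterior-posterior) edge
        long <- intersect(primary,
                          which(pairs$length_mm >= profile$min_edge_length))
        if (length(long)) sel <- long[sample.int(length(long), 1)]
      }
      pool <- sample(setdiff(primary, sel))
      sel <- c(sel, head(pool, max(0, profile$n_edges - length(sel))))
      short <- profile$n_edges - length(sel)
      if (short > 0) {                     # reciprocal fill
        left <- sample(setdiff(eligible, sel))
        sel <- c(sel, head(left, short))
      }
    }
    sel
  })
  edges <- pairs[sel, , drop = FALSE]
  edges$lag <- rep(1L, nrow(edges))
  edges$coeff <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 1),
                           runif(nrow(edges), profile$edge_strength_range[1],
                                 profile$edge_strength_range[2]))
  rownames(edges) <- NULL

  # Per-node oscillator frequencies spread over the central part of the
  # band (individual peak frequencies differ across sources in real
  # recordings). Identical frequencies would make driven chains resonate
  # coherently, producing near-collinear signals and unbounded chain gain.
  bw <- band$f_hi - band$f_lo
  f0 <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 2),
                  runif(m, band$f_lo + 0.15 * bw, band$f_hi - 0.15 * bw))
  # the AR(2) spectral peak sits below the pole angle for r < 1
  # (cos w_peak = (1 + r^2) / (2 r) * cos theta); invert that relation so
  # the realized periodogram peak, not the pole, lands on f0
  omega <- 2 * pi * f0 / rate
  theta <- acos(pmin(1, pmax(-1, 2 * pole_radius /
                               (1 + pole_radius^2) * cos(omega))))
  a <- array(0, c(2, m, m))
  for (i in seq_len(m)) {
    a[1, i, i] <- 2 * pole_radius * cos(theta[i])
    a[2, i, i] <- -pole_radius^2
  }
  for (k in seq_len(nrow(edges)))
    a[edges$lag[k], edges$dst[k], edges$src[k]] <- edges$coeff[k]
  # shrink cross-terms if coupling pushed the system to the edge of
  # stability; diagonal oscillators stay untouched
  repeat {
    spec <- mvar_spec(a, diag(m), coords = coords)
    st <- mvar_stable(spec)
    if (attr(st, "spectral_radius") < 0.995) break
    for (k in seq_len(nrow(edges))) {
      edges$coeff[k] <- edges$coeff[k] * 0.8
      a[edges$lag[k], edges$dst[k], edges$src[k]] <- edges$coeff[k]
    }
  }
  # calibrate per-node innovation variances so every source has unit
  # stationary variance: without this, resonant driving makes downstream
  # sources orders of magnitude stronger than their drivers, which no
  # physiological source configuration shows. The node variance is linear
  # in the innovation variances, so m Lyapunov solves give the exact gains.
  if (m <= 12) {
    G <- matrix(0, m, m)
    for (j in seq_len(m)) {
      e_j <- matrix(0, m, m); e_j[j, j] <- 1
      G[, j] <- diag(mvar_stationary_cov(a, e_j))
    }
    # non-negative Gauss-Seidel solve of G s = 1 with an innovation floor:
    # a heavily driven node may not be reducible to unit variance with a
    # non-negative innovation, so its innovation bottoms out at the floor
    s <- rep(1, m) / diag(G)
    for (it in seq_len(50)) {
      for (i in seq_len(m))
        s[i] <- max((1 - sum(G[i, -i] * s[-i])) / G[i, i], 0.02 / G[i, i])
    }
    spec <- mvar_spec(a, diag(as.numeric(s), m), coords = coords)
  }
  spec$truth <- edges
  spec$band <- band
  spec$rate <- rate
  spec$f0 <- f0
  spec$profile <- profile$name
  spec
}

#' Toy spherical lead field
#'
#' A synthetic fixed-orientation gain matrix: sensors on a scalp hemisphere
#' of radius 100 mm, with gain decaying smoothly with sensor-source
#' distance. A geometric stand-in adequate for exercising beamforming; it is
#' not a conductor model.
#'
#' @param source_coords `n_sources x 3` matrix (mm).
#' @param n_sensors number of scalp sensors (default 32).
#' @return a `leadfield` list: `gain` (sensors x sources), `sensor_coords`,
#'   `source_coords`, `head_model = "toy-sphere-gain"`.
#' @export
make_leadfield <- function(source_coords, n_sensors = 32) {
  source_coords <- as.matrix(source_coords)
  stop_if_not(ncol(source_coords) == 3, "`source_coords` must be n x 3 (mm)")
  # quasi-uniform hemisphere sampling (golden-angle spiral)
  k <- seq_len(n_sensors)
  z <- (k - 0.5) / n_sensors              # cos(elevation) in (0, 1): upper half
  phi <- k * pi * (3 - sqrt(5))
  r_scalp <- 100
  sens <- cbind(x = r_scalp * sqrt(1 - z^2) * cos(phi),
                y = r_scalp * sqrt(1 - z^2) * sin(phi),
                z = r_scalp * z)
  d <- sqrt(outer(rowSums(sens^2), rep(1, nrow(source_coords))) -
              2 * sens %*% t(source_coords) +
              outer(rep(1, n_sensors), rowSums(source_coords^2)))
  gain <- 1 / (1 + (d / 50)^2)
  structure(list(gain = gain, sensor_coords = sens,
                 source_coords = source_coords,
                 head_model = "toy-sphere-gain"),
            class = "leadfield")
}

#' Project source activity to sensors
#'
#' Linear instantaneous forward model: `sensors = gain %*% sources + noise`
#' with white Gaussian sensor noise.
#'
#' @param sources an [mc_series()] of source signals.
#' @param leadfield a [make_leadfield()] object (or any list with a `gain`
#'   matrix) whose source count matches `sources`.
#' @param sensor_noise_sd sensor noise standard deviation (same units as the
#'   projected signal; default 0).
#' @param seed integer seed for the noise draw.
#' @return an [mc_series()] of sensor signals.
#' @export
project_to_sensors <- function(sources, leadfield, sensor_noise_sd = 0,
                               seed = NULL) {
  stop_if_not(inherits(sources, "mc_series"), "`sources` must be an mc_series")
  gain <- leadfield$gain
  stop_if_not(ncol(gain) == n_channels(sources),
              sprintf("lead field expects %d sources but series has %d",
                      ncol(gain), n_channels(sources)))
  y <- gain %*% sources$data
  if (sensor_noise_sd > 0)
    y <- y + with_seed(seed, matrix(rnorm(length(y), sd = sensor_noise_sd),
                                    nrow(y), ncol(y)))
  mc_series(y, rate = sources$rate,
            labels = paste0("s", seq_len(nrow(gain))), t0 = sources$t0)
}

#' Simulate a yes/no detection session
#'
#' Equal-variance Gaussian signal-detection model: on signal trials the
#' decision variable is N(d', 1), on noise trials N(0, 1); the observer
#' responds "signal" when it exceeds `criterion`.
#'
#' @param n_trials trials per class (signal and noise).
#' @param dprime_true generative sensitivity d'.
#' @param criterion decision criterion (0 = neutral).
#' @param condition label stored with the session (default `"walker"`).
#' @param seed integer seed.
#' @return a `behavioral_session` list with `n_signal_trials`,
#'   `n_noise_trials`, `hits`, `false_alarms`, `condition`.
#' @export
#' @examples
#' s <- simulate_behavior(200, dprime_true = 2, seed = 1)
#' dprime(s)
simulate_behavior <- function(n_trials, dprime_true, criterion = 0,
                              condition = "walker", seed = NULL) {
  stop_if_not(is_count(n_trials), "`n_trials` must be a positive integer")
  p_hit <- pnorm(dprime_true - criterion)
  p_fa <- pnorm(-criterion)
  counts <- with_seed(seed, c(rbinom(1, n_trials, p_hit),
                              rbinom(1, n_trials, p_fa)))
  structure(list(n_signal_trials = n_trials, n_noise_trials = n_trials,
                 hits = counts[1], false_alarms = counts[2],
                 condition = condition),
            class = "behavioral_session")
}

## ---- point-light walker stimuli ------------------------------------------

#' Parametric point-light walker
#'
#' A sinusoidal-kinematics stand-in for motion-capture walker data: 15 dots
#' at the major joints, limbs swinging at the gait frequency (about two
#' steps, i.e. one full cycle, per second when played at `cycle_length`
#' samples per second) with a double-frequency vertical bob of the trunk.
#'
#' @param n_dots number of dots (default 15).
#' @param cycle_length samples per gait cycle (default 120).
#' @param n_cycles number of cycles (default 2).
#' @return a `dot_trajectories` list: `positions` (array n_dots x T x 2),
#'   `cycle_length`, `n_dots`.
#' @export
make_walker <- function(n_dots = 15, cycle_length = 120, n_cycles = 2) {
  stop_if_not(is_count(n_dots) && is_count(cycle_length) &&
                is_count(n_cycles), "sizes must be positive integers")
  T <- cycle_length * n_cycles
  ph <- 2 * pi * seq_len(T) / cycle_length
  # base joint layout (x, y) in display units, head at top
  base <- cbind(
    x = c(0, -8, 8, -12, 12, -10, 10, 0, -5, 5, -6, 6, -5, 5, 0),
    y = c(60, 50, 50, 38, 38, 26, 26, 42, 28, 28, 14, 14, 0, 0, 33))
  base <- base[seq_len(min(n_dots, 15)), , drop = FALSE]
  if (n_dots > 15)
    base <- rbind(base, cbind(x = runif(n_dots - 15, -12, 12),
                              y = runif(n_dots - 15, 0, 60)))
  # limb swing amplitude and phase per dot: arms/legs antiphase, trunk bobs
  amp_x <- c(0, 2, 2, 6, 6, 9, 9, 1, 5, 5, 8, 8, 10, 10, 1)[seq_len(n_dots)]
  amp_y <- c(1, 1, 1, 2, 2, 3, 3, 1, 2, 2, 3, 3, 2, 2, 1)[seq_len(n_dots)]
  phase <- c(0, 0, pi, 0, pi, 0, pi, 0, pi, 0, pi, 0, 0, pi, 0)[seq_len(n_dots)]
  amp_x[is.na(amp_x)] <- 4; amp_y[is.na(amp_y)] <- 2; phase[is.na(phase)] <- 0
  pos <- array(0, c(n_dots, T, 2))
  for (i in seq_len(n_dots)) {
    pos[i, , 1] <- base[i, 1] + amp_x[i] * sin(ph + phase[i])
    pos[i, , 2] <- base[i, 2] + amp_y[i] * sin(2 * ph + phase[i])
  }
  structure(list(positions = pos, cycle_length = cycle_length,
                 n_dots = n_dots),
            class = "dot_trajectories")
}

# Speed (display units per sample) along one trajectory, central differences
# at the interior, one-sided at the ends.
trajectory_speed <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(d[1], (d[-1] + d[-length(d)]) / 2, d[length(d)])
}

#' Scramble transform of a point-light walker
#'
#' Constructs the scramble (baseline) stimulus: the spatial positions of the
#' dot trajectories are permuted, and each trajectory is re-timed to the
#' constant speed equal to its mean speed over one cycle. The shape of each
#' path and each dot's cycle frequency are preserved; only the acceleration
#' profile characteristic of biological motion is destroyed.
#'
#' @param walker a [make_walker()]-style `dot_trajectories` object with at
#'   least one full cycle.
#' @param seed integer seed for the position permutation.
#' @return a `dot_trajectories` object of the same dimensions; attribute
#'   `permutation` records the applied position permutation.
#' @export
scramble_transform <- function(walker, seed = NULL) {
  stop_if_not(inherits(walker, "dot_trajectories"),
              "`walker` must be a dot_trajectories object")
  pos <- walker$positions
  n_dots <- dim(pos)[1]; T <- dim(pos)[2]; L <- walker$cycle_length
  stop_if_not(T >= L, "walker must contain at least one full cycle")
  perm <- with_seed(seed, sample.int(n_dots))
  out <- array(0, dim(pos))
  # move each trajectory to the centroid of its permutation partner
  cent <- t(apply(pos, 1, function(xy) colMeans(matrix(xy, ncol = 2))))
  for (i in seq_len(n_dots)) {
    xy <- matrix(pos[i, , ], ncol = 2)
    xy <- sweep(xy, 2, cent[i, ] - cent[perm[i], ])
    # cycle-wise constant-speed re-parameterization (preserves per-dot
    # cycle frequency: each cycle maps onto itself)
    for (c0 in seq.int(0, T - L, by = L)) {
      seg <- xy[c0 + seq_len(L), , drop = FALSE]
      d <- sqrt(rowSums(diff(seg)^2))
      total <- sum(d)
      if (total <= 0)
        stop("zero-length trajectory: dot does not move over a cycle",
             call. = FALSE)
      s <- c(0, cumsum(d))                       # arc length at each sample
      s_new <- seq(0, total, length.out = L)     # equal-arc-length grid
      out[i, c0 + seq_len(L), 1] <- approx(s, seg[, 1], xout = s_new,
                                           ties = "ordered")$y
      out[i, c0 + seq_len(L), 2] <- approx(s, seg[, 2], xout = s_new,
                                           ties = "ordered")$y
    }
  }
  structure(list(positions = out, cycle_length = L, n_dots = n_dots),
            class = "dot_trajectories", permutation = perm)
}
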