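---
title: "Methods: time-resolved directed connectivity for oscillatory source networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved directed connectivity for oscillatory source networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpdcnet)
```

## The problem

Sensorimotor engagement during the perception of biological motion is
indexed by oscillatory activity in the mu (8–12 Hz) and low-beta
(13–20 Hz) bands. Beyond per-region power and coherence, the question of
*who drives whom* among the cortical generators of these rhythms requires
directed, time-resolved connectivity measures. `tpdcnet` implements that
analysis chain for multichannel EEG-like recordings — desynchronization
indexing, frequency-domain beamforming to coherent sources, time-resolved
partial directed coherence (tPDC) with surrogate and time-reversal
significance testing, rank-based group statistics, and SVM group
classification — together with a synthetic-data generator that provides
ground-truth directed networks, so every stage of the chain is testable
without access to recorded data.

## The core model

All directed measures derive from a multivariate autoregressive (MVAR)
model of the $m$ source signals,
$$y_t = \sum_{r=1}^{p} A_r\, y_{t-r} + e_t, \qquad e_t \sim N(0, \Sigma).$$
Its frequency response $\bar A(f) = I - \sum_r A_r e^{-i 2\pi f r / f_s}$
defines partial directed coherence,
$$\pi_{ij}(f) = \frac{|\bar A_{ij}(f)|}{\sqrt{\sum_k |\bar A_{kj}(f)|^2}},$$
the column-normalized directed influence of node $j$ on node $i$
(`pdc_spectrum()`). By construction $\sum_i \pi_{ij}(f)^2 = 1$ for every
source column, which the test suite verifies to $10^{-6}$ across random
stable models.

### Dual-filter coefficient tracking

Time resolution comes from estimating $A_r$ at every sample with a dual
extended Kalman filter (`dekf_fit()`): a state filter tracks the stacked
lagged-signal state under the current coefficients, and a parameter filter
tracks $\mathrm{vec}(A_1 \ldots A_p)$ under a random-walk model, each
feeding the other within a sample step. PDC evaluated on the coefficient
trajectory yields the tPDC tensor $\pi_{ij}(f, t)$ (`tpdc_compute()`); a
band-and-time mean collapses it to one directed strength per edge.

Hyperparameters, with defaults and rationale:

* `q_param = 1e-4` — random-walk variance of the parameter filter. It sets
  the tracking/variance trade-off: the suite verifies that a coefficient
  step of 0.5 is crossed half-way within 500 samples, while stationary
  estimates stay within ±0.05 of the truth.
* `r_obs = 0.1` — observation-noise scale of the state filter, as a
  fraction of the innovation variance.
* Warm start and noise covariances come from a least-squares MVAR fit on
  the *whole* series. A short leading window would underestimate the
  innovation scale of strongly driven channels in surrogate refits (window
  shuffling destroys exactly the structure that made them predictable),
  making the parameter filter overconfident and inflating spurious
  coefficients; the full-series estimate removes that failure mode.
* `order` defaults to 5 at 500 Hz for real recordings; the simulation
  experiments use the generative order 2, stated with each experiment.

### Surrogate thresholds

Significance of an edge strength is assessed against surrogates built by
cutting the series into 1-s windows and permuting their order
(`bootstrap_threshold()`, 100 surrogates by default). Windows are permuted
*independently per channel*: this destroys all cross-channel coupling
(lagged and instantaneous) while preserving each channel's within-window
autocorrelation, which is precisely the null hypothesis a directed-coupling
test needs. A joint permutation of all channels is available
(`shuffle = "joint"`) but leaves the within-window cross-lag structure
intact — at 1-s windows and typical sampling rates more than 99% of lag
transitions survive — so surrogate strengths then equal observed strengths
and nothing can ever reach significance; it is retained for comparison
only. The per-edge threshold is the 95th percentile of the surrogate
distribution; the literal averaged-surrogate rule is available as
`threshold_mode = "mean"` but flags about half of all null edges and warns
accordingly. Thresholds may also be pooled over edges
(`scope = "global"`).

### Time-reversal validation

Volume conduction mixes sources into channels instantaneously; a mixture
of a stationary Gaussian source is statistically time-reversible, so its
apparent directed asymmetry *keeps* its sign when the recording is played
backwards, whereas a genuinely lagged interaction inverts it.
`time_reversal_test()` therefore recomputes the asymmetry
$\Delta = s_{\text{src}\to\text{dst}} - s_{\text{dst}\to\text{src}}$ on
the reversed series and passes an edge only if the sign inverts, at least
half the magnitude is retained (`gamma = 0.5`), and the original asymmetry
exceeds a floor of 0.1 — asymmetries at the scale of the tPDC estimation
noise are inconclusive regardless of sign behaviour.

Two implementation points matter. First, the test is applied *pairwise*,
on the two channels an edge links: the time-reversed version of a
correlated multivariate process has backward coefficients
$\Gamma(0) A^\top \Gamma(0)^{-1}$, not $A^\top$, so full-system per-edge
asymmetries need not invert even for genuinely lagged coupling, while the
two-channel subsystem's asymmetry does. Second, the pair fits use a higher
order (`trt_order = max(order, 10)`) because the bivariate margin of a
network process carries longer dependencies than the full system.

The validation suite shows 100% pass on constructed unidirectional lagged
couplings and 100% rejection of zero-lag mixtures (20 seeds each). The
test is intentionally conservative on *network margins*: when two nodes
share common drivers, the marginal asymmetry of the pair can point
backward, and such confounded edges fail. For that reason the
edge-recovery experiments quantify the detection stage (surrogate
thresholds) on its own, and the source-level cohort keeps the guard off by
default (`simulate_cohort(trt = FALSE)`) — there is no instantaneous
mixing in source-level simulations for it to reject. The sensor-level
pipeline (`run_pipeline()`), where beamformer leakage does create
instantaneous crosstalk, keeps it on.

## Source estimation

`dics_filter()` implements the frequency-domain beamformer: from the
band-averaged real part of the sensor cross-spectral density $C$
(`compute_csd()`, Welch cross-spectra with Hann windows and 50% overlap)
and a lead-field column $L_s$, the unit-gain spatial filter is
$w_s = (L_s^\top C_r^{-1} L_s)^{-1} L_s^\top C_r^{-1}$ with Tikhonov
loading $C_r = C + \lambda\, \overline{\mathrm{diag}(C)}\, I$
($\lambda = 0.05$ by default, standard beamformer practice; exposed
because no canonical value exists). Power maps, source-coherence maps,
source time-series extraction and band-power-proportional pooling of voxel
series follow from the filters; the per-voxel pooling weights are
proportional to band power and normalized to sum to one. Within-subject
source significance uses a Monte-Carlo permutation of 1-s segments with
the add-one estimator $p = (1 + \#\{\pi \ge \text{obs}\})/(1 + n_\pi)$ and
a 99th-percentile criterion.

The head model is deliberately simple: a synthetic spherical gain
(`make_leadfield()`, sensors on a 100-mm scalp sphere, gain decaying
smoothly with distance). It is a geometric stand-in adequate for
exercising and testing beamforming, not a conductor model; realistic
BEM/FEM modeling is out of scope, and user-supplied gain matrices are
accepted everywhere.

## The synthetic study conditions

`simulate_cohort()` emulates a two-group experiment: a control-like group
("TDC") with *dense long-range* directed source networks, stronger source
power and better detection behaviour, and a contrast group ("ASD-like")
with *sparse local* networks, weaker coupling and poorer behaviour.

The generator's central choices, made once:

* **Network layout.** Five nodes on a fixed pseudo-anatomical
  occipital-to-frontal template (`node_template()`), so "long-range"
  (anterior–posterior, ≥ 80 mm) and "local" (≤ 60 mm) are measurable.
  The dense profile carries 10 directed edges with at least one
  anterior–posterior connection; the sparse profile 4 short edges.
* **Dynamics.** Each node is a damped AR(2) oscillator whose pole angle is
  set so the *realized spectral peak* (not the pole) lands at the node's
  frequency; per-node frequencies are spread over the central 70% of the
  band, since identical frequencies would make driven chains resonate
  coherently into near-collinear signals. The default pole radius is 0.8:
  the coupled system's poles end up near 0.99 anyway (the generator
  rescales couplings until the companion spectral radius is below 0.995),
  and radii near 1 leave no stability headroom, forcing couplings to
  near zero.
* **Coupling.** Edges are lag-1 cross-coefficients oriented along a random
  topological order, so networks are acyclic whenever the edge count
  allows: cycles through identically tuned resonant nodes would make the
  network unstable at any useful coupling strength, and a dominant
  direction per connection is what the time-reversal criterion measures.
  Default strengths are 0.05–0.10 (dense) and 0.04–0.08 (sparse),
  encoding the hypoconnectivity contrast — fewer *and weaker* connections
  in the contrast group — while keeping driven-resonance variance
  amplification within a physiological order of magnitude. Innovation
  variances are then calibrated (non-negative Gauss–Seidel solve of the
  Lyapunov variance equations) so every source has approximately unit
  stationary variance.
* **Behaviour.** Yes/no detection sessions under the equal-variance
  signal-detection model, 80 trials per class and condition, generative
  d′ of 2.5/2.0 (walker/scramble) for controls and 1.2/1.0 for the
  contrast group — large, clearly separated sensitivities consistent with
  a marked group deficit; the criterion sits at d′/2 (unbiased observer).
* **Stimuli.** A parametric point-light walker (15 joint dots, sinusoidal
  limb kinematics, one gait cycle per second) stands in for motion-capture
  data. Its scramble transform permutes the dots' spatial positions and
  re-times each trajectory to the constant speed equal to its cycle-mean
  speed, preserving path shape and per-dot cycle frequency — removing
  exactly the acceleration cue that distinguishes biological motion.

What the generator does *not* emulate: 1/f background EEG, ocular or
muscle artifacts beyond simple amplitude outliers, nonstationary
(task-locked) connectivity within a trial, volume conduction beyond the
linear lead field, inter-subject anatomical variability, or any clinical
heterogeneity. Passing the simulation suites therefore demonstrates that
the estimators recover the truth under their own model class at realistic
sizes — not that they are robust to everything real recordings contain.

## Group analysis and classification

Per subject the pipeline produces band power of the first source, mean
pairwise source coherence ("total interaction strength"), and mean
directional coherence. The directional index divides the sum of
significant directed strengths by the number of *possible* directed
connections (non-significant connections contribute zero), so it reflects
total directed interaction strength and grows with both edge strength and
edge count; a mean over significant edges only is available
(`normalize = "significant"`) but discards the density information — and,
because column-normalized PDC makes each edge of a sparse network
individually stronger, it can rank a sparse network above a denser one.

Group tests are rank-based (Mann–Whitney, Kruskal–Wallis, two-sided,
α = 0.05, no multiple-testing correction — mirroring the analysis the
pipeline reproduces; a Shapiro–Wilk gate documents why the nonparametric
path is taken). d′ uses the 1/(2N) extreme-rate correction, the most
common convention. The behavioural outlier rule removes subjects ≥ 1.5 SD
from the group mean in a single, non-iterated pass. Age can be adjusted by
rank residualization before the group tests; how a covariate should enter
rank tests is genuinely open, and the linear-on-ranks choice is the
simplest defensible one.

Classification uses a soft-margin SVM with the cubic polynomial kernel
$K(x, y) = (0.25\, x^\top y + 1)^3$ and the penalty C searched over
1…10. "10-fold cross-validation with 75/25 splits" is internally
inconsistent (10-fold implies 90/10), so the scheme is 10 repeated
stratified Monte-Carlo splits at 75/25, honouring both stated numbers.
Standardization is computed on each training portion only, and C is
selected by nested inner splits within the training portion; a
white-noise-features suite verifies the absence of information leakage.
Note that with a *fixed* γ the kernel is not invariant to duplicating
feature columns (the inner product doubles); the suite asserts the exact
invariance — identical results when γ is halved in compensation.

## Numerical choices and degenerate inputs

* Welch estimation: Hann windows, 50% overlap, one-sided density scaling
  (a unit-amplitude sinusoid integrates to 0.5 over its band); windows
  shorter than one segment fall back to a single full-window periodogram
  (the 500-ms reference interval needs this).
* Band power integrates the PSD over `[f_lo, f_hi]`; the filter-Hilbert
  alternative was rejected for the default because the rest of the chain
  is frequency-domain and Welch integration is deterministic.
* The ERD index is `(ref - act)/ref * 100`, positive = desynchronization;
  it is scale-invariant and errors on non-positive reference power.
* The tPDC tensor guard errors when `m^2 F T` exceeds 5·10^7 cells and
  advises decimation; the default time decimation is 10.
* Degenerate inputs error loudly: unstable specifications (with the
  spectral radius in the message), non-PSD covariances, single-channel
  re-referencing, empty power windows, all-rejected epoch sets,
  zero-length scramble trajectories, zero-power pooling, all-tied
  Kruskal–Wallis input (H = 0, p = 1).

## Problem sizes used by the test and acceptance runs

Simulation experiments run at desk scale, chosen once: cohorts of 20
subjects per group, 30 s of source signal per subject at 250 Hz, MVAR
order 2, 30–40 surrogates per subject; DEKF recovery at 10,000 samples;
DICS localization on a 125-point grid with 48 sensors and 100 repetitions;
calibration suites with 20–40 seeds and 2,000 null replicates for the
rank-test error rates. The sampling rate of recorded data (500 Hz) and
the 1-s surrogate/permutation segments are retained everywhere they appear
as analysis constants.

## Known limitations

* tPDC has a nonzero noise floor (rectified estimation noise in
  $|\bar A_{ij}|$), so weak true couplings below roughly the surrogate
  threshold scale are undetectable in principle at these data lengths.
* Pairwise time-reversal validation is conservative under confounding:
  edges between nodes that share strong common drivers can fail even when
  genuinely present.
* The lead field is geometric, not biophysical; localization results
  validate the estimator's algebra, not conductor-model accuracy.
* The generator's networks are acyclic at default sizes; feedback loops
  between identically tuned resonators are unstable at useful coupling
  strengths in this model class, so reciprocal interactions are only
  exercised where the requested edge count forces them.
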