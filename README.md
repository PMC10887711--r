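# tpdcnet

Directed network inference from multivariate oscillatory time series, aimed
at EEG source signals in the mu (8–12 Hz) and low-beta (13–20 Hz) bands.
The package is written for researchers who want to go beyond per-region
power and coherence and ask *who drives whom* among the cortical
generators of sensorimotor rhythms — for example when comparing a control
group against a group with atypical biological-motion perception — and who
need every stage of that analysis to be testable against ground truth.

## What it computes

The core model is a (time-varying) multivariate autoregressive process
`y_t = Σ_r A_r y_{t−r} + e_t`. Its frequency response
`Ā(f) = I − Σ_r A_r e^{−i2πfr/fs}` defines **partial directed coherence**

```
π_ij(f) = |Ā_ij(f)| / sqrt(Σ_k |Ā_kj(f)|²),
```

the column-normalized directed influence of node *j* on node *i*
(`Σ_i π_ij(f)² = 1`). A **dual extended Kalman filter** tracks the
coefficients `A_r` at every sample — one filter estimates the lagged-signal
state, a second estimates the coefficients under a random-walk model, each
feeding the other — yielding the time-resolved tPDC tensor `π_ij(f, t)`.
Edge significance combines **window-shuffling surrogate thresholds**
(95th percentile of 100 refits on order-permuted 1-s windows) with a
**time-reversal test** (a genuinely lagged asymmetry inverts its sign when
the recording is played backwards; zero-lag volume-conduction mixing does
not).

Around that core the package provides the full chain: average
re-referencing, block trimming and epoching, the event-related
desynchronization index, Welch cross-spectra, DICS beamforming
(unit-gain spatial filters, power/coherence maps, pooled source signals,
segment-permutation significance), d′ scoring, rank-based group statistics
with effect sizes, brain–behavior correlation, and polynomial-kernel SVM
classification under repeated stratified cross-validation — plus a
synthetic-data generator that simulates two-group cohorts with known
directed source networks (dense long-range "control-like" vs sparse local
"contrast" profiles), forward projection through a toy spherical lead
field, signal-detection behaviour, and point-light walker / scramble
stimulus trajectories.

## Worked example

Simulate one subject's ground-truth mu-band network (5 sources, 10
directed edges, at least one long anterior–posterior connection), then
recover it blind from 30 s of source signal:

```r
library(tpdcnet)

prof <- group_network_profile("dense_longrange", n_nodes = 5, n_edges = 10)
net  <- make_group_network(prof, standard_band("mu"), rate = 250, seed = 7)
src  <- simulate_mvar(net, 7500, rate = 250, seed = 8)

res <- analyze_subject_connectivity(src, net$coords, standard_band("mu"),
                                    order = 2, n_boot = 40, seed = 9,
                                    trt = FALSE)
res$graph
#> <conn_graph> 5 nodes, 9/20 significant directed edges

res$graph$edges[res$graph$edges$significant,
                c("src", "dst", "strength", "threshold", "length_mm")]
#>    src dst strength threshold length_mm
#> 5    2   1     0.33      0.19        55
#> 6    2   3     0.29      0.24        55
#> 7    2   4     0.36      0.17        75
#> 8    2   5     0.33      0.18       119
#> 9    3   1     0.37      0.22        75
#> 11   3   4     0.42      0.19        55
#> 12   3   5     0.38      0.21        75
#> 16   4   5     0.61      0.35        55
#> 17   5   1     0.54      0.38       150

res$mean_directional_coherence
#> [1] 0.182
```

Each significant edge is a directed influence whose band-and-time-mean
tPDC (`strength`) exceeded its surrogate threshold; `length_mm` is the
Euclidean distance between the source coordinates (the 150-mm edge is the
long occipital-to-frontal connection). Against the generator's truth this
run recovers 9 of 10 edges with no false positives. The subject-level
mean directional coherence (0.182) divides the summed significant
strengths by the 20 possible directed connections; comparing it between
simulated dense and sparse cohorts (`simulate_cohort()`) reproduces the
expected group contrast under a Kruskal–Wallis test.

`run_pipeline(list(seed = 1))` chains the whole analysis — cohort
simulation, sensor projection, re-referencing, DICS source estimation,
tPDC with surrogate and time-reversal testing, group statistics, and SVM
classification — and returns a manifest with every derived seed, so a
config reproduces its run exactly.

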