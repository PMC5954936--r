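---
title: "Methods: source-space DTF connectivity and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space DTF connectivity and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfnet)
```

This vignette documents the models and estimators implemented in dtfnet,
the tunable parameters and their defaults, the numerical choices made where
several defensible options existed, what the synthetic-data generator does
and does not emulate, and the package's known limitations. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute.

## Pipeline overview

A recording travels through six stages: (1) sensor preprocessing, (2)
minimum-norm source imaging onto ROIs, (3) MVAR/DTF network estimation with
surrogate thresholding, (4) graph-theoretic summarization, (5) group
statistics, and (0) a synthetic-data module that generates every input with
known ground truth. `run_pipeline()` executes them in order from one
configuration with per-stage derived seeds, so reruns are byte-identical.

## Sensor preprocessing

**Band-pass filtering.** Zero-phase FIR, implemented as a Hamming-windowed
sinc band-pass built from two low-pass kernels with −6 dB points at the
band edges (default 0.5–30 Hz). The transition width is 25% of each cutoff
and the kernel length follows the Hamming rule (normalized transition
≈ 3.3/N), forced odd; the signal is reflection-padded and the group delay
compensated, so net phase is zero and length is preserved. With a 0.5 Hz
high-pass at 1 kHz this gives a ~26,000-tap kernel — applied by FFT
convolution, and demanding recordings longer than the group delay
(~13 s), which continuous EEG always satisfies.

**Downsampling** keeps every k-th sample (default 1000 → 100 Hz); the
30 Hz low-pass has already removed content above the new Nyquist.

**Epoching** cuts half-open windows `[−2000, +5000)` ms around each
trigger at 0-based sample indexing. Half-open windows make the early/late
interval split (`[−1000, +2000)` / `[+2000, +5000)` ms, 300 samples each
at 100 Hz) unambiguous: the +2000 ms boundary sample belongs to the late
interval only. Each epoch channel is mean-centred at extraction because
the downstream MVAR estimator assumes zero-mean series.

**Bad channels.** Electrode screening is traditionally done by visual inspection; a
reproducible surrogate flags channels whose robust z-score (median/MAD
across channels) of standard deviation or absolute linear drift slope
exceeds 5. The MAD denominator is unstable on very small montages; the
calibration target (no false flags in ≥ 95% of homogeneous-noise draws)
holds at the 64-channel montage size the pipeline is built for. A
user-supplied bad list is always unioned in, and the package never
auto-excludes subjects — it reports metrics and leaves exclusion to the
analyst.

**SOBI.** Second-order blind identification whitens the data (PCA reduced
to numerical rank) and approximately jointly diagonalizes the symmetrized
lagged covariances at lags 1..50 (at 100 Hz) by Jacobi sweeps with the
closed-form pairwise Givens angle; convergence is declared when every
rotation sine falls below 1e−8, and the off-diagonal criterion is
non-increasing across sweeps by construction of the angle. Component
rejection is user-driven (index list), matching practice where artifact
components are identified by inspection; reconstruction uses the retained
columns of the mixing matrix only.

**Spherical-spline interpolation** replaces bad channels with the
Legendre-series spline estimate from good channels: stiffness m = 4,
series truncation N = 50, ridge 1e−5 on the spline system — standard
published defaults. The constant term in the spline system makes a
spatially uniform field reproduce exactly, and the estimate is linear in
the data.

## Inverse solution

The minimum-norm objective ||m − Ld||² + λ||d||² is implemented as
plain (unweighted) MNE via the SVD filter-factor form; column-norm depth
weighting — the "weighted" variant — is available behind
`depth_weight = TRUE`, defaulting off so the default solver matches the
stated objective exactly.

λ is selected **once per epoch** on the epoch's full data block (the
cheapest defensible granularity; per-sample selection would be noisy and
expensive) from a 40-point grid log-spaced over [1e−6, 1e2] × mean squared
singular value of the lead field, making the grid scale-invariant. The
corner of the (log residual, log solution-norm) curve is located by the
discrete **triangle estimator** — the interior point at maximal
perpendicular distance from the chord joining the curve's endpoints.
Pointwise Menger curvature is computed as a diagnostic but not used for
selection: on log-spaced grids it concentrates on the steep
over-regularized limb and systematically overshoots the knee. Two
degenerate cases are handled explicitly: constant norms fall back to the
median grid value with a warning, and essentially noiseless data (residual
at the smallest grid λ below 1e−8 of the data norm — no noise floor, hence
no corner) short-circuit to the smallest interior grid value. Endpoints
are never selected.

ROI series are the arithmetic means of member dipoles' signed amplitudes;
signed averaging presumes consistently oriented dipoles, which the
synthetic geometry guarantees and real surface-normal source models
approximate. ROI membership is configuration, not derivation.

## MVAR and DTF

`fit_mvar()` solves the stacked multi-trial least-squares regression:
trials contribute independent equation blocks, so no lagged regressor ever
straddles a trial boundary. Order defaults to 8 at fs = 100 Hz, inside the
lag-bound rule (order < τ·fs for expected inter-areal lags τ ≈ 0.1 s);
`model_order_report()` profiles AIC/BIC and the lag bound as a decision
aid but never selects automatically — a single fixed order keeps all DTF
computations comparable. The Gram matrix condition is checked (refusal
above 1e12) and the residual covariance uses the regression denominator
n − k·p.

The transfer matrix H(f) = A(f)⁻¹ is evaluated on a 1 Hz grid from 1 to
fs/2 − 1 Hz, which resolves both analysis bands. Edge weights are the
**squared** DTF (the normalized form whose rows sum to one over sources),
averaged over alpha (8–12 Hz) or beta (13–30 Hz) grid points inclusive.
The diagonal is excluded from all network analysis. Internally the
storage convention is `[row = target, column = source]`; every text export
is labelled `source,target,weight` to preclude transposition ambiguity.

**Surrogate thresholding.** Each of the (default 1000; tests use 200)
surrogates independently phase-randomizes every channel of every trial —
FFT magnitudes kept, phases uniform, conjugate-symmetric — preserving
univariate spectra while destroying cross-channel causality, which is the
appropriate null for a directed cross-channel measure. The full
fit → transfer → DTF → band-average chain is recomputed per surrogate, and
an edge is retained iff its observed band weight exceeds the empirical
(1 − α) surrogate quantile. Thresholding is per band-aggregated edge (not
per frequency bin), since all downstream graphs are band-level.

## Graph metrics

- **Strengths**: IS/OS are weighted in/out sums; their totals are equal by
  construction.
- **Clustering**: the default honours the classic binary formula
  C_i = 2t_i/(k_i(k_i−1)) on the OR-symmetrized binarized graph, with
  C_i = 0 for degree < 2; a directed-weighted (cube-root, Fagiolo-style)
  variant is available because connectivity toolboxes commonly compute
  that instead — which of the two a given published table used is often
  undecidable, so the choice is an explicit, logged configuration field.
- **Path lengths**: weights in (0, 1] map to lengths by −ln w (the natural
  logarithmic conversion for DTF² weights: products of weights along a
  path become sums of lengths, and lengths are nonnegative); a reciprocal
  map is available behind a flag. All-pairs shortest directed paths by
  Floyd–Warshall. The nodal mean L_i averages the finite distances *from*
  node i; unreachable ordered pairs are excluded from the average (the
  metric is defined over connected pairs) and their count is always
  reported so the exclusion is visible. Binary graphs automatically use
  unit hop lengths, since −ln 1 = 0 would degenerate every distance.
- **Small-worldness**: SW = (CC/CC_rand)/(CPL/CPL_rand) against random
  directed graphs with identical node and edge counts, drawn uniformly
  without replacement over ordered off-diagonal pairs. One SW value is
  computed per null draw and the draws averaged (default 10,000 in the
  full profile; tests use 100–200). The weighted original is compared
  against binary (unit-length) nulls exactly as each is computed — an
  asymmetry inherent in the standard definition, documented here.
  Degenerate null draws (zero clustering) are dropped and counted rather
  than divided by.

## Group statistics

Edge-wise comparison (`nbs_fdr()`) uses pooled-variance two-sample t
statistics per off-diagonal edge, a permutation null from full random
relabelling with the observed labelling included in the count
(p = (1 + #{|t⋆| ≥ |t|})/(B + 1), the exact-test convention), and
Benjamini–Hochberg FDR across edges. Note the p-value floor 1/(B + 1)
interacts with BH: resolving k true edges among E edges at level α
requires B ≳ E/(kα) permutations — with 552 edges and α = 0.05, the
50,000-permutation full profile resolves single edges comfortably, while
the 2,000-permutation test profile is adequate for ≤ 30-edge networks.
Zero-variance edges get p = 1 with a note. Scalar properties are compared
through a Shapiro–Wilk gate (both samples pass at 0.05 → t-test, else
Mann–Whitney/Wilcoxon); Kolmogorov–Smirnov is computed and logged but does
not branch — one deterministic rule. Identical paired samples return the
maximal p directly. Between-interval contrasts are supported either on
raw values or on early–late difference scores via a configuration switch,
defaulting to difference scores. Strength-trend correlations choose
Pearson vs Spearman by the same normality gate.

## The synthetic-data generator

The generator emulates the study geometry: 64-channel recordings at
100 Hz (after nominal 1 kHz acquisition), epochs of −2000..+5000 ms, 24
ROI source processes, a 34-stimulus × 9-repetition schedule in 3 blocks
with 5 s videos and 4 s rests, and two-group cohorts. Specifics:

- **Self-dynamics**: each node is a damped resonator (AR(2) pole pair,
  default 10 Hz at pole radius 0.8) so sources have alpha-band content;
  couplings are drawn uniform ±[0.1, 0.5] at a random lag on randomly
  chosen ordered pairs, then everything is shrunk by factors of 0.95
  until the companion spectral radius is below 0.95. Simple,
  reproducible, detectable.
- **Burn-in**: 10·order·n_nodes samples discarded per trial.
- **SNR**: total signal power over total noise power across sensors, in
  dB — one unambiguous knob.
- **ROI expansion**: ROI series are copied to member dipoles with a fixed
  ±5% gain jitter, mimicking coherent cortical patches without a mesh.
- **Lead field**: a random sensors × dipoles matrix whose within-ROI
  columns share a common pattern with correlation `smoothness` (default
  0.9). This is a *statistical* stand-in — labelled synthetic — not a
  head model; it reproduces the rank structure and ROI coherence that
  matter for inverse-recovery testing, not volume-conduction physics.
- **Cohorts**: per-subject copies of the base system with Gaussian jitter
  (SD 0.02) on nonzero coefficients; group B additionally shifts planted
  edges' lag-1 coefficients. The jitter SD is a free parameter of the
  artifact, not an estimate of any study's between-subject variance —
  no published quantity constrains it.

Consequently, passing tests demonstrate correctness of the estimators and
pipeline plumbing under a favourable, well-specified generative model;
they do not demonstrate robustness to real-EEG phenomena (non-stationarity,
1/f background, volume-conduction leakage patterns, correlated muscle and
ocular artifacts beyond the planted kinds).

## Verification benchmarks and their design

Two benchmark choices deserve explanation:

**Exact support recovery** uses a deterministic 5-node system (chain
1→2→3→4→5 plus feedback 3→2; 11 of 20 ordered pairs communicate). DTF
measures direct *and* cascaded flow, so the target is
retain-all-communicating / reject-all-non-communicating. With 9
non-communicating pairs, an edge-wise level of 0.05 would leave ≈ 0.45
expected false edges per dataset, making exact recovery fail in roughly a
third of datasets regardless of data quantity — so the benchmark
thresholds at the smallest level resolvable with its 200 surrogates
(observed weight above every surrogate draw, α = 1/201 ≈ 0.005). The
study-level pipeline keeps α = 0.05.

**NBS power** uses a 10-node resonator-only base with 5 planted edges on
disjoint source/target pairs. The disjointness is essential: planted
effects on a connected base propagate through cascades and DTF row
normalization into *real* secondary group differences, which the edge test
then correctly flags — indistinguishable, for scoring purposes, from
false positives. With disjoint planted pairs the planted edges are the
only systematic differences, giving a clean count of hits and extras. The
coefficient shift (+0.2) yields band-weight shifts an order of magnitude
above the within-group SD, comfortably past the ≥ 1.5 SD regime the power
check targets.

Simulation scales in the shipped tests and acceptance script — e.g. 10
trials × 2000 samples for the benchmark, 5 × 500 for the 24-channel
type-I calibration, 200 surrogates, 2000 permutations, 200 small-world
nulls, 1000 small-graph oracle comparisons — are the package's chosen
verification sizes; the full analysis profile (1000 surrogates, 10,000
nulls, 50,000 permutations) is available via `default_config("full")`.

## Known limitations

- The lead field is statistical; localization accuracy against real head
  geometry is out of scope, and the consumed lead field is never computed
  from anatomy.
- λ per epoch is an assumption; per-subject or global selection would be
  legitimate alternatives and can be emulated by passing a fixed λ.
- DTF is estimated stationarily per interval; time-varying estimators are
  not implemented.
- The surrogate and permutation procedures are embarrassingly parallel
  but implemented serially; the full profile is compute-heavy by design.
- EDF support covers the common 16-bit, uniform-rate case; EDF+
  annotations are not parsed.
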