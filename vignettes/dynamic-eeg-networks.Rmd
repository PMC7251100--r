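---
title: "Dynamic EEG networks for seizure detection: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic EEG networks for seizure detection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seizr)
```

`seizr` detects epileptic seizure onsets from multichannel scalp EEG by
tracking the algebraic connectivity of a time-varying functional network.
This vignette documents the two inference models, every parameter that
matters, the synthetic data that the validation relies on, and the places
where the design was genuinely open — with the choices made and why.

## The detection principle

A seizure onset is widespread, band-limited, phase-locked activity across
electrodes. Treating the electrode array as a weighted graph, such activity
raises *every* edge weight, and with it the Fiedler eigenvalue λ₂ of the
graph Laplacian `L = D − A` — the algebraic connectivity, which is zero for
a disconnected graph, equals `n·w` for a complete graph of uniform weight
`w`, and is upper-bounded by what a *cut* of the graph can carry. That last
property is the artifact-rejection mechanism: a high-power transient on `m`
of `n` electrodes can at most add `m` strong "hub" vertices, bounding its
λ₂ contribution by about `m` regardless of amplitude, while a genuine
seizure pushes λ₂ toward `n`. With `n = 23` and `m = 2` the margin is an
order of magnitude. Detection is then a fixed threshold θ on λ₂, held for a
decision time before an event is declared.

## The spectral route

Per window (default 1 s, non-overlapping; the method is intended for
0.25–1 s epochs), each channel's one-sided DFT is taken with a rectangular
window and no zero padding — `p = |X|` (raw DFT moduli), phases
`φ = Arg X`, frequency resolution `1/w` Hz. Magnitudes outside the analysis
band (default 2–10 Hz, edges inclusive) are zeroed. The stage is validated
against Parseval's identity: the weighted one-sided energy
`Σ w_n p_n² / M` equals `Σ x²` to machine precision.

Band power is `P_i = Σ_n p[i, n]²` over in-band bins. The phrase "squared
power spectrum" is ambiguous between `Σ|X|²` and `Σ|X|⁴`; the default
`power_def = "magnitude"` takes `p = |X|` so that `P` is the window's band
*energy* (amplitude-squared scaling), which matches the route's motivating
RMS-power analogy; `power_def = "periodogram"` provides the
amplitude-to-the-fourth alternative.

The pairwise coefficients are `σᵖ_ij = P_i + P_j` and
`σᵠ_ij = (1/N) Σ_n sin(φ_jn − φ_in)` over the `N` in-band bins. `σᵠ`
behaves like a phase-lag index: zero for identical phase profiles,
antisymmetric, `|σᵠ| ≤ 1`. Their product `d_ij` feeds the adjacency map
`a_ij = 1 − exp(−|d_ij|^γ)`; the absolute value makes `A` symmetric even
though `σᵠ` is antisymmetric.

**γ (default 2).** The exponent sets how sharply small couplings are
squashed: for `|d| < 1`, `a ≈ |d|^γ`, so larger γ suppresses background
chatter; but since couplings during a seizure are far above 1 anyway,
γ ≳ 3 mostly shrinks legitimate mid-range values and costs sensitivity.

Two degenerate regimes are worth knowing. *Zero lag:* perfectly
phase-aligned channels (e.g. exact copies) give `σᵠ ≡ 0` and hence
`λ₂ ≡ 0` — the route is deliberately lag-sensitive, and a hypothetical
perfectly zero-lag seizure is a blind spot (in practice independent channel
noise breaks exact alignment). *Saturation:* `1 − exp(−|d|²)` is
numerically exactly 1.0 once `|d|² > ~745`; the invariant `a < 1` is open
mathematically but closed in double precision. Both are documented rather
than "fixed".

**Input scaling.** The route runs on raw (unfiltered) data scaled to
`[−1, 1]`; band restriction inside the method makes broadband prefiltering
redundant. Scaling is per channel by the channel's own maximum absolute
value over the whole recording (a global-maximum option exists). Per-channel
scaling keeps low-amplitude channels informative, and it means the largest
artifact on each channel sets that channel's scale — which is precisely
what keeps resting-state couplings inside the sensitive part of the
adjacency map in long recordings (see the generator section).

**Threshold calibration.** The published procedure fixes θ per patient by
visual inspection. `calibrate_threshold()` automates its spirit as
`θ = mean + k·sd` (default `k = 6`) over a seizure-free stretch of the λ₂
series — *including* unlabeled artifact windows, since no oracle removes
them in practice; their presence inflates the spread slightly and thus adds
a safety margin. A trailing moving-average variant (`moving_threshold()`)
is provided for recordings with slow drift. The 6-s decision time provides
a second, independent artifact defense: transients shorter than 6 s can
never confirm, whatever their λ₂.

**Detector conventions.** The event onset is reported at the *first
threshold crossing* (window start of the first super-threshold window), so
the measured delay `d` excludes the decision time and the latency is
`L = d + 6 s` by construction. Runs are confirmed first (span ≥ decision
time), then events closer than `min_gap` (default 10 s) merge. The
monotonicity "raising θ never increases TP or FP" holds for unimodal
excursions with `min_gap = 0` (nested super-level sets); an excursion that
dips between two thresholds can split, and merging can consolidate
differently — the property is tested under the conditions where it is a
theorem.

**Evaluation.** A detection is a true positive if its onset falls within
`[annotated onset − 10 s, annotated offset]`; the pre-onset tolerance is
required because network features regularly fire a few seconds before the
visually marked onset (published per-patient mean delays go down to −6 s).
Extra detections inside one seizure collapse to a single TP; detections
after the offset are false positives, counted per merged event.
`aggregate_reports()` implements both published conventions for pooling
per-patient rows: the unweighted mean across patients, and the TP-weighted
mean (equivalently, averaging over matched seizures). The bundled benchmark
tables print per-patient mean latencies floored at zero, so the TP-weighted
mean of printed latencies (4.44 s) is not the printed mean delay (−1.68 s)
plus 6; both modes are exposed and labeled rather than reconciled. The
TP-weighted mean of the printed, 2-decimal delay column is −1.6853, which
differs from the printed mean by half a unit in the last digit — the
aggregation evidently ran on unrounded values; recomputations are asserted
to one unit in the last printed digit.

## The coupling-function route

Each channel's dynamics is modeled as

$$\dot x_i = \sum_k a_k Q_k(x_i) + \sum_{j \ne i}\sum_{k,\ell}
  b_{ij}^{k\ell} P_k(x_i) P_\ell(x_j),$$

with `Q = P` the truncated trigonometric set
`{1, sin 2πu, cos 2πu, sin 4πu, cos 4πu}` (`r = 5`) on a unit domain. The
domain map is `u = (x+1)/2` for `[−1, 1]` amplitude signals and
`u = x/2π` for oscillator phases — the basis is 1-periodic in `u`, so
unwrapped phases need no wrapping and their derivatives stay smooth.
Derivatives are estimated by central differences (one-sided at recording
ends; when windowing, channels are differentiated before segmentation so
windows incur no edge error). Per channel, the coefficients solve
`min_z ‖y − A z‖` by SVD (minimum-norm), with optional Tikhonov ridge; a
numerically rank-deficient design escalates the ridge to
`1e−8 · trace(AᵀA)/C` with a warning. The per-channel problems share no
state, so any execution order gives bit-identical results.

**Identifiability.** The complete 2-D layout has
`C = r + r²(N−1)` columns. Because the first basis term is the constant,
every pair block's `ℓ = 1` columns `P_k(x_i)·1` *exactly duplicate* the
self block — the design is structurally rank-deficient, and a minimum-norm
(or ridge) solve spreads each self coefficient uniformly over its copies,
leaking e.g. an oscillator's natural frequency into every coupling strength.
(The source literature itself wavers between `r²N + 1` and `r + r²(N−1)`
for this dimension, which is a symptom of the same ambiguity.) The package's
resolution: terms that do not depend on the source channel are
self-dynamics *by definition*, so `infer_network()` solves on the reduced
design that omits `ℓ = 1` pair columns (`C = r + r(r−1)(N−1)`), reporting
zeros for the omitted coordinates. `build_design()` retains the complete
layout as the documented default contract. Exact recovery — coefficients
reproduced to 1e−6 from noiseless data with exact derivatives — is
accordingly stated on the identifiable coefficient set.

The directed strength is `α_ij = √(Σ_{kℓ} (b_ij^{kℓ})²)`, a Parseval-style
RMS power of the inferred interaction function; `α_ij ≠ α_ji` in general.
For eigen-analysis the strength matrix is symmetrized, `W = (J + Jᵀ)/2`,
since a Fiedler eigenvalue needs a symmetric Laplacian; whether the
original procedure symmetrizes is unstated, and the average is the neutral
choice. λ₂ is smoothed with an exponential moving average
(`β = 0.2` by default; `β = 1` is the identity, a constant series is a
fixed point, and the output is bounded by the running min and max). The
inference window defaults to 10 s (the workable range is 10–20 s at
256 Hz): the sample count `M` must comfortably exceed `C`
(`M = 2560` vs `C = 465` reduced, for `r = 5`, `N = 23`).

## What the synthetic generator emulates — and what it does not

The generator is the package's study conditions, not a tuning knob; its
defaults are fixed and everything below was set from the physics of the
method before the validation suite was frozen.

Per channel the background is 20 µV RMS pink noise (power slope −1), a
14 µV incoherent 3–9 Hz component (scalp EEG at rest carries substantial
theta/alpha power; this term sets the resting variability of the network),
and a weak 5 µV 10 Hz rhythm with i.i.d. phases. Seizures are coherent
`f₀ = 6 Hz` oscillations at 10× the background RMS with per-channel phase
lags `π/4 · i/n` and 1 s raised-cosine ramps; the lag profile makes `σᵠ`
large (zero lag is kept available as the documented adversarial case).
Artifacts are 3 s, 2-channel, incoherent 2–10 Hz bursts at 35× the
background RMS — mV-scale electrode pops, placed *in band* deliberately so
that their summed band power exceeds the seizure level (an out-of-band
artifact would be rejected trivially by the band restriction rather than by
the network). Artifact channel pairs cycle through a seed-shuffled
electrode order so that over a session every electrode is hit at least
once, as in real long-term recordings; this also keeps the per-channel
normalization scale comparable across channels, which places resting
couplings in the unsaturated part of `a = 1 − exp(−|d|²)` (baseline
λ₂ ≈ 5 ± 0.8, θ(k = 6) ≈ 10, artifact λ₂ ≤ baseline + 2, seizure
λ₂ ≈ 20–23 on the standard one-hour suite).

All generators are pure functions of (config, seed); the caller's RNG
state is restored. The oscillator simulator integrates
`ẋ_i = ω_i + Σ_j K_ij sin(x_j − x_i)` by fixed-step RK4 (step 2 ms,
validated against the isolated-rotation and two-node phase-locking closed
forms) with optional per-step Gaussian phase noise. The benchmark network
has 6 nodes, natural frequencies spread over `2π·[0.5, 1.6]` rad/s — wide
enough that moderate coupling does not phase-lock the system, because a
locked pair's coupling term is constant and indistinguishable from
self-dynamics — 8 random directed edges with `K ~ U(0.4, 0.7)`, phase noise
0.1 rad/√s, 80 s runs, 40 s inference windows.

What the generator does *not* emulate: physiological EEG morphology
(spikes, sharp waves, evolving seizure frequency), amplitude-depression
seizure onsets (the spectral route cannot detect suppressed-amplitude
onsets at all — it watches for λ₂ rising, not falling), channel-specific
artifact morphologies (eye blinks, chewing), nonstationary background, or
volume-conduction correlations between electrodes. Passing the synthetic
suite therefore demonstrates the *mechanism* — coherent in-band power
raises λ₂, confined incoherent power does not — not clinical performance;
the published per-patient numbers come from a full clinical corpus that is
out of desk-scale reach, and the package reproduces their aggregation
arithmetic exactly rather than their pipeline provenance.

## Numerical choices

* Rectangular FFT window, no detrending beyond preprocessing, inclusive
  band edges, resolution `1/w` Hz; band power is not normalized by window
  length (thresholds are calibrated per recording, so a constant factor is
  immaterial).
* Dense symmetric eigensolver for L (`n = 23` makes cost negligible);
  eigenvalues in `(−1e−12, 0)` are clamped to 0; the eigenratio is defined
  as 0 when `λ_n = 0`. The solver is cross-checked against the general
  (non-symmetric) eigensolver path on random graphs to 1e−9.
* Zero-phase band-pass: 4th-order Butterworth run forward–backward
  (1–50 Hz default). This is maximally flat but not perfectly so:
  re-filtering changes mid-band tones by ~4e−4 relative and band-edge
  content substantially, so "idempotence" holds exactly only for the
  demean/re-reference stages.
* EDF I/O is 16-bit with per-channel physical calibration; the writer
  recomputes its gains from the truncated 8-character header fields so the
  round trip is bounded by one digitization step. CSV round trips are exact
  to printed precision.
* Windows use 0-based half-open sample ranges; `t_k` is the window *end*
  time, and event onsets are reported at the window *start* of the first
  crossing so that `onset = t_k − hop`.

## Validation problem sizes

The test suite and acceptance script use: the one-hour 23-channel suite
(10 seizures, 20 artifacts; 3600 windows) for detection, with the artifact
rejection property evaluated over 100 transients across 5 seeds; 100
random weighted graphs (n ≤ 23) against the eigendecomposition oracle; 30
random frames against a naive double-loop implementation of the coupling
algebra (1e−12); 20 random windows for Parseval (1e−6); 20 seeded 6-node
oscillator networks for topology ROC AUC and 5 seeds × 3 gains for the
synchronizability monotonicity. These sizes exercise every claimed property
while keeping a full run in minutes on one CPU.

## Known limitations

* Amplitude-depression onsets are undetectable by design in the spectral
  route; use the coupling-function route (which watches topology, not
  power) where such morphologies matter.
* The spectral route's phase coupling vanishes for exactly zero-lag
  synchronization.
* λ₂ saturates at `n` once all pairwise couplings saturate, so severity
  beyond "fully synchronized" is not graded.
* The coupling-function route assumes the dynamics are expressible in a
  low-order trigonometric basis on a bounded domain; strongly phase-locked
  regimes make couplings unidentifiable from self-dynamics (a physics
  limit, not an implementation one).
* Threshold calibration assumes a seizure-free baseline stretch is
  available and representative.
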