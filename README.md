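# seizr

Dynamic EEG connectivity networks and seizure onset detection in R.

Epileptic seizures appear in scalp EEG as episodes of abnormally synchronous
activity across electrodes, typically in a low-frequency band (e.g. the
4–8 Hz theta band). Rather than thresholding the power of individual
channels — which is easily fooled by movement and electrode artifacts —
`seizr` treats the electrode array as a **time-varying weighted graph** and
tracks its *algebraic connectivity*: the Fiedler eigenvalue λ₂ of the graph
Laplacian, which is zero for a disconnected graph and grows with global
synchronization. A high-power transient confined to two electrodes can light
up a few edges, but it cannot raise the connectivity of the whole 23-vertex
graph; widespread coherent oscillations can. Thresholding λ₂ therefore
detects seizures while rejecting artifacts.

Two network-inference routes are provided:

**Spectral route** (fast; sub-second windows). For each non-overlapping
window the one-sided FFT gives per-channel magnitudes `p[i, n]` and phases
`φ[i, n]`, restricted to a band (default 2–10 Hz). With band power
`P_i = Σ_n p[i, n]²`:

```
σᵖ_ij = P_i + P_j                      (power coupling, symmetric)
σᵠ_ij = (1/N) Σ_n sin(φ_jn − φ_in)     (phase-lag coupling, antisymmetric)
d_ij  = σᵖ_ij σᵠ_ij,   d_ii = 0
a_ij  = 1 − exp(−|d_ij|^γ)             (γ = 2)
L     = D − A,  D = diag(rowSums(A))
```

and λ₂(L) per window is the detection feature. A seizure is declared when
λ₂ stays above a per-recording threshold θ for a 6-second decision time.

**Coupling-function route** (windows of 10 s and up). Each channel's
dynamics is modeled as self-dynamics plus pairwise coupling functions
expanded in a 2-D trigonometric basis (5 terms per dimension),

```
ẋ_i = Σ_k a_k Q_k(x_i) + Σ_{j≠i} Σ_{k,ℓ} b_ij^{kℓ} P_k(x_i) P_ℓ(x_j),
```

estimated per channel (independently, hence trivially parallel) by linear
least squares on the signal's time derivative. The directed coupling
strength is α_ij = √(Σ_{kℓ} (b_ij^{kℓ})²); the symmetrized strength matrix
yields λ₂, smoothed by an exponential moving average.

The package also ships event-level evaluation (sensitivity, false positives
per hour, per-seizure delay `d` and latency `L = d + 6 s`), EDF/CSV signal
I/O with CHB-MIT-style annotation parsing, and seeded synthetic generators
(background EEG with planted seizures and artifacts; coupled oscillator
networks with known topology) so the full pipeline is testable without any
external data.

## Worked example

Generate the standard synthetic study conditions — one hour of 23-channel,
256 Hz EEG with 10 planted seizures (coherent 6 Hz oscillations with fixed
inter-channel phase lags) and 20 two-channel artifact transients — then run
the spectral detector end to end:

```r
library(seizr)

gen <- gen_recording(synth_suite_config(seed = 1))
rec <- gen$recording
rec
#> <eeg_recording> 23 channels x 921600 samples (3600 s @ 256 Hz)
#>   10 annotated seizure interval(s)

ser <- lambda2_series(rec, window = 1, band = c(2, 10), gamma = 2)

baseline <- !logical(nrow(ser))
for (s in seq_len(nrow(rec$annotations))) {
  baseline <- baseline & !(ser$time_s > rec$annotations$onset[s] - 1 &
                           ser$time_s <= rec$annotations$offset[s] + 1)
}
theta <- calibrate_threshold(ser$lambda2[baseline], k = 6)
round(theta, 2)
#> [1] 9.86

cfg <- detector_config(threshold = theta, decision_time = 6)
events <- threshold_detect(ser, cfg)
report <- evaluate_detections(events, rec$annotations,
                              rec_duration(rec) / 3600, cfg)
report
#> <detection_report> NS = 10, TP = 10, FP = 0 | S = 100.00%, FP/h = 0
#>   mean delay 0.00 s, mean latency 6.00 s over 10 matched seizure(s)
```

All 10 planted seizures are found (λ₂ ≈ 20 during seizures against a
baseline near 5), none of the 20 artifacts triggers a false alarm even
though their summed band power exceeds the seizure level, the delay to the
annotated onset is 0 s, and the latency is exactly the 6 s decision time.
`autoplot(ser, threshold = theta, annotations = rec$annotations)` draws the
λ₂ trace with the threshold and the planted intervals.

The bundled published benchmark tables reproduce their printed summary
rows through the same aggregation code:

```r
aggregate_reports(chb_ft_table(), mode = "unweighted")[
  , c("n_seizures", "tp", "fp", "sensitivity_pct", "mean_latency_s", "mean_delay_s")]
#> # A tibble: 1 × 6
#>   n_seizures    tp    fp sensitivity_pct mean_latency_s mean_delay_s
#>        <int> <int> <int>           <dbl>          <dbl>        <dbl>
#> 1         94    88    99            93.6           16.1         10.1
```

A thin command-line interface wraps the same functions
(`system.file("cli", "seizr.R", package = "seizr")`) with subcommands
`simulate`, `detect`, `evaluate` and `spectrum`.

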