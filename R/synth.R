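#' Synthetic-recording configuration
#'
#' Describes a seeded synthetic multichannel EEG session: pink-noise
#' background with a weak posterior-rhythm component, plus planted seizure
#' episodes (coherent band-limited oscillations with fixed nonzero
#' inter-channel phase lags and elevated power) and artifact episodes
#' (high-power incoherent transients confined to a small channel subset).
#' All amplitudes are in microvolts.
#'
#' Defaults emulate an hour-scale scalp-EEG session: 23 channels at 256 Hz,
#' 20 uV RMS background with spectral slope -1, a 5 uV 10 Hz rhythm,
#' a 14 uV
#' incoherent 3-9 Hz component, seizures as 6 Hz oscillations at 10x the
#' background RMS with per-channel lags `pi/4 * i/n`, and artifacts as
#' 2-10 Hz incoherent bursts at 35x the background RMS (mV-scale electrode
#' pops) on 2 channels each. Artifact channel pairs cycle through a
#' seed-shuffled electrode order, so over a session every electrode carries
#' at least one artifact — mirroring long recordings in which every channel
#' pops at some point and keeping the per-channel amplitude normalization
#' comparable across channels.
#'
#' @param n_channels number of channels (default 23).
#' @param fs sampling rate in Hz (default 256).
#' @param duration recording length in seconds.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @param background_rms broadband background RMS amplitude (uV).
#' @param background_slope spectral power slope (default -1, pink).
#' @param background_band_rms RMS (uV) of the incoherent theta/alpha-range
#'   background component (independent band-limited noise per channel);
#'   scalp EEG at rest carries substantial power in this range, and this
#'   component sets the resting variability of the synchronization network.
#' @param background_band frequency band of that component (Hz).
#' @param rhythm_freq,rhythm_rms frequency (Hz) and RMS (uV) of the
#'   background rhythm (i.i.d. phase per channel).
#' @param seizures tibble with columns `onset`, `offset` (s) and optionally
#'   `f0` (Hz), `gain` (amplitude as a multiple of `background_rms`);
#'   `NULL` for none.
#' @param seizure_f0,seizure_gain defaults for missing seizure columns.
#' @param seizure_lag_scale per-channel phase lag of the seizure oscillation
#'   is `lag_scale * i / n_channels` radians (default `pi/4`); 0 is the
#'   documented adversarial zero-lag case that the phase-coupling route is
#'   blind to.
#' @param artifacts tibble with `onset`, `offset` (s) and optionally `gain`;
#'   `NULL` for none.
#' @param artifact_gain artifact RMS as a multiple of `background_rms`.
#' @param artifact_channels channels affected per artifact event (default 2).
#' @param artifact_band frequency band of artifact energy (Hz).
#' @param ramp raised-cosine on/off ramp for planted episodes (s).
#' @return a `synth_config` object.
#' @export
synth_config <- function(n_channels = 23, fs = 256, duration = 600, seed = 1,
                         background_rms = 20, background_slope = -1,
                         background_band_rms = 14, background_band = c(3, 9),
                         rhythm_freq = 10, rhythm_rms = 5,
                         seizures = NULL, seizure_f0 = 6, seizure_gain = 10,
                         seizure_lag_scale = pi / 4,
                         artifacts = NULL, artifact_gain = 35,
                         artifact_channels = 2, artifact_band = c(2, 10),
                         ramp = 1) {
  assert_scalar_number(duration, "duration", positive = TRUE)
  assert_scalar_number(fs, "fs", positive = TRUE)
  fix_intervals <- function(tbl, defaults) {
    if (is.null(tbl)) return(tibble::tibble(onset = numeric(), offset = numeric()))
    tbl <- tibble::as_tibble(tbl)
    if (any(tbl$onset < 0) || any(tbl$offset > duration)) {
      stop_seizr("planted intervals must lie inside the recording")
    }
    if (any(tbl$offset <= tbl$onset)) stop_seizr("interval offset must exceed onset")
    for (nm in names(defaults)) {
      if (!nm %in% names(tbl)) tbl[[nm]] <- defaults[[nm]]
    }
    tbl
  }
  structure(
    list(
      n_channels = n_channels, fs = fs, duration = duration, seed = seed,
      background_rms = background_rms, background_slope = background_slope,
      background_band_rms = background_band_rms, background_band = background_band,
      rhythm_freq = rhythm_freq, rhythm_rms = rhythm_rms,
      seizures = fix_intervals(seizures, list(f0 = seizure_f0, gain = seizure_gain)),
      seizure_lag_scale = seizure_lag_scale,
      artifacts = fix_intervals(artifacts, list(gain = artifact_gain)),
      artifact_channels = artifact_channels, artifact_band = artifact_band,
      ramp = ramp
    ),
    class = "synth_config"
  )
}

#' Standard synthetic evaluation suite
#'
#' The fixed study conditions used throughout the package's validation: a
#' one-hour, 23-channel, 256 Hz session with 10 planted seizures (20 s each,
#' 360 s apart) and 20 artifacts (3 s each, 180 s apart, jittered by a few
#' seconds), under the [synth_config()] defaults.
#'
#' @param seed integer seed.
#' @param duration total length in seconds (default 3600).
#' @param n_seizures,n_artifacts episode counts.
#' @return a `synth_config`.
#' @export
synth_suite_config <- function(seed = 1, duration = 3600, n_seizures = 10,
                               n_artifacts = 20) {
  with_seed(seed + 1000L, {
    seiz_spacing <- duration / n_seizures
    seiz_on <- (seq_len(n_seizures) - 1) * seiz_spacing + 150 %% seiz_spacing
    art_spacing <- duration / n_artifacts
    art_on <- (seq_len(n_artifacts) - 1) * art_spacing + 60 %% art_spacing +
      stats::runif(n_artifacts, -5, 5)
    synth_config(
      duration = duration, seed = seed,
      seizures = tibble::tibble(onset = seiz_on, offset = seiz_on + 20),
      artifacts = tibble::tibble(onset = art_on, offset = art_on + 3)
    )
  })
}

pink_noise <- function(n, fs, slope, rms) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]          # mirror to two-sided grid
  h <- numeric(n)
  nz <- f > 0
  h[nz] <- f[nz]^(slope / 2)
  x <- Re(stats::fft(X * h, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

bandlimited_noise <- function(n, fs, band, rms) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[f < band[[1]] | f > band[[2]]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  if (stats::sd(x) == 0) return(numeric(n))
  x * rms / stats::sd(x)
}

episode_envelope <- function(t, onset, offset, ramp) {
  env <- numeric(length(t))
  inside <- t >= onset & t <= offset
  env[inside] <- 1
  if (ramp > 0) {
    up <- t >= onset & t < onset + ramp
    env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp))
    down <- t > offset - ramp & t <= offset
    env[down] <- 0.5 * (1 - cos(pi * (offset - t[down]) / ramp))
  }
  env
}

#' Generate a synthetic recording with ground truth
#'
#' Renders a [synth_config()] into an `eeg_recording` (annotated with the
#' planted seizure intervals) plus a ground-truth list. Deterministic for a
#' fixed seed: calling twice with the same config gives bit-identical
#' output.
#'
#' @param config a `synth_config`.
#' @return list with elements `recording` (an `eeg_recording`) and `truth`
#'   (list with `seizures` and `artifacts` tibbles; the artifact table
#'   gains a `channels` list column naming the affected channels).
#' @export
gen_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- as.integer(round(config$duration * config$fs))
    t <- seq(0, n - 1) / config$fs
    nc <- config$n_channels
    data <- matrix(0, nrow = nc, ncol = n)
    for (i in seq_len(nc)) {
      data[i, ] <- pink_noise(n, config$fs, config$background_slope,
                              config$background_rms) +
        bandlimited_noise(n, config$fs, config$background_band,
                          config$background_band_rms) +
        sqrt(2) * config$rhythm_rms *
          sin(2 * pi * config$rhythm_freq * t + stats::runif(1, 0, 2 * pi))
    }

    lags <- config$seizure_lag_scale * seq_len(nc) / nc
    for (s in seq_len(nrow(config$seizures))) {
      sz <- config$seizures[s, ]
      env <- episode_envelope(t, sz$onset, sz$offset, config$ramp)
      idx <- which(env > 0)
      if (length(idx) == 0) next
      amp <- sz$gain * config$background_rms
      for (i in seq_len(nc)) {
        data[i, idx] <- data[i, idx] +
          amp * env[idx] * sin(2 * pi * sz$f0 * (t[idx] - sz$onset) + lags[[i]])
      }
    }

    art <- config$artifacts
    art_channels <- vector("list", nrow(art))
    if (nrow(art) > 0) {
      # cycle a shuffled electrode order so artifacts visit every channel
      order_pool <- rep(sample(nc), length.out = nrow(art) * config$artifact_channels)
      for (s in seq_len(nrow(art))) {
        chans <- order_pool[((s - 1) * config$artifact_channels + 1):
                            (s * config$artifact_channels)]
        art_channels[[s]] <- sort(chans)
        env <- episode_envelope(t, art$onset[[s]], art$offset[[s]],
                                min(config$ramp, 0.25))
        idx <- which(env > 0)
        if (length(idx) == 0) next
        for (ch in chans) {
          burst <- bandlimited_noise(length(idx), config$fs,
                                     config$artifact_band,
                                     art$gain[[s]] * config$background_rms)
          data[ch, idx] <- data[ch, idx] + env[idx] * burst
        }
      }
    }
    art$channels <- art_channels

    rec <- new_recording(
      data, fs = config$fs,
      annotations = config$seizures[, c("onset", "offset")]
    )
    list(
      recording = rec,
      truth = list(seizures = config$seizures, artifacts = art,
                   config = config)
    )
  })
}

#' Coupled-oscillator network specification
#'
#' A network of `n` phase oscillators
#' \deqn{\dot x_i = \omega_i + \sum_{j \ne i} K_{ij} \sin(x_j - x_i)}
#' with directed, weighted adjacency `K` (`K[i, j]` couples source `j` into
#' target `i`), integrated by fixed-step 4th-order Runge-Kutta with optional
#' additive Gaussian noise per step. The pairwise sine coupling lies exactly
#' in the span of the `r = 5` trigonometric basis on the phase domain, so
#' these systems provide a ground-truth benchmark for [infer_network()].
#'
#' @param n number of oscillators (ignored when `omega`/`K` are given).
#' @param omega natural frequencies in rad/s (default spread over
#'   `[2 pi 0.5, 2 pi 1.6]` — wide enough that moderate coupling does not
#'   phase-lock the network, keeping the coupling functions identifiable).
#' @param K directed coupling matrix with zero diagonal.
#' @param step integration step in seconds; must satisfy
#'   `step <= 1 / (10 * max(omega))`.
#' @param fs_out output sampling rate in Hz (an integer number of steps per
#'   output sample).
#' @param noise_sd standard deviation of the Brownian phase noise
#'   (rad / sqrt(s)); per integration step the increment has sd
#'   `noise_sd * sqrt(step)`.
#' @param seed integer seed (initial phases and noise).
#' @return an `oscillator_spec`.
#' @export
oscillator_spec <- function(n = 6, omega = NULL, K = NULL, step = 0.002,
                            fs_out = 25, noise_sd = 0, seed = 1) {
  if (is.null(omega)) omega <- 2 * pi * seq(0.5, 1.6, length.out = n)
  n <- length(omega)
  if (is.null(K)) K <- matrix(0, n, n)
  if (!is.matrix(K) || any(dim(K) != n)) stop_seizr("`K` must be n x n")
  if (any(diag(K) != 0)) stop_seizr("`K` must have a zero diagonal")
  if (step > 1 / (10 * max(abs(omega)))) {
    stop_seizr("integration step too large: need step <= 1 / (10 * max(omega))")
  }
  sub <- 1 / (fs_out * step)
  if (abs(sub - round(sub)) > 1e-9) {
    stop_seizr("1 / fs_out must be an integer multiple of `step`")
  }
  structure(
    list(n = n, omega = omega, K = K, step = step, fs_out = fs_out,
         noise_sd = noise_sd, seed = seed),
    class = "oscillator_spec"
  )
}

#' Simulate a coupled-oscillator network
#'
#' @param spec an [oscillator_spec()].
#' @param duration simulated time in seconds.
#' @param export `"phase"` (default) returns unwrapped phases in radians —
#'   feed these to [infer_network()] with `fourier_basis(r, domain =
#'   "phase")`; `"sine"` returns `sin(phase)`, mimicking amplitude signals.
#' @return list with `recording` (states sampled at `fs_out`) and `truth`
#'   (list with `K_true`, `omega`, `spec`).
#' @export
simulate_oscillators <- function(spec, duration, export = c("phase", "sine")) {
  stopifnot(inherits(spec, "oscillator_spec"))
  export <- match.arg(export)
  with_seed(spec$seed, {
    n_out <- as.integer(round(duration * spec$fs_out))
    sub <- as.integer(round(1 / (spec$fs_out * spec$step)))
    x <- stats::runif(spec$n, 0, 2 * pi)
    drift <- function(x) {
      # sum_j K[i, j] * sin(x_j - x_i)
      spec$omega + rowSums(spec$K * sin(outer(-x, x, `+`)))
    }
    out <- matrix(0, nrow = spec$n, ncol = n_out)
    h <- spec$step
    for (s_i in seq_len(n_out)) {
      for (sub_i in seq_len(sub)) {
        k1 <- drift(x)
        k2 <- drift(x + h / 2 * k1)
        k3 <- drift(x + h / 2 * k2)
        k4 <- drift(x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (spec$noise_sd > 0) {
          x <- x + stats::rnorm(spec$n, 0, spec$noise_sd * sqrt(h))
        }
        if (!all(is.finite(x)) || max(abs(k1)) * h > 1) {
          stop_seizr("integration unstable; use a smaller `step`")
        }
      }
      out[, s_i] <- x
    }
    data <- if (export == "sine") sin(out) else out
    rec <- new_recording(data, fs = spec$fs_out,
                         labels = sprintf("osc%02d", seq_len(spec$n)))
    list(recording = rec,
         truth = list(K_true = spec$K, omega = spec$omega, spec = spec,
                      export = export))
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes the signal (EDF or CSV), the seizure annotations as CSV
#' (`onset,offset` seconds) and the ground truth as JSON into `dir`. The
#' EDF round trip through [read_edf()] is lossy only up to 16-bit
#' quantization; the CSV round trip is exact to printed precision.
#'
#' @param rec an `eeg_recording`.
#' @param truth ground-truth list from [gen_recording()] (or `NULL`).
#' @param dir output directory (created if missing).
#' @param format `"edf"` or `"csv"`.
#' @return named character vector of the written paths (`recording`,
#'   `annotations`, `truth`).
#' @export
write_fixture <- function(rec, truth, dir, format = c("edf", "csv")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, paste0("recording.", format))
  if (format == "edf") write_edf(rec, rec_path) else write_csv_recording(rec, rec_path)
  ann_path <- file.path(dir, "annotations.csv")
  write_annotations(rec$annotations, ann_path)
  truth_path <- file.path(dir, "ground_truth.json")
  tr <- truth
  if (!is.null(tr$config)) tr$config <- unclass(tr$config)
  if (!is.null(tr$spec)) tr$spec <- unclass(tr$spec)
  jsonlite::write_json(
    list(fs = rec$fs, n_channels = nrow(rec$data),
         seizures = as.data.frame(tr$seizures %||% rec$annotations),
         artifacts = if (!is.null(tr$artifacts)) {
           as.data.frame(tr$artifacts[, c("onset", "offset")])
         },
         K_true = tr$K_true),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  c(recording = rec_path, annotations = ann_path, truth = truth_path)
}
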