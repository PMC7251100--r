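#' Preprocess a recording
#'
#' Standard scalp-EEG conditioning: per-channel baseline (mean) removal,
#' average re-referencing (the channel-mean of every sample column is
#' subtracted, so columns sum to zero afterwards), and a zero-phase band-pass
#' filter (4th-order Butterworth applied forward-backward, 1-50 Hz by
#' default). Annotations and metadata are carried through unchanged.
#'
#' @param rec an [new_recording()] object.
#' @param band_lo,band_hi band-pass edges in Hz; must satisfy
#'   `band_lo < band_hi < fs/2`.
#' @param rereference subtract the instantaneous channel average? (default TRUE)
#' @param remove_baseline subtract each channel's mean? (default TRUE)
#' @param filter apply the band-pass at all? Set `FALSE` to keep the raw
#'   spectrum (the spectral network route works on unfiltered data).
#' @return a preprocessed `eeg_recording`.
#' @export
preprocess <- function(rec, band_lo = 1, band_hi = 50, rereference = TRUE,
                       remove_baseline = TRUE, filter = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  if (filter) {
    if (band_lo <= 0 || band_lo >= band_hi) {
      stop_seizr("need 0 < band_lo < band_hi")
    }
    if (band_hi >= rec$fs / 2) {
      stop_seizr(sprintf(
        "band_hi = %g Hz is at or above the Nyquist frequency %g Hz",
        band_hi, rec$fs / 2
      ))
    }
  }
  if (remove_baseline) x <- x - rowMeans(x)
  if (rereference) x <- sweep(x, 2, colMeans(x))
  if (filter) {
    bf <- signal::butter(4, c(band_lo, band_hi) / (rec$fs / 2), type = "pass")
    for (i in seq_len(nrow(x))) {
      x[i, ] <- signal::filtfilt(bf, x[i, ])
    }
  }
  new_recording(x, fs = rec$fs, labels = rec$labels,
                start_time = rec$start_time, annotations = rec$annotations)
}

#' Scale a recording into \[-1, 1\]
#'
#' Divides each channel by its own maximum absolute value over the whole
#' recording, so every channel attains a peak of +/-1 (per-channel scaling
#' keeps low-amplitude channels informative). `scope = "recording"` instead
#' divides all channels by the single global maximum.
#'
#' @param rec an `eeg_recording`.
#' @param scope `"channel"` (default) or `"recording"`.
#' @return the rescaled `eeg_recording`. All-zero channels are left as zeros
#'   with a warning.
#' @export
normalize_range <- function(rec, scope = c("channel", "recording")) {
  stopifnot(inherits(rec, "eeg_recording"))
  scope <- match.arg(scope)
  x <- rec$data
  if (scope == "recording") {
    m <- max(abs(x))
    if (m == 0) {
      warning("all-zero recording left unscaled")
    } else {
      x <- x / m
    }
  } else {
    m <- apply(abs(x), 1, max)
    zero <- m == 0
    if (any(zero)) {
      warning(sprintf("all-zero channel(s) left unscaled: %s",
                      paste(rec$labels[zero], collapse = ", ")))
      m[zero] <- 1
    }
    x <- x / m
  }
  new_recording(x, fs = rec$fs, labels = rec$labels,
                start_time = rec$start_time, annotations = rec$annotations)
}

#' Sliding-window plan
#'
#' Describes how a recording is cut into analysis windows: length `w`
#' seconds, hop `hop` seconds (defaults to `w`, i.e. non-overlapping).
#' Sample ranges are 0-based and half-open; times are seconds from recording
#' start.
#'
#' @param w window length in seconds (> 0); `w * fs` must be an integer
#'   number of samples when applied.
#' @param hop hop between window starts in seconds (> 0).
#' @return a `window_plan` object.
#' @export
window_plan <- function(w, hop = w) {
  assert_scalar_number(w, "w", positive = TRUE)
  assert_scalar_number(hop, "hop", positive = TRUE)
  structure(list(w = w, hop = hop), class = "window_plan")
}

#' Cut a recording into windows
#'
#' Returns one row per complete window; a trailing partial window is dropped.
#' `t_k` is the window *end* time in seconds, matching the convention that a
#' per-window feature computed from samples in `[t_k - w, t_k)` is available
#' at time `t_k`.
#'
#' @param rec an `eeg_recording`.
#' @param plan a [window_plan()], or a single number taken as the window
#'   length in seconds (non-overlapping).
#' @return a tibble with columns `window` (1-based index), `t_k` (window end
#'   time, s) and `data` (list column of channels x samples matrices).
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 2560), 2, 2560), fs = 256)
#' seg <- segment(rec, 1)
#' nrow(seg)   # 10 windows
#' @export
segment <- function(rec, plan) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.numeric(plan)) plan <- window_plan(plan)
  n_w <- plan$w * rec$fs
  n_h <- plan$hop * rec$fs
  if (abs(n_w - round(n_w)) > 1e-9 || abs(n_h - round(n_h)) > 1e-9) {
    stop_seizr("window and hop must be whole numbers of samples")
  }
  n_w <- as.integer(round(n_w))
  n_h <- as.integer(round(n_h))
  n <- ncol(rec$data)
  starts <- seq(0L, n - n_w, by = n_h)
  if (n < n_w) starts <- integer()
  tibble::tibble(
    window = seq_along(starts),
    t_k = rec$start_time + (starts + n_w) / rec$fs,
    data = lapply(starts, function(s) rec$data[, (s + 1L):(s + n_w), drop = FALSE])
  )
}
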