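#' Per-window FFT power and phase spectra
#'
#' Computes the one-sided discrete Fourier spectrum of every channel in a
#' window (rectangular window, no zero-padding). Magnitudes are the raw DFT
#' moduli `p[i, n] = |X[i, n]|` and phases `phi[i, n] = Arg(X[i, n])` in
#' `(-pi, pi]`; the frequency grid has resolution `fs / M` for an `M`-sample
#' window.
#'
#' @param x numeric channels x samples matrix (one analysis window), or a
#'   vector for a single channel.
#' @param fs sampling rate in Hz.
#' @return a `spectral_frame`: list with `freqs` (Hz), `p` and `phi`
#'   (channels x frequencies matrices), `fs`, `n_samples`, and band-selection
#'   slots (`band`, `band_idx`, `n_band`) initialized to the full grid.
#' @examples
#' t <- seq(0, 1 - 1 / 256, by = 1 / 256)
#' sf <- compute_spectrum(sin(2 * pi * 5 * t), fs = 256)
#' sf$freqs[which.max(sf$p)]   # 5 Hz
#' @export
compute_spectrum <- function(x, fs) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  m <- ncol(x)
  if (m < 2) stop_seizr("window must contain at least 2 samples")
  assert_scalar_number(fs, "fs", positive = TRUE)
  X <- t(stats::mvfft(t(x)))
  keep <- seq_len(floor(m / 2) + 1L)
  X <- X[, keep, drop = FALSE]
  freqs <- (keep - 1L) * fs / m
  structure(
    list(
      freqs = freqs,
      p = Mod(X),
      phi = Arg(X),
      fs = fs,
      n_samples = m,
      band = c(0, fs / 2),
      band_idx = seq_along(freqs),
      n_band = length(freqs)
    ),
    class = "spectral_frame"
  )
}

#' Restrict a spectrum to a frequency band
#'
#' Zeroes the magnitude of every frequency component outside `[f_lo, f_hi]`
#' (band edges inclusive); phases are retained. Subsequent band power and
#' phase-coupling computations then run over the surviving bins only.
#'
#' @param frame a [compute_spectrum()] result.
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi <= fs/2`. The default
#'   2-10 Hz brackets the rhythms in which seizure synchronization typically
#'   appears (e.g. the 4-8 Hz theta band).
#' @return the band-limited `spectral_frame` with `band`, `band_idx`,
#'   `n_band` updated.
#' @export
band_restrict <- function(frame, f_lo = 2, f_hi = 10) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (f_lo >= f_hi) stop_seizr("need f_lo < f_hi")
  if (f_hi > frame$fs / 2 + 1e-12) stop_seizr("f_hi exceeds the Nyquist frequency")
  idx <- which(frame$freqs >= f_lo - 1e-12 & frame$freqs <= f_hi + 1e-12)
  if (length(idx) == 0) {
    stop_seizr(sprintf("band [%g, %g] Hz contains no frequency bins at resolution %g Hz",
                       f_lo, f_hi, frame$fs / frame$n_samples))
  }
  out <- frame$p
  out[, -idx] <- 0
  frame$p <- out
  frame$band <- c(f_lo, f_hi)
  frame$band_idx <- idx
  frame$n_band <- length(idx)
  frame
}

#' Per-channel band power
#'
#' Sums the squared magnitude spectrum of each channel over the in-band bins:
#' `P[i] = sum_n p[i, n]^2`. Under the default `power_def = "magnitude"`
#' (`p = |X|`) this is the band energy of the window and scales with the
#' square of the signal amplitude; `"periodogram"` squares once more
#' (`sum |X|^4`), scaling with the fourth power.
#'
#' @param frame a (band-restricted) `spectral_frame`.
#' @param power_def `"magnitude"` (default) or `"periodogram"`.
#' @return a `band_power` object: list with `P` (per-channel scalar, >= 0),
#'   `band`, `n_band`.
#' @export
band_power <- function(frame, power_def = c("magnitude", "periodogram")) {
  stopifnot(inherits(frame, "spectral_frame"))
  power_def <- match.arg(power_def)
  p <- frame$p[, frame$band_idx, drop = FALSE]
  P <- switch(power_def,
    magnitude = rowSums(p^2),
    periodogram = rowSums(p^4)
  )
  structure(list(P = P, band = frame$band, n_band = frame$n_band),
            class = "band_power")
}

#' Pairwise power and phase coupling coefficients
#'
#' Combines per-channel band powers and cross-channel phase differences into
#' the coupling coefficients of the synchronization network:
#' \deqn{\sigma^p_{ij} = \sigma^p_{ji} = P_i + P_j}
#' \deqn{\sigma^\phi_{ij} = -\sigma^\phi_{ji} =
#'   \frac{1}{N}\sum_{n} \sin(\phi_{j,n} - \phi_{i,n})}
#' where the sum runs over the `N = n_band` in-band frequency bins, and
#' \eqn{d_{ij} = \sigma^p_{ij}\,\sigma^\phi_{ij}} with a zero diagonal.
#' \eqn{\sigma^\phi} behaves like a phase-lag index: it vanishes for
#' identical (zero-lag) phase profiles and is bounded by 1 in magnitude.
#'
#' @param frame a band-restricted `spectral_frame`.
#' @param bp the matching [band_power()] result (computed from `frame` if
#'   omitted).
#' @param power_def forwarded to [band_power()] when `bp` is missing.
#' @return list with matrices `sigma_p` (symmetric, >= 0), `sigma_phi`
#'   (antisymmetric, |.| <= 1) and `d`.
#' @export
coupling_matrices <- function(frame, bp = NULL,
                              power_def = c("magnitude", "periodogram")) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (is.null(bp)) bp <- band_power(frame, match.arg(power_def))
  if (frame$n_band < 1) stop_seizr("no in-band frequency bins")
  P <- bp$P
  sigma_p <- outer(P, P, `+`)
  phi <- frame$phi[, frame$band_idx, drop = FALSE]
  # sum_n sin(phi_j - phi_i) = Im[ conj(E) E^T ]_{ij} with E = exp(i phi)
  E <- exp(1i * phi)
  sigma_phi <- Im(Conj(E) %*% t(E)) / frame$n_band
  d <- sigma_p * sigma_phi
  diag(d) <- 0
  diag(sigma_p) <- 2 * P
  labels <- rownames(frame$p)
  dimnames(sigma_p) <- dimnames(sigma_phi) <- dimnames(d) <- list(labels, labels)
  list(sigma_p = sigma_p, sigma_phi = sigma_phi, d = d)
}

#' Adjacency, degree and Laplacian of the synchronization network
#'
#' Maps the pairwise coupling magnitudes to edge weights in `[0, 1)` via
#' `a_ij = 1 - exp(-|d_ij|^gamma)`, and forms the degree matrix
#' `D = diag(rowSums(A))` and graph Laplacian `L = D - A`. Because `|d_ij|`
#' is symmetric the adjacency is symmetric with a zero diagonal, and `L` is
#' positive semidefinite with zero row sums.
#'
#' `gamma` (default 2) controls robustness: it flattens small couplings
#' (|d| < 1) toward zero while saturating strong ones, but values much above
#' 3 suppress genuine in-band synchronization as well.
#'
#' @param d coupling matrix with zero diagonal (from [coupling_matrices()]).
#' @param gamma positive exponent.
#' @return list with matrices `A`, `D`, `L` and the `gamma` used.
#' @examples
#' adjacency(matrix(c(0, 1, 1, 0), 2), gamma = 2)$A[1, 2]  # 1 - exp(-1)
#' @export
adjacency <- function(d, gamma = 2) {
  if (gamma <= 0) stop_seizr("`gamma` must be > 0")
  if (any(diag(d) != 0)) stop_seizr("`d` must have a zero diagonal")
  A <- 1 - exp(-abs(d)^gamma)
  diag(A) <- 0
  A <- (A + t(A)) / 2              # guards against asymmetric rounding only
  D <- diag(rowSums(A), nrow = nrow(A))
  L <- D - A
  dimnames(D) <- dimnames(L) <- dimnames(A)
  list(A = A, D = D, L = L, gamma = gamma)
}

#' Fiedler eigenvalue (algebraic connectivity)
#'
#' Eigen-decomposes a graph Laplacian and returns the second-smallest
#' eigenvalue `lambda2` (zero iff the graph is disconnected), the largest
#' eigenvalue `lambda_n`, and the eigenratio `R = lambda2 / lambda_n`
#' (0 when `lambda_n = 0`). Eigenvalues within `-1e-12` of zero are clamped
#' to zero.
#'
#' @param L symmetric Laplacian matrix with zero row sums.
#' @param tol symmetry tolerance; an asymmetry beyond it is an error.
#' @return list with `lambda2`, `lambda_n`, `eigenratio`.
#' @examples
#' g <- adjacency(matrix(1, 3, 3) - diag(3))
#' fiedler(g$L)$lambda2   # complete graph on 3 nodes: lambda2 = 3
#' @export
fiedler <- function(L, tol = 1e-8) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop_seizr("`L` must be square")
  if (max(abs(L - t(L))) > tol * max(1, max(abs(L)))) {
    stop_seizr("`L` is not symmetric within tolerance")
  }
  vals <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  vals[vals > -1e-12 & vals < 0] <- 0
  lambda2 <- vals[[2]]
  lambda_n <- vals[[length(vals)]]
  list(
    lambda2 = lambda2,
    lambda_n = lambda_n,
    eigenratio = if (lambda_n == 0) 0 else lambda2 / lambda_n
  )
}

#' Synchronization network for one window
#'
#' Runs the single-window spectral pipeline: FFT spectrum, band restriction,
#' band power, coupling coefficients, adjacency/Laplacian, Fiedler value.
#'
#' @param x channels x samples window matrix.
#' @param fs sampling rate (Hz).
#' @param band two-element numeric, band edges in Hz.
#' @param gamma adjacency exponent.
#' @param power_def see [band_power()].
#' @return a `network_frame`: list with `sigma_p`, `sigma_phi`, `d`, `A`,
#'   `D`, `L`, `gamma`, `lambda2`, `lambda_n`, `eigenratio`.
#' @export
network_frame <- function(x, fs, band = c(2, 10), gamma = 2,
                          power_def = c("magnitude", "periodogram")) {
  power_def <- match.arg(power_def)
  sf <- band_restrict(compute_spectrum(x, fs), band[[1]], band[[2]])
  cm <- coupling_matrices(sf, band_power(sf, power_def))
  g <- adjacency(cm$d, gamma)
  fe <- fiedler(g$L)
  structure(c(cm, g, fe), class = "network_frame")
}

#' Algebraic-connectivity time series of a recording
#'
#' The end-to-end spectral route: the recording is (optionally) scaled into
#' `[-1, 1]`, cut into windows, and each window is mapped to the Fiedler
#' eigenvalue of its synchronization network. Seizure onsets appear as
#' sustained rises of `lambda2`; incoherent high-power transients confined to
#' a few channels barely move it, because two strongly coupled vertices
#' cannot raise the global connectivity of a 23-vertex graph.
#'
#' @param rec an `eeg_recording`.
#' @param window window length in seconds (default 1; the method is designed
#'   for short epochs of 0.25-1 s).
#' @param hop hop in seconds (default `window`, non-overlapping).
#' @param band analysis band in Hz (default `c(2, 10)`).
#' @param gamma adjacency exponent (default 2).
#' @param power_def see [band_power()].
#' @param normalize scale into `[-1, 1]` first? (default TRUE; see
#'   [normalize_range()]).
#' @param prefilter apply the 1-50 Hz zero-phase band-pass before analysis?
#'   Default FALSE: the band restriction inside the spectral route makes
#'   broadband prefiltering unnecessary.
#' @param keep_networks also return the per-window `network_frame`s as a
#'   list column (memory-heavy for long recordings).
#' @return a `connectivity_series`: tibble with columns `time_s` (window end
#'   time), `lambda2`, `lambda_n`, `eigenratio` (and `network` if requested),
#'   carrying the analysis parameters as attributes.
#' @export
lambda2_series <- function(rec, window = 1, hop = window, band = c(2, 10),
                           gamma = 2, power_def = c("magnitude", "periodogram"),
                           normalize = TRUE, prefilter = FALSE,
                           keep_networks = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  power_def <- match.arg(power_def)
  if (prefilter) rec <- preprocess(rec)
  if (normalize) rec <- normalize_range(rec)
  seg <- segment(rec, window_plan(window, hop))
  frames <- lapply(seg$data, network_frame, fs = rec$fs, band = band,
                   gamma = gamma, power_def = power_def)
  out <- tibble::tibble(
    time_s = seg$t_k,
    lambda2 = vapply(frames, `[[`, numeric(1), "lambda2"),
    lambda_n = vapply(frames, `[[`, numeric(1), "lambda_n"),
    eigenratio = vapply(frames, `[[`, numeric(1), "eigenratio")
  )
  if (keep_networks) out$network <- frames
  structure(out,
            class = c("connectivity_series", class(out)),
            window = window, hop = hop, band = band, gamma = gamma,
            power_def = power_def)
}

#' Write a connectivity series to CSV
#'
#' @param series a [lambda2_series()] result.
#' @param path output path; columns `time_s,lambda2,lambda_n,eigenratio`.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  keep <- intersect(c("time_s", "lambda2", "lambda_n", "eigenratio", "ema"),
                    names(series))
  readr::write_csv(tibble::as_tibble(series)[, keep], path)
  invisible(path)
}
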