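#' Trigonometric (Fourier) basis for coupling-function expansion
#'
#' The coupling-function route models each channel's dynamics as
#' \deqn{\dot x_i = \sum_k a_k Q_k(x_i) +
#'   \sum_{j \ne i} \sum_{k,\ell} b_{ij}^{k\ell} P_k(x_i) P_\ell(x_j)}
#' with `Q = P` a truncated Fourier set on the unit interval. With the
#' default `r = 5` the terms are `1, sin(2 pi u), cos(2 pi u), sin(4 pi u),
#' cos(4 pi u)`; general `r` continues the sin/cos pairs. The state is
#' mapped to `u` by a domain map: `"amplitude"` sends `[-1, 1]` signals to
#' `u = (x + 1) / 2`, `"phase"` sends radians to `u = x / (2 pi)` — the
#' basis is 1-periodic in `u`, so unwrapped phases need no wrapping.
#'
#' @param r number of basis terms (>= 1; the first is the constant).
#' @param domain `"amplitude"` or `"phase"`.
#' @return a `fourier_basis` object.
#' @export
fourier_basis <- function(r = 5, domain = c("amplitude", "phase")) {
  if (r < 1) stop_seizr("`r` must be >= 1")
  structure(list(r = as.integer(r), domain = match.arg(domain)),
            class = "fourier_basis")
}

map_to_unit <- function(x, basis) {
  switch(basis$domain,
    amplitude = (x + 1) / 2,
    phase = x / (2 * pi)
  )
}

#' Evaluate the basis on state values
#'
#' @param basis a [fourier_basis()].
#' @param x state values (signal in `[-1, 1]` for the amplitude domain,
#'   radians for the phase domain).
#' @return a `length(x)` x `r` matrix; column `k` is the `k`-th basis term.
#' @export
eval_basis <- function(basis, x) {
  u <- map_to_unit(x, basis)
  out <- matrix(1, nrow = length(u), ncol = basis$r)
  for (k in seq_len(basis$r)[-1]) {
    m <- k %/% 2
    out[, k] <- if (k %% 2 == 0) sin(2 * pi * m * u) else cos(2 * pi * m * u)
  }
  out
}

#' First-order derivative estimate
#'
#' Central differences on the interior, one-sided differences at the
#' endpoints; units are signal per second. For a well-resolved sinusoid of
#' frequency `f` the interior error is bounded by `(2 pi f)^3 / (6 fs^2)`.
#'
#' @param x numeric vector, or channels x samples matrix (row-wise).
#' @param fs sampling rate in Hz.
#' @return derivative of the same shape as `x`.
#' @export
estimate_derivative <- function(x, fs) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, estimate_derivative, fs = fs)))
  }
  n <- length(x)
  if (n < 3) stop_seizr("need at least 3 samples to estimate a derivative")
  dx <- numeric(n)
  dx[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  dx[1] <- (x[2] - x[1]) * fs
  dx[n] <- (x[n] - x[n - 1]) * fs
  dx
}

#' Build the per-channel linear inverse problem
#'
#' For target channel `i`, stacks the regression of its derivative samples
#' on the basis evaluations: `r` self-dynamics columns `Q_k(x_i)` followed,
#' for each source channel `j != i` in ascending order, by the `r^2` product
#' columns `P_k(x_i) P_l(x_j)` in `(k, l)` row-major order. The column count
#' is `C = r + r^2 (N - 1)` (555 for `r = 5`, `N = 23`).
#'
#' @param x channels x samples window matrix, in the basis domain.
#' @param i target channel index.
#' @param basis a [fourier_basis()].
#' @param fs sampling rate in Hz (used to differentiate channel `i` when
#'   `deriv` is not supplied).
#' @param deriv optional precomputed derivative samples for channel `i`
#'   (e.g. differentiated before windowing, or exact derivatives in
#'   simulation studies).
#' @param drop_redundant omit the `l = 1` columns of every pair block.
#'   Because the first basis term is the constant, `P_k(x_i) P_1(x_j) =
#'   P_k(x_i)` duplicates the self block exactly, making the full design
#'   rank-deficient and the self/coupling split non-identifiable: a
#'   minimum-norm solve spreads each self coefficient uniformly over its
#'   copies and contaminates every coupling strength. Terms that do not
#'   depend on the source channel are self-dynamics by definition, so
#'   [infer_network()] drops them (`C = r + r (r - 1) (N - 1)` columns);
#'   the default `FALSE` keeps the complete `C = r + r^2 (N - 1)` layout.
#' @return a `design_problem`: list with `y` (M-vector), `A` (M x C matrix)
#'   and `map`, a tibble with one row per column (`col`, `src`, `k`, `l`;
#'   `src = NA` for the self block).
#' @export
build_design <- function(x, i, basis, fs = NULL, deriv = NULL,
                         drop_redundant = FALSE) {
  stopifnot(inherits(basis, "fourier_basis"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n_ch <- nrow(x)
  m <- ncol(x)
  r <- basis$r
  l_keep <- if (drop_redundant && r > 1) 2:r else seq_len(r)
  C <- r + r * length(l_keep) * (n_ch - 1L)
  if (m < C) {
    stop_seizr(sprintf(
      "underdetermined system: %d samples for %d coefficients; use a longer window",
      m, C
    ))
  }
  if (is.null(deriv)) {
    if (is.null(fs)) stop_seizr("supply `fs` or precomputed `deriv`")
    deriv <- estimate_derivative(x[i, ], fs)
  }
  if (length(deriv) != m) stop_seizr("`deriv` length must match the window")

  B <- lapply(seq_len(n_ch), function(ch) eval_basis(basis, x[ch, ]))
  A <- matrix(0, nrow = m, ncol = C)
  A[, seq_len(r)] <- B[[i]]
  src <- rep(NA_integer_, r)
  kk <- seq_len(r)
  ll <- rep(NA_integer_, r)
  col <- r
  for (j in setdiff(seq_len(n_ch), i)) {
    for (k in seq_len(r)) {
      for (l in l_keep) {
        col <- col + 1L
        A[, col] <- B[[i]][, k] * B[[j]][, l]
      }
    }
    src <- c(src, rep(j, r * length(l_keep)))
    kk <- c(kk, rep(seq_len(r), each = length(l_keep)))
    ll <- c(ll, rep(l_keep, times = r))
  }
  structure(
    list(
      y = as.numeric(deriv),
      A = A,
      map = tibble::tibble(col = seq_len(C), src = src, k = kk, l = ll),
      channel = i,
      n_channels = n_ch,
      r = r
    ),
    class = "design_problem"
  )
}

#' Solve the linear inverse problem
#'
#' Minimum-norm least-squares solution of `min_z ||y - A z||` via the
#' singular value decomposition, with optional Tikhonov regularization.
#' When `ridge = 0` and the design is numerically rank-deficient, the ridge
#' is escalated automatically to `1e-8 * trace(A'A) / C` with a warning.
#'
#' @param problem a [build_design()] result (or any list with `y` and `A`).
#' @param ridge Tikhonov parameter >= 0.
#' @return the coefficient vector `z` (length `ncol(A)`).
#' @export
solve_inverse <- function(problem, ridge = 0) {
  A <- problem$A
  y <- problem$y
  if (!all(is.finite(A)) || !all(is.finite(y))) {
    stop_seizr("design matrix or data vector contains non-finite entries")
  }
  if (ridge < 0) stop_seizr("`ridge` must be >= 0")
  C <- ncol(A)
  if (ridge == 0) {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
    rank <- sum(sv$d > tol)
    if (rank < C) {
      ridge <- 1e-8 * sum(sv$d^2) / C
      warning(sprintf(
        "rank-deficient design (rank %d < %d); escalating ridge to %.3g",
        rank, C, ridge
      ))
    } else {
      return(drop(sv$v %*% ((crossprod(sv$u, y)) / sv$d)))
    }
  }
  AtA <- crossprod(A)
  diag(AtA) <- diag(AtA) + ridge
  drop(solve(AtA, crossprod(A, y)))
}

#' Coupling strengths from a coefficient vector
#'
#' Collapses the `r x r` coefficient block of every source channel into a
#' scalar coupling strength, the root-sum-square
#' `alpha_ij = sqrt(sum_kl (b_ij^kl)^2)` of the two-dimensional basis
#' coefficients — by Parseval's relation, a measure of the RMS power of the
#' inferred interaction function from `j` into `i`.
#'
#' @param z coefficient vector from [solve_inverse()].
#' @param map the column map from the matching [build_design()] problem (a
#'   `design_problem` may be passed directly).
#' @return list with `a` (self coefficients), `b` (named list of `r x r`
#'   coefficient matrices per source channel) and `alpha` (named vector of
#'   coupling strengths, one per source channel).
#' @export
coupling_strengths <- function(z, map) {
  if (inherits(map, "design_problem")) map <- map$map
  if (length(z) != nrow(map)) {
    stop_seizr("coefficient vector length does not match the column map")
  }
  self <- is.na(map$src)
  a <- z[self]
  srcs <- sort(unique(map$src[!self]))
  r <- max(map$k)
  b <- lapply(srcs, function(j) {
    rows <- which(!self & map$src == j)
    bm <- matrix(0, r, r)
    bm[cbind(map$k[rows], map$l[rows])] <- z[rows]
    bm
  })
  names(b) <- as.character(srcs)
  alpha <- vapply(b, function(bm) sqrt(sum(bm^2)), numeric(1))
  list(a = a, b = b, alpha = alpha)
}

#' Infer the time-varying directed coupling network
#'
#' Runs the coupling-function route over sliding windows: for each window
#' and each target channel independently (the per-channel problems share no
#' state, so any execution order gives identical results), the channel's
#' derivative is regressed on the two-dimensional basis and the coefficient
#' blocks are collapsed into the directed strength matrix `J = [alpha_ij]`
#' (row = target, column = source, zero diagonal; `J` need not be
#' symmetric).
#'
#' Derivatives are estimated once per channel on the full recording (central
#' differences) and then windowed, so window edges incur no one-sided
#' differentiation error.
#'
#' @param rec an `eeg_recording`. For EEG use, preprocess first (1-50 Hz
#'   band-pass, average re-reference) and leave `normalize = TRUE` so the
#'   signals live on the basis domain; for oscillator phase data use
#'   `basis = fourier_basis(r, domain = "phase")` and `normalize = FALSE`.
#' @param window window length in seconds (10-20 s recommended so that the
#'   sample count comfortably exceeds the coefficient count).
#' @param hop hop in seconds (default `window`).
#' @param basis a [fourier_basis()].
#' @param ridge Tikhonov parameter for [solve_inverse()].
#' @param normalize scale into `[-1, 1]` first (amplitude domain only).
#' @return a `coupling_series`: tibble with columns `time_s` and `J` (list
#'   of strength matrices), carrying the parameters as attributes.
#' @export
infer_network <- function(rec, window = 10, hop = window,
                          basis = fourier_basis(5), ridge = 0,
                          normalize = basis$domain == "amplitude") {
  stopifnot(inherits(rec, "eeg_recording"), inherits(basis, "fourier_basis"))
  if (normalize) rec <- normalize_range(rec)
  n_ch <- nrow(rec$data)
  dx <- estimate_derivative(rec$data, rec$fs)
  drec <- new_recording(dx, fs = rec$fs, labels = rec$labels,
                        start_time = rec$start_time)
  seg_x <- segment(rec, window_plan(window, hop))
  seg_dx <- segment(drec, window_plan(window, hop))
  J <- purrr::map2(seg_x$data, seg_dx$data, function(xw, dxw) {
    Jw <- matrix(0, n_ch, n_ch, dimnames = list(rec$labels, rec$labels))
    for (i in seq_len(n_ch)) {
      prob <- build_design(xw, i, basis, deriv = dxw[i, ],
                           drop_redundant = TRUE)
      cs <- coupling_strengths(solve_inverse(prob, ridge), prob$map)
      Jw[i, as.integer(names(cs$alpha))] <- cs$alpha
    }
    Jw
  })
  out <- tibble::tibble(time_s = seg_x$t_k, J = J)
  structure(out,
            class = c("coupling_series", class(out)),
            window = window, hop = hop, r = basis$r,
            domain = basis$domain, ridge = ridge)
}

#' Exponential moving average
#'
#' `ema_t = beta * x_t + (1 - beta) * ema_{t-1}`, initialized at `x_1`.
#' `beta = 1` reproduces the raw series; a constant series is a fixed point
#' for every `beta`; the output is bounded by the running min and max.
#'
#' @param x numeric vector.
#' @param beta smoothing factor in (0, 1].
#' @return the smoothed vector.
#' @export
ema <- function(x, beta) {
  if (beta <= 0 || beta > 1) stop_seizr("`beta` must be in (0, 1]")
  if (length(x) == 0) return(x)
  out <- numeric(length(x))
  out[[1]] <- x[[1]]
  for (t in seq_along(x)[-1]) {
    out[[t]] <- beta * x[[t]] + (1 - beta) * out[[t - 1]]
  }
  out
}

#' Synchronizability series of an inferred coupling network
#'
#' Converts each directed strength matrix into an undirected weighted graph
#' by symmetrization, `W = (J + t(J)) / 2` (a Fiedler eigenvalue requires a
#' symmetric Laplacian), forms `L = diag(rowSums(W)) - W`, and tracks the
#' algebraic connectivity `lambda2` together with its exponential moving
#' average.
#'
#' @param cs a [infer_network()] result, or a list of strength matrices with
#'   a matching `time_s` vector.
#' @param beta EMA smoothing factor (default 0.2).
#' @param time_s window times when `cs` is a bare list of matrices.
#' @return a `sync_series`: tibble with columns `time_s`, `lambda2`, `ema`.
#' @export
synchronizability <- function(cs, beta = 0.2, time_s = NULL) {
  if (inherits(cs, "coupling_series")) {
    J <- cs$J
    time_s <- cs$time_s
  } else {
    J <- cs
    time_s <- time_s %||% seq_along(J)
  }
  lambda2 <- vapply(J, function(Jw) {
    if (any(Jw < 0)) stop_seizr("coupling strengths must be nonnegative")
    W <- (Jw + t(Jw)) / 2
    diag(W) <- 0
    L <- diag(rowSums(W), nrow = nrow(W)) - W
    fiedler(L)$lambda2
  }, numeric(1))
  out <- tibble::tibble(time_s = time_s, lambda2 = lambda2,
                        ema = ema(lambda2, beta))
  structure(out, class = c("sync_series", class(out)), beta = beta)
}

#' @describeIn infer_network long-format view of a coupling series: one row
#'   per (window, source, target) with the inferred strength.
#' @param x a `coupling_series`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.coupling_series <- function(x, ...) {
  purrr::map2_dfr(x$time_s, x$J, function(t, Jw) {
    idx <- which(row(Jw) != col(Jw))
    tibble::tibble(
      time_s = t,
      src = colnames(Jw)[col(Jw)[idx]] %||% col(Jw)[idx],
      dst = rownames(Jw)[row(Jw)[idx]] %||% row(Jw)[idx],
      alpha = Jw[idx]
    )
  })
}

#' Write a coupling series as long-format CSV
#'
#' Columns `time_s,src,dst,alpha`, one row per directed pair per window.
#'
#' @param cs a [infer_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coupling_csv <- function(cs, path) {
  readr::write_csv(tidy.coupling_series(cs), path)
  invisible(path)
}
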