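# Shared fixtures and independent oracles for the test suite.

# deterministic multichannel test recording (sinusoids + noise)
make_recording <- function(n_ch = 3, fs = 256, duration = 4, seed = 7) {
  withr::with_seed(seed, {
    t <- seq(0, duration - 1 / fs, by = 1 / fs)
    data <- t(sapply(seq_len(n_ch), function(i) {
      sin(2 * pi * (3 + i) * t + i / 2) + 0.3 * rnorm(length(t))
    }))
    new_recording(data, fs = fs)
  })
}

# union-find connectivity oracle on the support graph a_ij > 0
graph_connected <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (A[i, j] > 0) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# Mann-Whitney rank AUC: probability a true edge outranks a non-edge
auc_rank <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  mean(outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`))
}

# naive double-loop implementation of the coupling coefficients
coupling_oracle <- function(frame, P) {
  n <- nrow(frame$p)
  idx <- frame$band_idx
  sp <- sphi <- d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sp[i, j] <- P[i] + P[j]
      s <- 0
      for (b in idx) s <- s + sin(frame$phi[j, b] - frame$phi[i, b])
      sphi[i, j] <- s / length(idx)
      if (i != j) d[i, j] <- sp[i, j] * sphi[i, j]
    }
  }
  list(sigma_p = sp, sigma_phi = sphi, d = d)
}

# hand-written EDF with two different per-signal sampling rates
write_mixed_rate_edf <- function(path) {
  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  ns <- 2L
  nr <- c(64L, 32L)
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("X", 80), con, eos = NULL)
  writeChar(pad("X", 80), con, eos = NULL)
  writeChar(pad("01.01.00", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256 + 256 * ns, 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(1, 8), con, eos = NULL)
  writeChar(pad(1, 8), con, eos = NULL)
  writeChar(pad(ns, 4), con, eos = NULL)
  writeChar(paste(pad(c("fast", "slow"), 16), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep(-100, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep(100, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep(-32768, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep(32767, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(nr, 8), collapse = ""), con, eos = NULL)
  writeChar(paste(pad(rep("", ns), 32), collapse = ""), con, eos = NULL)
  writeBin(integer(sum(nr)), con, size = 2, endian = "little")
  path
}

# flat lambda2-style series for detector tests
flat_series <- function(values, hop = 1) {
  tibble::tibble(time_s = seq_along(values) * hop, lambda2 = values)
}
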