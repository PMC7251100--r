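test_that("spectrum of an integer-cycle sinusoid concentrates in one bin", {
  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sf <- compute_spectrum(sin(2 * pi * 5 * t), fs)
  expect_equal(sf$freqs, 0:128)
  peak <- which.max(sf$p[1, ])
  expect_equal(sf$freqs[peak], 5)
  expect_true(all(sf$p[1, -peak] < 1e-9 * sf$p[1, peak]))
  expect_equal(sf$p[1, peak], fs / 2, tolerance = 1e-12)

  zero <- compute_spectrum(matrix(0, 2, 64), fs)
  expect_true(all(zero$p == 0))
  expect_error(compute_spectrum(matrix(1, 1, 1), fs), "at least 2 samples")
})

test_that("one-sided spectrum satisfies Parseval's identity", {
  withr::with_seed(11, {
    for (m in c(64, 256, 255)) {   # even and odd window lengths
      x <- rnorm(m)
      sf <- compute_spectrum(x, fs = m)
      w <- rep(2, length(sf$freqs))
      w[1] <- 1
      if (m %% 2 == 0) w[length(w)] <- 1
      energy_freq <- sum(w * sf$p[1, ]^2) / m
      expect_equal(energy_freq, sum(x^2), tolerance = 1e-6)
    }
  })
})

test_that("band restriction keeps inclusive edges and zeroes the rest", {
  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sf <- compute_spectrum(rbind(sin(2 * pi * 5 * t), cos(2 * pi * 40 * t)), fs)
  br <- band_restrict(sf, 2, 10)
  expect_equal(br$n_band, 9)                 # 2..10 Hz at 1 Hz resolution
  expect_equal(br$freqs[br$band_idx], 2:10)
  expect_true(all(br$p[, -br$band_idx] == 0))
  expect_equal(br$phi, sf$phi)               # phases retained
  expect_equal(br$p[2, br$band_idx], rep(0, 9))  # 40 Hz tone wiped in band

  full <- band_restrict(sf, 0, fs / 2)
  expect_equal(full$p, sf$p)
  expect_error(band_restrict(sf, 3.2, 3.8), "no frequency bins")
  expect_error(band_restrict(sf, 2, 200), "Nyquist")
})

test_that("band power sums squared magnitudes with the documented amplitude scaling", {
  frame <- structure(
    list(freqs = c(2, 3), p = matrix(c(3, 0, 4, 0), 2, 2), phi = matrix(0, 2, 2),
         fs = 8, n_samples = 8, band = c(2, 3), band_idx = 1:2, n_band = 2L),
    class = "spectral_frame"
  )
  expect_equal(band_power(frame)$P, c(25, 0))

  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  p1 <- band_power(band_restrict(compute_spectrum(sin(2 * pi * 5 * t), fs), 2, 10))$P
  p2 <- band_power(band_restrict(compute_spectrum(2 * sin(2 * pi * 5 * t), fs), 2, 10))$P
  expect_equal(p2 / p1, 4, tolerance = 1e-9)   # magnitude: energy ~ amplitude^2
  q1 <- band_power(band_restrict(compute_spectrum(sin(2 * pi * 5 * t), fs), 2, 10),
                   "periodogram")$P
  q2 <- band_power(band_restrict(compute_spectrum(2 * sin(2 * pi * 5 * t), fs), 2, 10),
                   "periodogram")$P
  expect_equal(q2 / q1, 16, tolerance = 1e-9)  # periodogram: ~ amplitude^4
})

test_that("phase coupling vanishes at zero lag and saturates at quadrature", {
  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 7 * t)
  same <- band_restrict(compute_spectrum(rbind(x, x), fs), 2, 10)
  cm <- coupling_matrices(same)
  expect_equal(cm$sigma_phi[1, 2], 0)
  expect_equal(cm$d[1, 2], 0)

  # quadrature lag at every in-band bin
  phi <- matrix(0, 2, 129)
  phi[2, ] <- pi / 2
  quad <- structure(
    list(freqs = 0:128, p = matrix(1, 2, 129), phi = phi, fs = 256,
         n_samples = 256, band = c(2, 10), band_idx = 3:11, n_band = 9L),
    class = "spectral_frame"
  )
  cmq <- coupling_matrices(quad)
  expect_equal(cmq$sigma_phi[1, 2], 1)
  expect_equal(cmq$sigma_phi[2, 1], -1)
})

test_that("coupling matrices match the naive double-loop oracle", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      x <- matrix(rnorm(3 * 128), 3, 128)
      sf <- band_restrict(compute_spectrum(x, 128), 2, 10)
      bp <- band_power(sf)
      cm <- coupling_matrices(sf, bp)
      oracle <- coupling_oracle(sf, bp$P)
      expect_lt(max(abs(cm$sigma_phi - oracle$sigma_phi)), 1e-12)
      expect_lt(max(abs(cm$d - oracle$d)), 1e-10)
      expect_equal(cm$sigma_p[1, 2], bp$P[1] + bp$P[2])
      # structural invariants
      expect_equal(cm$sigma_p, t(cm$sigma_p))
      expect_equal(cm$sigma_phi, -t(cm$sigma_phi))
      expect_true(all(abs(cm$sigma_phi) <= 1 + 1e-12))
      expect_true(all(diag(cm$d) == 0))
    }
  })
})

test_that("adjacency map follows 1 - exp(-|d|^gamma) with a valid Laplacian", {
  d <- matrix(c(0, 1, -2, 1, 0, 0.5, -2, 0.5, 0), 3, 3)
  g <- adjacency(d, gamma = 2)
  expect_equal(g$A[1, 2], 1 - exp(-1))
  expect_equal(g$A[1, 3], 1 - exp(-4))       # |-2|^2
  expect_true(all(diag(g$A) == 0))
  expect_equal(g$A, t(g$A))
  expect_true(all(g$A >= 0 & g$A <= 1))  # saturates to 1.0 in double precision
  expect_equal(rowSums(g$L), rep(0, 3), tolerance = 1e-14)
  expect_true(min(eigen(g$L, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  expect_error(adjacency(d, gamma = 0), "gamma")
  expect_error(adjacency(diag(3)), "zero diagonal")
  # a -> 1 monotonically as |d| grows
  a_seq <- 1 - exp(-abs(c(0.1, 1, 2, 4))^2)
  expect_true(all(diff(a_seq) > 0) && all(a_seq < 1))
})

test_that("fiedler matches closed forms and flags asymmetry", {
  for (n in c(3, 5, 8)) {
    for (w in c(1, 0.25)) {
      A <- matrix(w, n, n) - diag(w, n)
      L <- diag(rowSums(A)) - A
      expect_equal(fiedler(L)$lambda2, n * w, tolerance = 1e-10)
    }
  }
  empty <- fiedler(matrix(0, 4, 4))
  expect_equal(empty$lambda2, 0)
  expect_equal(empty$eigenratio, 0)
  expect_error(fiedler(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("lambda2 > 0 exactly when the support graph is connected", {
  withr::with_seed(21, {
    hits <- 0
    for (trial in 1:100) {
      n <- sample(4:10, 1)
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (runif(1) < runif(1, 0.1, 0.5)) {
            d[i, j] <- d[j, i] <- runif(1, 0.5, 2) * sample(c(-1, 1), 1)
          }
        }
      }
      g <- adjacency(d)
      lam2 <- fiedler(g$L)$lambda2
      connected <- graph_connected(g$A)
      hits <- hits + connected
      if (connected) expect_gt(lam2, 1e-8) else expect_lt(lam2, 1e-10)
    }
    expect_gt(hits, 5)   # both branches exercised
    expect_lt(hits, 95)
  })
})

test_that("amplitude scaling increases band power, couplings and lambda2", {
  withr::with_seed(5, {
    x <- 0.02 * matrix(rnorm(4 * 256), 4, 256)   # unsaturated coupling regime
    f1 <- network_frame(x, 256)
    f2 <- network_frame(2 * x, 256)
    p1 <- band_power(band_restrict(compute_spectrum(x, 256)))$P
    p2 <- band_power(band_restrict(compute_spectrum(2 * x, 256)))$P
    expect_true(all(p2 > p1))
    expect_true(all(abs(f2$d) >= abs(f1$d)))
    expect_true(all(f2$A >= f1$A - 1e-15))
    expect_gte(f2$lambda2, f1$lambda2)
    expect_gt(f2$lambda2, f1$lambda2)    # strict: some sigma_phi != 0 here
    # phases are scale-invariant
    expect_equal(f1$sigma_phi, f2$sigma_phi, tolerance = 1e-10)
  })
})

test_that("identical channels (zero lag) give an identically zero network", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 6 * t) + 0.2 * sin(2 * pi * 3 * t + 1)
  rec <- new_recording(matrix(x, nrow = 3, ncol = length(x), byrow = TRUE), fs)
  ser <- lambda2_series(rec)
  expect_true(all(abs(ser$lambda2) < 1e-9))
})

test_that("lambda2 rises during a planted coherent seizure and only there", {
  # artifacts set the per-channel normalization scale, as in real sessions
  cfg <- synth_config(
    n_channels = 8, duration = 120, seed = 5,
    seizures = tibble::tibble(onset = 60, offset = 80),
    artifacts = tibble::tibble(onset = c(10, 25, 95, 110),
                               offset = c(13, 28, 98, 113))
  )
  gen <- gen_recording(cfg)
  ser <- lambda2_series(gen$recording)
  in_seiz <- ser$time_s > 61 & ser$time_s <= 80
  base <- ser$lambda2[ser$time_s <= 58 | ser$time_s > 82]
  expect_gt(min(ser$lambda2[in_seiz]), max(base))
  expect_gt(median(ser$lambda2[in_seiz]), 4 * median(base))
})

test_that("per-window network frames satisfy the structural invariants", {
  rec <- make_recording(n_ch = 6, duration = 8, seed = 13)
  ser <- lambda2_series(rec, keep_networks = TRUE)
  for (nf in ser$network) {
    expect_true(all(nf$A >= 0 & nf$A <= 1))
    expect_equal(nf$A, t(nf$A))
    expect_true(all(diag(nf$A) == 0))
    expect_lt(max(abs(rowSums(nf$L))), 1e-12)
    ev <- eigen(nf$L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_gte(nf$lambda_n, nf$lambda2)
    expect_gte(nf$lambda2, 0)
  }
})
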