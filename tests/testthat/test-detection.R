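test_that("threshold detection confirms runs and reports first-crossing onsets", {
  cfg <- detector_config(threshold = 1, decision_time = 6, min_gap = 10)

  expect_equal(nrow(threshold_detect(flat_series(rep(0.5, 200)), cfg)), 0)

  # above threshold for exactly 6 s starting at t = 100
  v <- rep(0, 200)
  v[101:106] <- 2
  ev <- threshold_detect(flat_series(v), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 100)
  expect_equal(ev$confirm_time, 106)
  expect_equal(ev$offset, 106)

  # one second too short: not confirmed
  v5 <- rep(0, 200)
  v5[101:105] <- 2
  expect_equal(nrow(threshold_detect(flat_series(v5), cfg)), 0)

  # two confirmed bursts 5 s apart merge under min_gap = 30
  v2 <- rep(0, 200)
  v2[51:60] <- 2
  v2[66:75] <- 2
  merged <- threshold_detect(flat_series(v2),
                             detector_config(1, min_gap = 30))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$onset, 50)
  expect_equal(merged$offset, 75)
  apart <- threshold_detect(flat_series(v2), detector_config(1, min_gap = 3))
  expect_equal(nrow(apart), 2)
})

test_that("raising the threshold never increases detections or false positives", {
  # unimodal bursts: each excursion crosses any threshold at most once, so
  # super-level sets are nested and the event counts are monotone in theta
  v <- rep(0, 700)
  heights <- c(6, 3, 8, 2, 5, 4)
  centers <- c(100, 200, 300, 400, 500, 600)
  for (b in seq_along(centers)) {
    idx <- (centers[b] - 15):(centers[b] + 15)
    v[idx] <- heights[b] * (1 - abs(idx - centers[b]) / 16)
  }
  ann <- annotations_tbl(tibble::tibble(onset = c(80, 280), offset = c(120, 320)))
  prev_tp <- Inf
  prev_fp <- Inf
  for (theta in c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 7)) {
    cfg <- detector_config(theta, decision_time = 2, min_gap = 0)
    rep_ <- evaluate_detections(threshold_detect(flat_series(v), cfg), ann,
                                duration_h = 1 / 6, cfg)
    expect_lte(rep_$tp, prev_tp)
    expect_lte(rep_$fp, prev_fp)
    prev_tp <- rep_$tp
    prev_fp <- rep_$fp
  }
  expect_equal(prev_tp, 1)   # only the tallest annotated burst survives theta = 7
  expect_equal(prev_fp, 0)
})

test_that("threshold calibration follows mean + k sd with optional clipping", {
  expect_warning(theta <- calibrate_threshold(rep(2, 30), k = 6), "60 windows")
  expect_equal(theta, 2)

  withr::with_seed(99, {
    base <- rnorm(3600)
    expect_lt(abs(calibrate_threshold(base, k = 6) - 6), 0.3)
  })

  spiky <- c(rep(1, 200), 50)
  raw <- calibrate_threshold(spiky, k = 6)
  clipped <- calibrate_threshold(spiky, k = 6, clip_quantile = 0.99)
  expect_lt(clipped, raw)

  mt <- moving_threshold(flat_series(rnorm(400)), k = 6, width = 100)
  expect_length(mt, 400)
  expect_true(all(is.finite(mt)))
})

test_that("event scoring applies the matching window, delay and latency conventions", {
  cfg <- detector_config(1, decision_time = 6, pre_onset_tolerance = 10)
  ann <- annotations_tbl(tibble::tibble(onset = 100, offset = 140))

  ev <- tibble::tibble(onset = 104, confirm_time = 110, offset = 150)
  rep_ <- evaluate_detections(ev, ann, duration_h = 1, cfg)
  expect_equal(rep_$tp, 1)
  expect_equal(rep_$fp, 0)
  expect_equal(rep_$matches$delay_s, 4)
  expect_equal(rep_$matches$latency_s, 10)   # L = d + decision_time exactly

  early <- tibble::tibble(onset = 92, confirm_time = 98, offset = 120)
  expect_equal(evaluate_detections(early, ann, 1, cfg)$tp, 1)       # within tolerance
  expect_equal(evaluate_detections(early, ann, 1, cfg)$matches$delay_s, -8)
  too_early <- tibble::tibble(onset = 85, confirm_time = 91, offset = 120)
  expect_equal(evaluate_detections(too_early, ann, 1, cfg)$fp, 1)

  late <- tibble::tibble(onset = 141, confirm_time = 147, offset = 160)
  expect_equal(evaluate_detections(late, ann, 1, cfg)$fp, 1)        # after offset

  # two detections inside one seizure collapse to a single TP
  two <- tibble::tibble(onset = c(101, 120), confirm_time = c(107, 126),
                        offset = c(110, 130))
  rep2 <- evaluate_detections(two, ann, 1, cfg)
  expect_equal(rep2$tp, 1)
  expect_equal(rep2$fp, 0)
  expect_equal(rep2$matches$delay_s, 1)      # earliest detection is the match

  none <- evaluate_detections(tibble::tibble(onset = numeric(),
                                             confirm_time = numeric(),
                                             offset = numeric()),
                              annotations_tbl(tibble::tibble(onset = c(1, 50, 90),
                                                             offset = c(10, 60, 100))),
                              duration_h = 10, cfg)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fp_per_hour, 0)

  overlap <- tibble::tibble(onset = c(10, 15), offset = c(20, 30))
  expect_error(evaluate_detections(ev, overlap, 1, cfg), "overlap")
})

test_that("glance and tidy expose report counts and per-seizure matches", {
  cfg <- detector_config(1)
  ann <- annotations_tbl(tibble::tibble(onset = 100, offset = 140))
  ev <- tibble::tibble(onset = 104, confirm_time = 110, offset = 150)
  rep_ <- evaluate_detections(ev, ann, 2, cfg)
  g <- glance(rep_)
  expect_equal(g$n_seizures, 1)
  expect_equal(g$sensitivity_pct, 100)
  expect_equal(g$fp_per_hour, 0)
  expect_equal(nrow(tidy(rep_)), 1)
})

test_that("report pooling reproduces the published aggregation arithmetic", {
  ft <- aggregate_reports(chb_ft_table(), mode = "unweighted")
  expect_equal(ft$n_seizures, 94)
  expect_equal(ft$tp, 88)
  expect_equal(ft$fp, 99)
  expect_equal(round(ft$sensitivity_pct, 2), 93.62)
  expect_equal(round(ft$mean_latency_s, 2), 16.06)
  expect_equal(round(ft$mean_delay_s, 2), 10.06)

  icon <- aggregate_reports(chb_icon_table(), mode = "tp_weighted")
  expect_equal(icon$n_seizures, 198)
  expect_equal(icon$tp, 156)
  expect_equal(round(icon$sensitivity_pct, 2), 78.79)
  expect_equal(round(icon$mean_latency_s, 2), 4.44)
  # recomputation from the rounded per-patient rows gives -1.6853;
  # agree with the printed -1.68 to one unit in the last printed digit
  expect_lt(abs(icon$mean_delay_s - (-1.68)), 0.01)

  # pooled sensitivity is order-invariant
  shuffled <- chb_ft_table()[sample(17), ]
  expect_equal(aggregate_reports(shuffled)$sensitivity_pct, ft$sensitivity_pct)

  # a single report aggregates to itself
  cfg <- detector_config(1)
  ann <- annotations_tbl(tibble::tibble(onset = 100, offset = 140))
  ev <- tibble::tibble(onset = 104, confirm_time = 110, offset = 150)
  one <- evaluate_detections(ev, ann, 2, cfg)
  agg <- aggregate_reports(list(one))
  expect_equal(agg$sensitivity_pct, one$sensitivity)
  expect_equal(agg$mean_latency_s, one$mean_latency_s)
})
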