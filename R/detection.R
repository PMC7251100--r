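#' Detector configuration
#'
#' @param threshold detection threshold on the feature series (same units as
#'   `lambda2`).
#' @param decision_time confirmation period in seconds (default 6): the
#'   feature must stay above threshold at least this long before a seizure
#'   is declared. Transient artifacts shorter than the decision time can
#'   therefore never trigger a detection.
#' @param min_gap events separated by less than this many seconds are merged
#'   into one (default 10).
#' @param pre_onset_tolerance seconds before an annotated onset within which
#'   a detection still counts as a true positive (default 10; detectors
#'   driven by network features regularly fire slightly before the marked
#'   onset).
#' @return a `detector_config` object.
#' @export
detector_config <- function(threshold, decision_time = 6, min_gap = 10,
                            pre_onset_tolerance = 10) {
  assert_scalar_number(threshold, "threshold")
  assert_scalar_number(decision_time, "decision_time")
  if (decision_time < 0) stop_seizr("`decision_time` must be >= 0")
  assert_scalar_number(min_gap, "min_gap")
  assert_scalar_number(pre_onset_tolerance, "pre_onset_tolerance")
  structure(
    list(threshold = threshold, decision_time = decision_time,
         min_gap = min_gap, pre_onset_tolerance = pre_onset_tolerance),
    class = "detector_config"
  )
}

series_values <- function(series, value_col = NULL) {
  value_col <- value_col %||%
    intersect(c("ema", "lambda2", "value"), names(series))[[1]]
  if (is.na(value_col)) stop_seizr("no feature column found in series")
  list(time = series$time_s, value = series[[value_col]], col = value_col)
}

#' Threshold detection of seizure events
#'
#' Scans a feature series (window end times `time_s`, feature `lambda2` or
#' `ema`) for runs above the threshold. A run of windows is confirmed as an
#' event when it spans at least `decision_time` seconds; confirmed events
#' closer than `min_gap` seconds are merged. The reported `onset` is the
#' *start* of the first super-threshold window (the first crossing), so the
#' detection delay can be measured before the confirmation completes;
#' `confirm_time = onset + decision_time`; `offset` is the end of the last
#' super-threshold window.
#'
#' @param series a tibble with `time_s` and a feature column (`ema` is
#'   preferred over `lambda2` when both are present), e.g. from
#'   [lambda2_series()] or [synchronizability()].
#' @param config a [detector_config()].
#' @param value_col feature column name override.
#' @return a tibble of events: `onset`, `confirm_time`, `offset` (seconds).
#' @export
threshold_detect <- function(series, config, value_col = NULL) {
  stopifnot(inherits(config, "detector_config"))
  sv <- series_values(series, value_col)
  n <- length(sv$value)
  empty <- tibble::tibble(onset = numeric(), confirm_time = numeric(),
                          offset = numeric())
  if (n == 0) return(empty)
  hop <- if (n > 1) min(diff(sv$time)) else sv$time[[1]]
  above <- sv$value > config$threshold
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(
    first = starts[r$values],
    last = ends[r$values]
  )
  # window at time t covers (t - hop, t]; a run of m windows spans m * hop s
  runs$onset <- sv$time[runs$first] - hop
  runs$offset <- sv$time[runs$last]
  runs <- runs[runs$offset - runs$onset >= config$decision_time - 1e-9, ]
  if (nrow(runs) == 0) return(empty)

  merged <- runs[1, c("onset", "offset")]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs$onset[[i]] - merged$offset[[last]] < config$min_gap) {
        merged$offset[[last]] <- runs$offset[[i]]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, c("onset", "offset")])
      }
    }
  }
  tibble::tibble(
    onset = merged$onset,
    confirm_time = merged$onset + config$decision_time,
    offset = merged$offset
  )
}

#' Calibrate a detection threshold from baseline activity
#'
#' The published pipeline fixes a constant per-patient threshold by visual
#' inspection; this helper automates the spirit of that choice as
#' `theta = mean + k * sd` over a seizure-free stretch of the feature
#' series. Optionally the baseline is clipped at an upper quantile first, so
#' that rare high spikes do not inflate the spread.
#'
#' @param baseline numeric vector of baseline feature values (no annotated
#'   seizures), or a series tibble.
#' @param k number of standard deviations above the mean (default 6).
#' @param clip_quantile optional upper quantile (e.g. 0.99) at which the
#'   baseline is clipped before computing mean and sd.
#' @param value_col feature column when `baseline` is a tibble.
#' @return the threshold `theta`.
#' @export
calibrate_threshold <- function(baseline, k = 6, clip_quantile = NULL,
                                value_col = NULL) {
  if (is.data.frame(baseline)) baseline <- series_values(baseline, value_col)$value
  baseline <- baseline[is.finite(baseline)]
  if (length(baseline) < 60) {
    warning("baseline shorter than 60 windows; threshold may be unstable")
  }
  if (!is.null(clip_quantile)) {
    hi <- stats::quantile(baseline, clip_quantile, names = FALSE)
    baseline <- pmin(baseline, hi)
  }
  mean(baseline) + k * stats::sd(baseline)
}

#' Moving-average threshold series
#'
#' A time-varying variant of [calibrate_threshold()]: at each window the
#' threshold is the mean plus `k` standard deviations of the most recent
#' `width` seconds of the feature (trailing window, current sample
#' excluded; the first `width` seconds fall back to the global statistics).
#'
#' @param series a feature series tibble.
#' @param k standard-deviation multiplier.
#' @param width trailing window in seconds (default 300).
#' @param value_col feature column override.
#' @return numeric vector of per-window thresholds.
#' @export
moving_threshold <- function(series, k = 6, width = 300, value_col = NULL) {
  sv <- series_values(series, value_col)
  n <- length(sv$value)
  hop <- if (n > 1) min(diff(sv$time)) else 1
  w <- max(2L, round(width / hop))
  out <- numeric(n)
  glob <- mean(sv$value) + k * stats::sd(sv$value)
  for (t in seq_len(n)) {
    if (t <= w) {
      out[[t]] <- glob
    } else {
      recent <- sv$value[(t - w):(t - 1L)]
      out[[t]] <- mean(recent) + k * stats::sd(recent)
    }
  }
  out
}

#' Score detected events against annotations
#'
#' Event-level evaluation: a detected event is a true positive when its
#' onset falls in `[annotated onset - pre_onset_tolerance, annotated
#' offset]`; at most one detection counts per annotated seizure (extra
#' detections inside the same seizure are absorbed, not penalized as false
#' positives only if they also overlap the annotation; events after the
#' offset are false positives). For each matched seizure the delay is
#' `d = detected onset - annotated onset` and the latency adds the decision
#' time, `L = d + decision_time`.
#'
#' @param events event tibble from [threshold_detect()].
#' @param annotations annotated intervals ([annotations_tbl()]).
#' @param duration_h recording duration in hours (> 0), for the false-alarm
#'   rate.
#' @param config the [detector_config()] used for detection.
#' @return a `detection_report`: list with counts (`n_seizures`, `tp`,
#'   `fp`), rates (`sensitivity` in percent, `fp_per_hour`), the per-seizure
#'   match table `matches` (columns `onset`, `offset`, `detected`,
#'   `delay_s`, `latency_s`) and the input `events` with a `label` column
#'   (`"TP"`/`"FP"`).
#' @export
evaluate_detections <- function(events, annotations, duration_h, config) {
  stopifnot(inherits(config, "detector_config"))
  assert_scalar_number(duration_h, "duration_h", positive = TRUE)
  ann <- annotations_tbl(annotations)
  if (nrow(ann) > 1 && any(ann$onset[-1] < ann$offset[-nrow(ann)])) {
    stop_seizr("annotations overlap; merge them first")
  }
  events <- tibble::as_tibble(events)
  label <- rep("FP", nrow(events))
  matches <- tibble::tibble(
    onset = ann$onset, offset = ann$offset,
    detected = FALSE, delay_s = NA_real_, latency_s = NA_real_
  )
  for (s in seq_len(nrow(ann))) {
    lo <- ann$onset[[s]] - config$pre_onset_tolerance
    hi <- ann$offset[[s]]
    cand <- which(label == "FP" & events$onset >= lo & events$onset <= hi)
    if (length(cand) > 0) {
      first <- cand[[which.min(events$onset[cand])]]
      label[[first]] <- "TP"
      # later detections within the same annotated seizure are absorbed
      inside <- cand[events$onset[cand] <= hi]
      label[setdiff(inside, first)] <- "dup"
      matches$detected[[s]] <- TRUE
      matches$delay_s[[s]] <- events$onset[[first]] - ann$onset[[s]]
      matches$latency_s[[s]] <- matches$delay_s[[s]] + config$decision_time
    }
  }
  tp <- sum(label == "TP")
  fp <- sum(label == "FP")
  ns <- nrow(ann)
  events$label <- ifelse(label == "dup", "TP", label)
  structure(
    list(
      n_seizures = ns, tp = tp, fp = fp,
      sensitivity = if (ns == 0) NA_real_ else 100 * tp / ns,
      fp_per_hour = fp / duration_h,
      duration_h = duration_h,
      mean_delay_s = mean(matches$delay_s, na.rm = TRUE),
      mean_latency_s = mean(matches$latency_s, na.rm = TRUE),
      matches = matches,
      events = events,
      config = config
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> NS = %d, TP = %d, FP = %d | S = %s%%, FP/h = %.3g\n",
    x$n_seizures, x$tp, x$fp,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f", x$sensitivity)),
    x$fp_per_hour
  ))
  if (x$tp > 0) {
    cat(sprintf("  mean delay %.2f s, mean latency %.2f s over %d matched seizure(s)\n",
                x$mean_delay_s, x$mean_latency_s, x$tp))
  }
  invisible(x)
}

#' @describeIn evaluate_detections one-row summary tibble of a report
#'   (NS/TP/FP, sensitivity, FP/h, mean delay and latency).
#' @param x a `detection_report`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.detection_report <- function(x, ...) {
  tibble::tibble(
    n_seizures = x$n_seizures, tp = x$tp, fp = x$fp,
    sensitivity_pct = x$sensitivity,
    fp_per_hour = x$fp_per_hour,
    mean_delay_s = x$mean_delay_s,
    mean_latency_s = x$mean_latency_s,
    duration_h = x$duration_h
  )
}

#' @describeIn evaluate_detections per-annotated-seizure match table.
#' @exportS3Method generics::tidy
tidy.detection_report <- function(x, ...) x$matches

#' Pool per-patient detection reports
#'
#' Counts (`NS`, `TP`, `FP`) are pooled by summation and the pooled
#' sensitivity is `100 * sum(TP) / sum(NS)` regardless of patient order.
#' The timing columns support two published aggregation conventions:
#' `"unweighted"` averages each patient's mean delay/latency with equal
#' weight, `"tp_weighted"` weights each patient by its true-positive count
#' (equivalently, averages over matched seizures).
#'
#' @param reports a list of `detection_report`s, or a summary table with
#'   columns `n_seizures`, `tp`, `fp`, `mean_delay_s`, `mean_latency_s`
#'   (and optionally `fp_per_hour`), one row per patient.
#' @param mode `"unweighted"` or `"tp_weighted"`.
#' @return a one-row tibble with pooled counts, pooled sensitivity (percent),
#'   mean latency/delay under the requested mode, and the mean per-patient
#'   false-alarm rate when available.
#' @export
aggregate_reports <- function(reports, mode = c("unweighted", "tp_weighted")) {
  mode <- match.arg(mode)
  if (inherits(reports, "detection_report")) reports <- list(reports)
  tbl <- if (is.data.frame(reports)) {
    tibble::as_tibble(reports)
  } else {
    if (length(reports) == 0) stop_seizr("no reports to aggregate")
    dplyr::bind_rows(lapply(reports, glance.detection_report))
  }
  if (nrow(tbl) == 0) stop_seizr("no reports to aggregate")
  w <- switch(mode, unweighted = rep(1, nrow(tbl)), tp_weighted = tbl$tp)
  wmean <- function(v) {
    keep <- !is.na(v) & w > 0
    if (!any(keep)) return(NA_real_)
    sum(v[keep] * w[keep]) / sum(w[keep])
  }
  tibble::tibble(
    n_patients = nrow(tbl),
    n_seizures = sum(tbl$n_seizures),
    tp = sum(tbl$tp),
    fp = sum(tbl$fp),
    sensitivity_pct = 100 * sum(tbl$tp) / sum(tbl$n_seizures),
    mean_latency_s = wmean(tbl$mean_latency_s),
    mean_delay_s = wmean(tbl$mean_delay_s),
    mean_fp_per_hour = if ("fp_per_hour" %in% names(tbl)) {
      mean(tbl$fp_per_hour)
    } else {
      NA_real_
    },
    mode = mode
  )
}

#' Write detected events to CSV
#'
#' @param events event tibble (optionally with a `label` column).
#' @param path output path; columns `onset_s,confirm_s,offset_s,label`.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- tibble::tibble(
    onset_s = events$onset,
    confirm_s = events$confirm_time,
    offset_s = events$offset,
    label = if ("label" %in% names(events)) events$label else NA_character_
  )
  readr::write_csv(out, path)
  invisible(path)
}
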