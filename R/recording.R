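#' Multichannel EEG recording
#'
#' An `eeg_recording` bundles a channels-by-samples signal matrix with its
#' sampling rate, channel labels, a start-time offset and (optionally) a table
#' of annotated seizure intervals. It is the common currency of the package:
#' readers produce it, the preprocessing and network-inference stages consume
#' it, and the synthetic generators emit it.
#'
#' @param data numeric matrix, channels x samples (microvolts for scalp EEG).
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to
#'   `rownames(data)` or `ch01`, `ch02`, ...
#' @param start_time offset of the first sample in seconds (default 0).
#' @param annotations a data frame with `onset`/`offset` columns in seconds
#'   (see [annotations_tbl()]), or `NULL` for none.
#'
#' @return an object of class `eeg_recording`: a list with elements `data`,
#'   `fs`, `labels`, `start_time`, `annotations`.
#' @examples
#' rec <- new_recording(matrix(rnorm(512), 2, 256), fs = 256)
#' rec
#' @export
new_recording <- function(data, fs, labels = NULL, start_time = 0,
                          annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_seizr("`data` must be a numeric channels x samples matrix")
  }
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (anyNA(data)) stop_seizr("`data` contains NA values")
  labels <- labels %||% rownames(data) %||% sprintf("ch%02d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop_seizr("`labels` length must equal the number of channels")
  }
  if (anyDuplicated(labels)) stop_seizr("channel labels must be unique")
  rownames(data) <- labels
  annotations <- annotations_tbl(annotations)
  structure(
    list(
      data = data,
      fs = fs,
      labels = as.character(labels),
      start_time = start_time,
      annotations = annotations
    ),
    class = "eeg_recording"
  )
}

#' Seizure annotation table
#'
#' Normalizes seizure intervals to a tibble with numeric `onset` and `offset`
#' columns (seconds from recording start), sorted by onset. Each interval must
#' satisfy `0 <= onset < offset`.
#'
#' @param x `NULL`, a data frame with `onset`/`offset` columns, or a numeric
#'   matrix/vector coercible to one.
#' @return a tibble with columns `onset`, `offset`.
#' @export
annotations_tbl <- function(x = NULL) {
  if (is.null(x)) {
    return(tibble::tibble(onset = numeric(), offset = numeric()))
  }
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2L) {
    x <- tibble::tibble(onset = x[[1]], offset = x[[2]])
  }
  x <- tibble::as_tibble(as.data.frame(x))
  if (!all(c("onset", "offset") %in% names(x))) {
    stop_seizr("annotations need `onset` and `offset` columns")
  }
  x <- dplyr::arrange(x[, c("onset", "offset")], .data$onset)
  if (nrow(x) > 0 && any(x$onset < 0)) stop_seizr("annotation onset < 0")
  if (any(x$offset <= x$onset)) {
    stop_seizr("annotation offset must exceed onset")
  }
  x
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples (%.6g s @ %g Hz)\n",
    nrow(x$data), ncol(x$data), dur, x$fs
  ))
  if (nrow(x$annotations) > 0) {
    cat(sprintf("  %d annotated seizure interval(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Recording duration in seconds
#' @param rec an [new_recording()] object.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs
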