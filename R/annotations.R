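#' Read seizure annotations
#'
#' Parses annotated seizure intervals from either a simple CSV file with
#' `onset,offset` columns (seconds from recording start) or a CHB-MIT style
#' summary text file (`Seizure Start Time: 2996 seconds` / `Seizure End
#' Time: 3036 seconds` blocks, optionally grouped under `File Name:` lines).
#' The dialect is autodetected from the file extension (`.csv` vs `.txt`)
#' unless given explicitly.
#'
#' @param path path to the annotation file.
#' @param dialect `"auto"` (default), `"csv"` or `"chbmit"`.
#' @param file for the CHB-MIT dialect: restrict to the seizures listed under
#'   this `File Name:` entry (e.g. `"chb01_03.edf"`). `NULL` returns all.
#' @param overlap what to do with overlapping intervals: `"error"` (default)
#'   or `"merge"` (union of overlapping intervals).
#' @return a tibble of intervals as from [annotations_tbl()], sorted and
#'   non-overlapping.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("onset,offset", "10,25"), f)
#' read_annotations(f)
#' @export
read_annotations <- function(path, dialect = c("auto", "csv", "chbmit"),
                             file = NULL, overlap = c("error", "merge")) {
  dialect <- match.arg(dialect)
  overlap <- match.arg(overlap)
  if (!file.exists(path)) stop_seizr(sprintf("annotation file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "chbmit"
  }
  ann <- switch(dialect,
    csv = read_annotations_csv(path),
    chbmit = read_annotations_chbmit(path, file = file)
  )
  ann <- annotations_tbl(ann)
  resolve_overlaps(ann, overlap)
}

read_annotations_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  tbl <- readr::read_csv(
    I(paste(lines, collapse = "\n")),
    col_names = !grepl("^[0-9.+-]", lines[[1]]),
    show_col_types = FALSE
  )
  if (ncol(tbl) < 2) stop_seizr("annotation CSV needs two columns: onset,offset")
  names(tbl)[1:2] <- c("onset", "offset")
  tbl[, 1:2]
}

read_annotations_chbmit <- function(path, file = NULL) {
  lines <- readLines(path, warn = FALSE)
  current_file <- NA_character_
  onset <- offset <- numeric()
  files <- character()
  pending <- NA_real_
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*File Name\\s*:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 2) {
      current_file <- m[[2]]
      next
    }
    m <- regmatches(ln, regexec("Seizure.*Start Time\\s*:\\s*([0-9.]+)\\s*sec", ln))[[1]]
    if (length(m) == 2) {
      pending <- as.numeric(m[[2]])
      next
    }
    m <- regmatches(ln, regexec("Seizure.*End Time\\s*:\\s*([0-9.]+)\\s*sec", ln))[[1]]
    if (length(m) == 2) {
      if (is.na(pending)) stop_seizr("CHB-MIT summary: end time without start time")
      onset <- c(onset, pending)
      offset <- c(offset, as.numeric(m[[2]]))
      files <- c(files, current_file)
      pending <- NA_real_
    }
  }
  tbl <- tibble::tibble(onset = onset, offset = offset, file = files)
  if (!is.null(file)) tbl <- tbl[!is.na(tbl$file) & tbl$file == file, ]
  tbl[, c("onset", "offset")]
}

resolve_overlaps <- function(ann, overlap) {
  if (nrow(ann) < 2) return(ann)
  overlaps <- ann$onset[-1] < ann$offset[-nrow(ann)]
  if (!any(overlaps)) return(ann)
  if (overlap == "error") {
    stop_seizr("overlapping annotation intervals (use overlap = \"merge\")")
  }
  merged <- ann[1, ]
  for (i in 2:nrow(ann)) {
    last <- nrow(merged)
    if (ann$onset[[i]] < merged$offset[[last]]) {
      merged$offset[[last]] <- max(merged$offset[[last]], ann$offset[[i]])
    } else {
      merged <- dplyr::bind_rows(merged, ann[i, ])
    }
  }
  merged
}

#' Write annotations to CSV
#'
#' @param ann annotation tibble ([annotations_tbl()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann <- annotations_tbl(ann)
  readr::write_csv(ann, path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' The CSV layout is samples in rows, channels in columns (one named column
#' per channel); the sampling rate travels separately since CSV has no
#' header metadata.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @return an `eeg_recording`.
#' @export
read_csv_recording <- function(path, fs) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  new_recording(t(as.matrix(tbl)), fs = fs, labels = names(tbl))
}

#' Write a recording to CSV
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_recording <- function(rec, path) {
  tbl <- tibble::as_tibble(t(rec$data))
  names(tbl) <- rec$labels
  readr::write_csv(tbl, path)
  invisible(path)
}
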