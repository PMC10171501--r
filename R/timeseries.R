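#' ROI time-series objects
#'
#' An `roi_timeseries` wraps one subject's T x m matrix of BOLD-like signals
#' (rows = volumes, columns = regions of interest), the repetition time, and
#' the ROI labels.
#'
#' @param data Numeric T x m matrix, all entries finite, T >= 2, m >= 2.
#' @param tr Repetition time in seconds (> 0).
#' @param subject_id Subject identifier.
#' @param roi_labels Character vector of m unique ROI labels; defaults to the
#'   column names of `data` or `ROI_001`-style labels.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr, subject_id = "subject", roi_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data) %||% sprintf("ROI_%03d", seq_len(ncol(data)))
  }
  validate_roi_timeseries(data, tr, subject_id, roi_labels)
  colnames(data) <- roi_labels
  structure(
    list(subject_id = as.character(subject_id), data = data, tr = as.numeric(tr),
         roi_labels = as.character(roi_labels)),
    class = "roi_timeseries"
  )
}

validate_roi_timeseries <- function(data, tr, subject_id, roi_labels) {
  if (!is.numeric(tr) || length(tr) != 1 || !is.finite(tr) || tr <= 0) {
    abort("`tr` must be a single positive number of seconds.")
  }
  if (nrow(data) < 2 || ncol(data) < 2) {
    abort("time series must have T >= 2 volumes and m >= 2 ROIs.")
  }
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-finite value for subject '%s' at row %d, column %d ('%s').",
      subject_id, bad[1, 1], bad[1, 2], roi_labels[bad[1, 2]]
    ))
  }
  if (anyDuplicated(roi_labels)) {
    abort(sprintf("duplicate ROI labels: %s",
                  paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject '%s': %d volumes x %d ROIs, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Read an ROI time-series TSV
#'
#' Expects a tab-separated file with a header row of ROI labels and one row
#' per volume. Malformed files (ragged rows, non-numeric or non-finite
#' cells, duplicate labels) raise an error naming the offending location.
#'
#' @param path Path to the TSV file.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject identifier; defaults to the file name stem.
#' @return An [roi_timeseries()] object with column order preserved.
#' @export
read_timeseries <- function(path, tr, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                        na = character(), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed time-series file '%s': row %d, column %d (%s).",
      path, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  mat <- as.matrix(df)
  roi_timeseries(mat, tr = tr, subject_id = subject_id, roi_labels = colnames(df))
}

#' Write an ROI time-series TSV
#'
#' @param ts An [roi_timeseries()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  readr::write_tsv(as_tibble(as.data.frame(ts$data)), path, progress = FALSE)
  invisible(path)
}
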