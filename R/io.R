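#' Read and write minute-epoch CSV files
#'
#' The epoch CSV format has a header and two columns: `timestamp` (ISO-8601,
#' minute resolution) and `counts` (nonnegative, or `NA` for an explicit
#' gap). Reading validates the file: malformed rows are reported with their
#' line number, timestamps must be strictly increasing with no duplicated
#' minutes, and counts must be nonnegative where present. The write-read
#' round trip is lossless to sub-microsecond count precision.
#'
#' @param path File path.
#' @return `read_epoch_csv()` returns a minute-epoch tibble (`time`,
#'   `counts`); `write_epoch_csv()` returns `path` invisibly.
#' @export
read_epoch_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    counts = readr::col_double()
  ), progress = FALSE))
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed epoch CSV: first bad row at line %d (%s)",
                  pr$row[1] + 1L, pr$expected[1]))
  }
  if (!all(c("timestamp", "counts") %in% names(raw))) {
    abort("epoch CSV must have columns `timestamp` and `counts`")
  }
  if (anyNA(raw$timestamp)) {
    abort(sprintf("malformed epoch CSV: unparseable timestamp at line %d",
                  which(is.na(raw$timestamp))[1] + 1L))
  }
  dt <- diff(as.numeric(raw$timestamp))
  if (any(dt == 0)) {
    abort(sprintf("duplicated minute at line %d", which(dt == 0)[1] + 2L))
  }
  if (any(dt < 0)) {
    abort(sprintf("non-monotone timestamps at line %d", which(dt < 0)[1] + 2L))
  }
  if (any(raw$counts < 0, na.rm = TRUE)) {
    abort(sprintf("negative counts at line %d",
                  which(raw$counts < 0)[1] + 1L))
  }
  tibble(time = raw$timestamp, counts = raw$counts)
}

#' @rdname read_epoch_csv
#' @param epochs Minute-epoch data frame (`time`, `counts`).
#' @export
write_epoch_csv <- function(epochs, path) {
  stopifnot(is.data.frame(epochs), all(c("time", "counts") %in% names(epochs)))
  out <- tibble(
    timestamp = format(epochs$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    counts = epochs$counts
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write raw accelerometry CSV files
#'
#' Format: header `timestamp, ax, ay, az`, accelerations in g-units,
#' timestamps at the sampling resolution (fractional seconds allowed).
#'
#' @param path File path.
#' @return `read_accel_csv()` returns a tibble (`time`, `ax`, `ay`, `az`)
#'   with the inferred `"sample_rate"` attribute.
#' @export
read_accel_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    ax = readr::col_double(), ay = readr::col_double(),
    az = readr::col_double()
  ), progress = FALSE))
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed accel CSV: first bad row at line %d", pr$row[1] + 1L))
  }
  out <- tibble(time = raw$timestamp, ax = raw$ax, ay = raw$ay, az = raw$az)
  attr(out, "sample_rate") <- infer_sample_rate(out$time)
  out
}

#' @rdname read_accel_csv
#' @param accel Accelerometry data frame (`time`, `ax`, `ay`, `az`).
#' @export
write_accel_csv <- function(accel, path) {
  stopifnot(is.data.frame(accel), all(c("time", "ax", "ay", "az") %in% names(accel)))
  out <- tibble(
    timestamp = format(accel$time, "%Y-%m-%dT%H:%M:%OS4", tz = "UTC"),
    ax = accel$ax, ay = accel$ay, az = accel$az
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write cohort metadata CSV files
#'
#' Format: `participant_id, group, barthel_index, four_at` (scores integer;
#' `four_at` may be `NA` where the instrument was not administered).
#'
#' @param path File path.
#' @return A tibble with the four columns above.
#' @export
read_cohort_csv <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    barthel_index = readr::col_integer(),
    four_at = readr::col_integer()
  ), progress = FALSE))
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed cohort CSV: first bad row at line %d", pr$row[1] + 1L))
  }
  if (any(raw$barthel_index < 0 | raw$barthel_index > 100, na.rm = TRUE)) {
    abort("barthel_index outside [0, 100]")
  }
  if (any(raw$four_at < 0 | raw$four_at > 12, na.rm = TRUE)) {
    abort("four_at outside [0, 12]")
  }
  if (anyDuplicated(raw$participant_id)) {
    abort("duplicated participant_id")
  }
  as_tibble(raw)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame with at least the four metadata columns.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("participant_id", "group", "barthel_index", "four_at")
  stopifnot(is.data.frame(cohort), all(cols %in% names(cohort)))
  readr::write_csv(cohort[, cols], path, progress = FALSE)
  invisible(path)
}
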