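#' Hourly-averaged activity profile
#'
#' Collapses a minute-epoch series into the hourly series that underlies the
#' nonparametric rhythm indicators: one value per clock hour per day, the
#' mean of that hour's sixty minute-counts. The series must span whole
#' calendar days (1440-minute blocks starting at local midnight). Minutes may
#' be `NA` (explicit gaps); an hour with fewer than `min_valid_minutes` valid
#' minutes is marked invalid and its activity set to `NA`.
#'
#' @param epochs A minute-epoch data frame with columns `time` (POSIXct,
#'   consecutive minutes starting at midnight) and `counts`, or a bare
#'   numeric vector of minute counts assumed to start at midnight.
#' @param min_days Minimum number of whole days required (default 7).
#' @param min_valid_minutes Minimum valid minutes for an hour to count
#'   (default 45).
#' @return A tibble with columns `day` (1-based), `hour` (0-23), `activity`
#'   (hourly mean, `NA` if invalid), `n_valid`, `valid`.
#' @export
#' @examples
#' e <- simulate_epochs(rhythm_params(), seed = 1)
#' h <- hourly_average(e)
hourly_average <- function(epochs, min_days = 7, min_valid_minutes = 45) {
  counts <- epoch_counts(epochs)
  nd <- length(counts) %/% 1440L
  if (nd < min_days) {
    abort(sprintf("insufficient days: %d whole day(s) present, %d required",
                  nd, min_days))
  }
  m <- matrix(counts[seq_len(nd * 1440L)], nrow = 60L)
  n_valid <- colSums(!is.na(m))
  activity <- suppressWarnings(colMeans(m, na.rm = TRUE))
  valid <- n_valid >= min_valid_minutes
  activity[!valid] <- NA_real_
  activity[valid & n_valid == 0] <- NA_real_
  tibble(
    day = rep(seq_len(nd), each = 24L),
    hour = rep(0:23, nd),
    activity = activity,
    n_valid = as.integer(n_valid),
    valid = valid
  )
}

# Extract the minute-count vector from an epoch data frame (validating
# midnight alignment and minute spacing) or pass a numeric vector through.
epoch_counts <- function(epochs) {
  if (is.numeric(epochs)) {
    if (length(epochs) < 1440L) abort("series must cover at least one whole day")
    return(as.double(epochs))
  }
  if (!is.data.frame(epochs) || !all(c("time", "counts") %in% names(epochs))) {
    abort("`epochs` must be a data frame with columns `time` and `counts`")
  }
  tm <- epochs$time
  if (nrow(epochs) < 2) abort("series must cover at least one whole day")
  dt <- as.double(diff(as.numeric(tm)))
  if (any(abs(dt - 60) > 1e-6)) {
    abort("epoch series must be consecutive one-minute epochs with no implicit gaps")
  }
  lt <- as.POSIXlt(tm[1])
  if (lt$hour != 0 || lt$min != 0) {
    abort("epoch series must start at local midnight (whole-day blocks)")
  }
  if (nrow(epochs) %% 1440L != 0L) {
    abort("epoch series must span whole days (multiple of 1440 minutes)")
  }
  as.double(epochs$counts)
}

# hourly activity matrix (24 x days) of valid days only; errors mirrored from
# the indicator definitions
valid_day_hours <- function(hourly) {
  stopifnot(is.data.frame(hourly), all(c("day", "hour", "activity") %in% names(hourly)))
  nd <- max(hourly$day)
  m <- matrix(hourly$activity, nrow = 24L)
  ok <- !apply(m, 2, anyNA)
  list(m = m[, ok, drop = FALSE], kept = which(ok), dropped = which(!ok))
}

#' Interdaily stability (IS)
#'
#' The fraction of the hourly series' variance explained by its average
#' 24-hour profile:
#' \deqn{IS = \frac{N \sum_{h=1}^{p} (\bar{X}_h - \bar{X})^2}
#'                 {p \sum_{i=1}^{N} (X_i - \bar{X})^2}}
#' where \eqn{X_i} are the `N` hourly averaged counts, \eqn{\bar{X}_h} the
#' 24-point daily template (`p = 24`) and \eqn{\bar{X}} the grand mean.
#' IS lies in `[0, 1]`; 1 means every day repeats the same profile, and the
#' expectation under unstructured noise is approximately `1 / day_count`.
#'
#' Days containing any invalid hour are excluded before the computation.
#'
#' @param hourly Output of [hourly_average()], or a numeric vector of hourly
#'   values whose length is a multiple of 24.
#' @return A single number in `[0, 1]`.
#' @export
interdaily_stability <- function(hourly) {
  x <- hourly_values(hourly)
  nd <- length(x) / 24
  if (nd < 2) abort("interdaily stability needs at least 2 complete days")
  xb <- mean(x)
  ss_tot <- sum((x - xb)^2)
  if (ss_tot < 1e-24) abort("undefined: constant series has no rhythm variance")
  tmpl <- rowMeans(matrix(x, nrow = 24L))
  length(x) * sum((tmpl - xb)^2) / (24 * ss_tot)
}

#' Intradaily variability (IV)
#'
#' The normalised mean squared successive difference of the hourly series:
#' \deqn{IV = \frac{N \sum_{i=2}^{N} (X_i - X_{i-1})^2}
#'                 {(N-1) \sum_{i=1}^{N} (X_i - \bar{X})^2}}
#' IV quantifies the frequency and extent of transitions between rest and
#' activity. A smooth 24-hour sinusoid gives IV near
#' `2 * (1 - cos(2*pi/24))` (about 0.07), unstructured noise gives about 2,
#' and a series alternating between two values every hour attains 4.
#'
#' @inheritParams interdaily_stability
#' @return A single nonnegative number.
#' @export
intradaily_variability <- function(hourly) {
  x <- hourly_values(hourly, require_full_days = FALSE)
  if (length(x) < 3) abort("intradaily variability needs at least 3 hourly values")
  xb <- mean(x)
  ss_tot <- sum((x - xb)^2)
  if (ss_tot < 1e-24) abort("undefined: constant series has no rhythm variance")
  n <- length(x)
  n * sum(diff(x)^2) / ((n - 1) * ss_tot)
}

hourly_values <- function(hourly, require_full_days = TRUE) {
  if (is.numeric(hourly)) {
    if (require_full_days && length(hourly) %% 24L != 0L) {
      abort("hourly vector length must be a multiple of 24")
    }
    if (anyNA(hourly)) abort("hourly vector must not contain NA; use hourly_average()")
    return(as.double(hourly))
  }
  v <- valid_day_hours(hourly)
  if (ncol(v$m) == 0) abort("no complete days left after exclusions")
  as.double(v$m)
}

# Scan all fully-contained (or circularly wrapped) windows of a single day's
# minute counts. NA minutes are ignored within a window mean.
window_scan <- function(day_counts, wrap = FALSE) {
  has_na <- anyNA(day_counts)
  scan1 <- function(x, width, which_fun) {
    n <- 1440L
    if (wrap) x <- c(x, x[seq_len(width - 1L)])
    n_starts <- if (wrap) n else n - width + 1L
    starts <- seq_len(n_starts)
    if (has_na) {
      nav <- is.na(x)
      xs <- x
      xs[nav] <- 0
      cs <- cumsum(c(0, xs))
      cn <- cumsum(c(0L, !nav))
      ns <- cn[starts + width] - cn[starts]
      means <- (cs[starts + width] - cs[starts]) / ns
      means[ns == 0L] <- NA_real_
    } else {
      cs <- cumsum(c(0, x))
      means <- (cs[starts + width] - cs[starts]) / width
    }
    # earliest onset among ties, robust to cumulative-sum rounding
    best <- which_fun(means)
    tol <- 1e-9 * max(1, abs(means[best]))
    k <- which(abs(means - means[best]) <= tol)[1]
    list(value = means[k], onset = k - 1L)
  }
  m10 <- scan1(day_counts, 600L, which.max)
  l5 <- scan1(day_counts, 300L, which.min)
  list(m10 = m10$value, m10_onset = m10$onset,
       l5 = l5$value, l5_onset = l5$onset)
}

# hourly-resolution variant: windows over the day's 24 hourly means
window_scan_hourly <- function(day_counts, wrap = FALSE) {
  h <- colMeans(matrix(day_counts, nrow = 60L), na.rm = TRUE)
  scan1 <- function(width, which_fun) {
    x <- if (wrap) c(h, h[seq_len(width - 1L)]) else h
    starts <- seq_len(if (wrap) 24L else 24L - width + 1L)
    means <- vapply(starts, function(s) mean(x[s:(s + width - 1L)]), numeric(1))
    k <- which_fun(means)
    list(value = means[k], onset = (k - 1L) * 60L)
  }
  m10 <- scan1(10L, which.max)
  l5 <- scan1(5L, which.min)
  list(m10 = m10$value, m10_onset = m10$onset,
       l5 = l5$value, l5_onset = l5$onset)
}

#' Per-day most-active-10h and least-active-5h windows
#'
#' For each calendar day, finds the 10 consecutive hours with the highest
#' mean activity (M10) and the 5 consecutive hours with the lowest (L5) by a
#' moving-average scan, by default at one-minute resolution over windows
#' fully contained in the day. Ties are broken by the earliest clock time.
#' Onsets are reported as minutes after midnight.
#'
#' A day is excluded (and flagged, not silently dropped) when any of its
#' hours has fewer than `min_valid_minutes` valid minutes.
#'
#' @inheritParams hourly_average
#' @param wrap If `TRUE`, windows may wrap circularly across the day
#'   boundary, which suits night-spanning sleep; the default confines windows
#'   to each 24-hour block.
#' @param resolution `"minute"` (600/300-minute windows at 1-minute steps,
#'   the default) or `"hour"` (10/5-hour windows over hourly means).
#' @return A tibble with columns `day`, `m10`, `m10_onset`, `l5`, `l5_onset`
#'   (onsets in minutes after midnight; `NA` rows mark excluded days) and
#'   `valid`.
#' @export
m10_l5_by_day <- function(epochs, min_valid_minutes = 45, wrap = FALSE,
                          resolution = c("minute", "hour")) {
  resolution <- match.arg(resolution)
  counts <- epoch_counts(epochs)
  nd <- length(counts) %/% 1440L
  if (nd < 1) abort("insufficient days: need at least one whole day")
  dm <- matrix(counts[seq_len(nd * 1440L)], nrow = 1440L)
  scan_fun <- if (resolution == "minute") window_scan else window_scan_hourly
  m10 <- l5 <- rep(NA_real_, nd)
  m10o <- l5o <- rep(NA_integer_, nd)
  valid <- logical(nd)
  for (d in seq_len(nd)) {
    x <- dm[, d]
    if (anyNA(x)) {
      hv <- 60L - colSums(matrix(is.na(x), nrow = 60L))
      if (any(hv < min_valid_minutes)) next
    }
    s <- scan_fun(x, wrap = wrap)
    m10[d] <- s$m10
    m10o[d] <- as.integer(s$m10_onset)
    l5[d] <- s$l5
    l5o[d] <- as.integer(s$l5_onset)
    valid[d] <- TRUE
  }
  tibble(day = seq_len(nd), m10 = m10, m10_onset = m10o,
         l5 = l5, l5_onset = l5o, valid = valid)
}

#' Relative amplitude from composite M10 and L5
#'
#' `RA = (M10 - L5) / (M10 + L5)`: the dimensionless strength of the
#' day-night activity contrast, in `[0, 1]`. Defined whenever `M10 + L5 > 0`;
#' a zero L5 with positive M10 gives the maximal value 1.
#'
#' @param m10 Composite most-active-10h mean activity (>= 0).
#' @param l5 Composite least-active-5h mean activity (>= 0).
#' @return A number in `[0, 1]` (`NA` when `m10 + l5` is 0).
#' @export
#' @examples
#' relative_amplitude(38.91, 9.67)  # ~0.60
relative_amplitude <- function(m10, l5) {
  if (any(m10 < l5, na.rm = TRUE)) {
    abort("`m10` must be at least `l5`: M10 is a maximum, L5 a minimum")
  }
  out <- ifelse(m10 + l5 > 0, (m10 - l5) / (m10 + l5), NA_real_)
  out
}

#' Nonparametric rest-activity rhythm metrics of one recording
#'
#' Computes the five indicators of a minute-epoch recording: interdaily
#' stability (IS) and intradaily variability (IV) from the hourly series,
#' composite M10 and L5 as the across-day means of the per-day window values,
#' and relative amplitude from the composites, `RA = (M10 - L5)/(M10 + L5)`.
#' Days with missing hours are excluded from all five and reported.
#'
#' @inheritParams m10_l5_by_day
#' @param min_days Minimum number of usable whole days (default 7, the
#'   conventional floor for these indicators).
#' @param allow_insufficient If `TRUE`, proceed (with a warning) below
#'   `min_days` instead of erroring; IS/IV are `NA` when fewer than 2 days
#'   remain.
#' @return An object of class `rar_metrics`: a list with elements `is`,
#'   `iv`, `m10`, `l5`, `ra`, `per_day` (the [m10_l5_by_day()] table),
#'   `n_days_used`, `days_excluded` and `options`. Has [tidy()], [glance()],
#'   `print()` and [autoplot()] methods.
#' @export
#' @examples
#' e <- simulate_epochs(rhythm_params(mesor = 3, amplitude = 40), seed = 2)
#' m <- rar_metrics(e)
#' glance(m)
rar_metrics <- function(epochs, min_days = 7, min_valid_minutes = 45,
                        wrap = FALSE, resolution = c("minute", "hour"),
                        allow_insufficient = FALSE) {
  resolution <- match.arg(resolution)
  counts <- epoch_counts(epochs)
  per_day <- m10_l5_by_day(counts, min_valid_minutes = min_valid_minutes,
                           wrap = wrap, resolution = resolution)
  used <- per_day$day[per_day$valid]
  if (length(used) < min_days) {
    msg <- sprintf("insufficient days: %d usable day(s), %d required",
                   length(used), min_days)
    if (!allow_insufficient) abort(msg)
    warn(paste0(msg, " (proceeding: `allow_insufficient = TRUE`)"))
  }
  # hourly values of the retained days, as interdaily_stability()/
  # intradaily_variability() would see them via hourly_average()
  nd <- length(counts) %/% 1440L
  hm <- suppressWarnings(
    colMeans(matrix(counts[seq_len(nd * 1440L)], nrow = 60L), na.rm = TRUE)
  )
  hx <- as.double(matrix(hm, nrow = 24L)[, used, drop = FALSE])
  safe <- function(f, x) tryCatch(f(x), error = function(e) NA_real_)
  is_v <- if (length(used) >= 2) safe(interdaily_stability, hx) else NA_real_
  iv_v <- if (length(used) >= 1) safe(intradaily_variability, hx) else NA_real_
  m10 <- mean(per_day$m10[per_day$valid])
  l5 <- mean(per_day$l5[per_day$valid])
  ra <- if (length(used)) relative_amplitude(m10, l5) else NA_real_
  structure(
    list(
      is = is_v, iv = iv_v,
      m10 = if (length(used)) m10 else NA_real_,
      l5 = if (length(used)) l5 else NA_real_,
      ra = ra,
      per_day = per_day,
      n_days_used = length(used),
      days_excluded = per_day$day[!per_day$valid],
      options = list(min_days = min_days,
                     min_valid_minutes = min_valid_minutes,
                     wrap = wrap, resolution = resolution)
    ),
    class = "rar_metrics"
  )
}

#' @export
print.rar_metrics <- function(x, ...) {
  cat("Rest-activity rhythm metrics\n")
  cat(sprintf("  IS  %.2f   IV  %.2f\n", x$is, x$iv))
  cat(sprintf("  M10 %.2f   L5  %.2f   RA %.2f\n", x$m10, x$l5, x$ra))
  cat(sprintf("  days used: %d", x$n_days_used))
  if (length(x$days_excluded)) {
    cat(sprintf("  (excluded: %s)", paste(x$days_excluded, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @rdname rar_metrics
#' @param x A `rar_metrics` object.
#' @param ... Unused.
#' @method tidy rar_metrics
#' @export
tidy.rar_metrics <- function(x, ...) {
  tibble(
    metric = c("is", "iv", "m10", "l5", "ra"),
    value = c(x$is, x$iv, x$m10, x$l5, x$ra)
  )
}

#' @rdname rar_metrics
#' @method glance rar_metrics
#' @export
glance.rar_metrics <- function(x, ...) {
  tibble(is = x$is, iv = x$iv, m10 = x$m10, l5 = x$l5, ra = x$ra,
         n_days_used = x$n_days_used,
         n_days_excluded = length(x$days_excluded))
}
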