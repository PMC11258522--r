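#' Combine tri-axial acceleration into a movement magnitude
#'
#' Removes the quasi-static (gravity and posture) component from each axis
#' with a centred 10-second moving mean, then combines the residuals into the
#' per-sample Euclidean norm. The output is a nonnegative movement magnitude
#' at the original sampling rate.
#'
#' @param accel Data frame with columns `time`, `ax`, `ay`, `az` (g-units),
#'   e.g. from [simulate_accel()] or [read_accel_csv()].
#' @param gravity_window Moving-mean window in seconds (default 10). Windows
#'   are truncated (not padded) at the recording edges.
#' @param sample_rate Samples per second; inferred from `time` when `NULL`.
#' @return A tibble with columns `time` and `value` (nonnegative magnitude),
#'   with the sampling rate in the `"sample_rate"` attribute.
#' @export
combine_axes <- function(accel, gravity_window = 10, sample_rate = NULL) {
  if (!is.data.frame(accel) || !all(c("time", "ax", "ay", "az") %in% names(accel))) {
    abort("`accel` must have columns `time`, `ax`, `ay`, `az`")
  }
  if (nrow(accel) == 0) abort("empty recording")
  fs <- sample_rate %||% infer_sample_rate(accel$time)
  w <- max(1L, round(gravity_window * fs))
  dx <- accel$ax - running_mean(accel$ax, w)
  dy <- accel$ay - running_mean(accel$ay, w)
  dz <- accel$az - running_mean(accel$az, w)
  out <- tibble(time = accel$time, value = sqrt(dx^2 + dy^2 + dz^2))
  attr(out, "sample_rate") <- fs
  out
}

# centred moving mean with truncated (partial) windows at the edges
running_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

infer_sample_rate <- function(tm) {
  if (length(tm) < 2) abort("cannot infer sample rate from fewer than 2 samples")
  dt <- median(diff(as.numeric(tm)))
  if (!is.finite(dt) || dt <= 0) abort("non-increasing timestamps")
  fs <- 1 / dt
  round(fs)
}

#' Zero-phase Butterworth bandpass of a movement series
#'
#' Applies a 4th-order Butterworth bandpass (default 0.5-3 Hz, the wrist
#' movement band) forward and backward, giving zero phase shift and doubling
#' the stopband attenuation. Edge samples are retained, not trimmed.
#'
#' @param series Data frame with columns `time` and `value`, e.g. from
#'   [combine_axes()].
#' @param low,high Band edges in Hz; `high` must be below the Nyquist
#'   frequency.
#' @param order Butterworth design order per band edge (default 4).
#' @param sample_rate Samples per second; inferred when `NULL`.
#' @return A tibble with columns `time` and `value` (signed, zero-mean in the
#'   passband sense).
#' @export
bandpass <- function(series, low = 0.5, high = 3, order = 4, sample_rate = NULL) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    abort("`series` must have columns `time` and `value`")
  }
  fs <- sample_rate %||% attr(series, "sample_rate") %||% infer_sample_rate(series$time)
  if (high >= fs / 2) {
    abort(sprintf("upper band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
                  high, fs / 2))
  }
  if (low <= 0 || low >= high) abort("band edges must satisfy 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- tibble(time = series$time,
                value = signal::filtfilt(bf, series$value))
  attr(out, "sample_rate") <- fs
  out
}

#' Integrate a filtered movement series into minute acti-counts
#'
#' Rectifies the filtered signal, zeroes samples at or below `threshold`,
#' sums the surviving samples within each consecutive 2-second segment, and
#' reports each minute's acti-count as the mean of its thirty 2-second sums.
#' A trailing partial minute is dropped.
#'
#' @param series Data frame with columns `time` and `value` (a filtered
#'   movement magnitude, signed).
#' @param threshold Activity floor in the same units as `value` (default
#'   0.01 g); samples at or below it are discarded. Must be nonnegative.
#' @param segment Integration segment length in seconds (default 2).
#' @param sample_rate Samples per second; inferred when `NULL`.
#' @return A minute-epoch tibble with columns `time` (minute-aligned) and
#'   `counts` (nonnegative).
#' @export
integrate_epochs <- function(series, threshold = 0.01, segment = 2,
                             sample_rate = NULL) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    abort("`series` must have columns `time` and `value`")
  }
  if (threshold < 0) abort("`threshold` must be nonnegative")
  fs <- sample_rate %||% attr(series, "sample_rate") %||% infer_sample_rate(series$time)
  seg_len <- segment * fs
  if (abs(seg_len - round(seg_len)) > 1e-9) {
    abort("`sample_rate` must divide into whole integration segments")
  }
  seg_len <- as.integer(round(seg_len))
  seg_per_min <- as.integer(round(60 / segment))
  n_min <- length(series$value) %/% (60L * fs)
  if (n_min < 1) abort("series must span at least one whole minute")
  v <- abs(series$value[seq_len(n_min * 60L * fs)])
  v[v <= threshold] <- 0
  seg_sums <- colSums(matrix(v, nrow = seg_len))
  counts <- colMeans(matrix(seg_sums, nrow = seg_per_min))
  tibble(
    time = series$time[1] + 60 * (seq_len(n_min) - 1),
    counts = counts
  )
}

#' Raw accelerometry to minute acti-counts
#'
#' The full preprocessing chain: [combine_axes()] (gravity removal and
#' Euclidean combination), [bandpass()] (0.5-3 Hz zero-phase Butterworth) and
#' [integrate_epochs()] (thresholded 2-second integration averaged per
#' minute).
#'
#' @inheritParams combine_axes
#' @inheritParams bandpass
#' @inheritParams integrate_epochs
#' @return A minute-epoch tibble (`time`, `counts`).
#' @export
#' @examples
#' p <- rhythm_params(mesor = 3, amplitude = 30)
#' acc <- simulate_accel(p, sample_rate = 16, seed = 1, duration_minutes = 5)
#' derive_counts(acc)
derive_counts <- function(accel, low = 0.5, high = 3, threshold = 0.01,
                          gravity_window = 10, order = 4, segment = 2,
                          sample_rate = NULL) {
  fs <- sample_rate %||% attr(accel, "sample_rate") %||% infer_sample_rate(accel$time)
  accel |>
    combine_axes(gravity_window = gravity_window, sample_rate = fs) |>
    bandpass(low = low, high = high, order = order, sample_rate = fs) |>
    integrate_epochs(threshold = threshold, segment = segment, sample_rate = fs)
}
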