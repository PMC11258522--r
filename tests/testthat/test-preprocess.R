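accel_df <- function(ax, ay, az, fs,
                     start = as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) {
  out <- tibble::tibble(
    time = start + (seq_along(ax) - 1) / fs,
    ax = ax, ay = ay, az = az
  )
  attr(out, "sample_rate") <- fs
  out
}

test_that("pure gravity combines to an exactly zero movement magnitude", {
  fs <- 20
  n <- fs * 120
  acc <- accel_df(rep(0, n), rep(0, n), rep(1, n), fs)
  out <- combine_axes(acc)
  expect_true(all(out$value == 0))
})

test_that("a single-axis sinusoid survives axis combination as its rectified envelope", {
  fs <- 20
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  a <- 0.4
  acc <- accel_df(a * sin(2 * pi * 1 * t), rep(0, length(t)), rep(1, length(t)), fs)
  out <- combine_axes(acc)
  interior <- out$value[(10 * fs):(50 * fs)]
  expect_equal(max(interior), a, tolerance = 0.02)
  # rectified-sine pattern: interior troughs reach ~0
  expect_lt(min(interior), 0.02 * a)
})

test_that("axis combination equals a direct per-sample loop oracle", {
  fs <- 10
  set.seed(31)
  n <- 200
  ax <- rnorm(n); ay <- rnorm(n); az <- 1 + rnorm(n)
  out <- combine_axes(accel_df(ax, ay, az, fs), gravity_window = 2)
  w <- 2 * fs  # window in samples
  half <- w %/% 2
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    oracle[i] <- sqrt((ax[i] - mean(ax[lo:hi]))^2 +
                      (ay[i] - mean(ay[lo:hi]))^2 +
                      (az[i] - mean(az[lo:hi]))^2)
  }
  expect_equal(out$value, oracle, tolerance = 1e-12)
})

test_that("an empty recording is rejected", {
  acc <- tibble::tibble(time = as.POSIXct(character()), ax = numeric(),
                        ay = numeric(), az = numeric())
  expect_error(combine_axes(acc), "empty")
})

test_that("the bandpass keeps the movement band and rejects drift and high frequencies", {
  fs <- 30
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  series <- function(f) {
    s <- tibble::tibble(time = as.POSIXct("2023-03-06", tz = "UTC") + t,
                        value = sin(2 * pi * f * t))
    attr(s, "sample_rate") <- fs
    s
  }
  interior <- function(y) y[round(length(y) * 0.3):round(length(y) * 0.7)]
  g15 <- max(abs(interior(bandpass(series(1.5))$value)))
  expect_gte(g15, 0.89)
  expect_lte(g15, 1.12)
  expect_lte(max(abs(interior(bandpass(series(0.05))$value))), 0.1)
  expect_lte(max(abs(interior(bandpass(series(10))$value))), 0.1)
  z <- series(1); z$value <- 0 * z$value
  expect_true(all(bandpass(z)$value == 0))
})

test_that("a band edge at or above Nyquist is rejected", {
  fs <- 5
  t <- seq(0, 10, by = 1 / fs)
  s <- tibble::tibble(time = as.POSIXct("2023-03-06", tz = "UTC") + t,
                      value = rnorm(length(t)))
  expect_error(bandpass(s, high = 3, sample_rate = fs), "Nyquist")
})

sample_series <- function(values, fs,
                          start = as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) {
  s <- tibble::tibble(time = start + (seq_along(values) - 1) / fs, value = values)
  attr(s, "sample_rate") <- fs
  s
}

test_that("epoch integration implements the 2-second-sum / minute-mean rule", {
  fs <- 10
  # sub-threshold signal integrates to zero
  v <- rep(0.005, fs * 120)
  expect_true(all(integrate_epochs(sample_series(v, fs), threshold = 0.01)$counts == 0))
  # one aligned 2-s burst of constant value v in minute 2 -> (2*fs*v)/30
  v <- rep(0, fs * 180)
  v[(60 * fs + 20 * fs + 1):(60 * fs + 22 * fs)] <- 0.5
  counts <- integrate_epochs(sample_series(v, fs), threshold = 0.01)$counts
  expect_equal(counts, c(0, 2 * fs * 0.5 / 30, 0), tolerance = 1e-12)
  # threshold 0, constant value -> every minute 2*fs*v
  v <- rep(0.3, fs * 120)
  counts <- integrate_epochs(sample_series(v, fs), threshold = 0)$counts
  expect_equal(counts, rep(2 * fs * 0.3, 2), tolerance = 1e-12)
})

test_that("epoch integration rejects bad thresholds and short series", {
  fs <- 10
  expect_error(integrate_epochs(sample_series(rep(1, fs * 120), fs),
                                threshold = -1), "nonnegative")
  expect_error(integrate_epochs(sample_series(rep(1, fs * 30), fs)),
               "whole minute")
})

test_that("acti-counts are nonnegative and scale exactly with movement amplitude", {
  fs <- 16
  set.seed(41)
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  move <- rnorm(length(t), 0, 0.05) * sin(2 * pi * 1.3 * t)
  acc1 <- accel_df(move, rep(0, length(t)), rep(1, length(t)), fs)
  acc3 <- accel_df(3 * move, rep(0, length(t)), rep(1, length(t)), fs)
  c1 <- derive_counts(acc1, threshold = 0)$counts
  c3 <- derive_counts(acc3, threshold = 0)$counts
  expect_true(all(c1 >= 0))
  expect_equal(c3, 3 * c1, tolerance = 1e-9)
})

test_that("a perturbation confined to one minute only reaches adjacent epochs", {
  fs <- 10
  n <- fs * 600  # 10 minutes
  base <- rep(0, n)
  pert <- base
  m <- 5  # 1-based minute index of the perturbation
  idx <- ((m - 1) * 60 * fs + 25 * fs + 1):((m - 1) * 60 * fs + 27 * fs)
  pert[idx] <- 0.6 * sin(2 * pi * 1.5 * seq_along(idx) / fs)
  c_base <- derive_counts(accel_df(base, base, 1 + base, fs))$counts
  c_pert <- derive_counts(accel_df(pert, 0 * pert, 1 + 0 * pert, fs))$counts
  changed <- which(abs(c_pert - c_base) > 1e-9)
  expect_true(all(changed >= m - 1 & changed <= m + 1))
  expect_true(m %in% changed)
})

test_that("epoch CSV files round-trip losslessly and reject corrupt input", {
  e <- simulate_epochs(rhythm_params(mesor = 2, amplitude = 25), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(e, path)
  back <- read_epoch_csv(path)
  expect_equal(nrow(back), 7 * 1440)
  expect_equal(back$counts, e$counts, tolerance = 1e-9)
  expect_equal(as.numeric(back$time), as.numeric(e$time))

  dup <- readLines(path)
  writeLines(c(dup, dup[2]), path)
  expect_error(read_epoch_csv(path), "monotone|duplicated")

  writeLines(c("timestamp,counts",
               "2023-03-06T00:00:00,1.0",
               "2023-03-06T00:01:00,not-a-number"), path)
  expect_error(read_epoch_csv(path), "line 3|malformed")
})

test_that("accel and cohort CSV files round-trip and validate score ranges", {
  p <- rhythm_params(mesor = 3, amplitude = 30)
  acc <- simulate_accel(p, sample_rate = 10, seed = 2, duration_minutes = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(acc, path)
  back <- read_accel_csv(path)
  expect_equal(back$ax, acc$ax, tolerance = 1e-4)
  expect_equal(attr(back, "sample_rate"), 10)

  co <- tibble::tibble(participant_id = c("P1", "P2"), group = c("a", "b"),
                       barthel_index = c(40L, 55L), four_at = c(2L, NA))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, cpath)
  expect_equal(read_cohort_csv(cpath), co)
  bad <- co; bad$barthel_index[1] <- 101L
  write_cohort_csv(bad, cpath)
  expect_error(read_cohort_csv(cpath), "barthel")
})
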