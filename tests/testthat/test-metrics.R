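test_that("hourly averaging reduces minutes to per-hour means", {
  x <- rep(2.5, 2 * 1440)
  h <- hourly_average(x, min_days = 2)
  expect_equal(nrow(h), 48)
  expect_true(all(h$activity == 2.5))

  x <- rep(0, 1440 * 2)
  x[5 * 60 + 7] <- 60  # one minute of 60 inside hour 5 of day 1
  h <- hourly_average(x, min_days = 2)
  expect_equal(h$activity[h$day == 1 & h$hour == 5], 1)
  expect_true(all(h$activity[!(h$day == 1 & h$hour == 5)] == 0))

  set.seed(8)
  x <- rexp(2 * 1440)
  h <- hourly_average(x, min_days = 2)
  oracle <- vapply(seq_len(48), function(k) {
    mean(x[((k - 1) * 60 + 1):(k * 60)])
  }, numeric(1))
  expect_equal(h$activity, oracle, tolerance = 1e-12)

  expect_error(hourly_average(x, min_days = 3), "insufficient days")
})

test_that("IS, IV, M10 and L5 match nested-loop oracles on toy series", {
  set.seed(17)
  for (rep_i in 1:5) {
    nd <- sample(2:3, 1)
    counts <- rexp(nd * 1440, rate = 1 / 10) *
      rep(1 + sin(2 * pi * seq_len(1440) / 1440), nd)
    h <- hourly_average(counts, min_days = nd)
    expect_equal(interdaily_stability(h), oracle_is(h$activity),
                 tolerance = 1e-12)
    expect_equal(intradaily_variability(h), oracle_iv(h$activity),
                 tolerance = 1e-12)
    pd <- m10_l5_by_day(counts)
    for (d in seq_len(nd)) {
      o <- oracle_m10_l5(counts[((d - 1) * 1440 + 1):(d * 1440)])
      expect_equal(pd$m10[d], o$m10, tolerance = 1e-12)
      expect_equal(pd$l5[d], o$l5, tolerance = 1e-12)
      expect_equal(pd$m10_onset[d], o$m10_onset)
      expect_equal(pd$l5_onset[d], o$l5_onset)
    }
  }
})

test_that("IS is exactly 1 for identical days and errors on a constant series", {
  day <- 1 + sin(2 * pi * (0:23) / 24)
  x <- rep(day, 7)
  expect_equal(interdaily_stability(x), 1, tolerance = 1e-12)
  expect_error(interdaily_stability(rep(3, 48)), "constant")
  expect_error(interdaily_stability(day), "2 complete days")
})

test_that("IV attains its closed-form values on canonical series", {
  expect_equal(intradaily_variability(rep(c(1, 5), 24)), 4, tolerance = 1e-12)
  x <- sin(2 * pi * (0:167) / 24)
  expect_lt(abs(intradaily_variability(x) - 2 * (1 - cos(2 * pi / 24))), 0.005)
  expect_error(intradaily_variability(c(1, 2)), "at least 3")
  expect_error(intradaily_variability(rep(1, 24)), "constant")
})

test_that("M10/L5 window search finds block extremes with earliest-onset ties", {
  day <- c(rep(10, 600), rep(0, 840))
  pd <- m10_l5_by_day(day)
  expect_equal(pd$m10, 10)
  expect_equal(pd$m10_onset, 0)
  expect_equal(pd$l5, 0)
  expect_equal(pd$l5_onset, 600)

  pd <- m10_l5_by_day(rep(4.2, 1440))
  expect_equal(pd$m10, 4.2)
  expect_equal(pd$l5, 4.2)
  expect_equal(pd$m10_onset, 0)  # all windows tie; earliest wins
  expect_equal(pd$l5_onset, 0)
})

test_that("composite metrics follow the averaged-windows-then-RA rule", {
  set.seed(23)
  counts <- rexp(7 * 1440) * rep(1 + pmax(0, sin(2 * pi * seq_len(1440) / 1440)), 7)
  m <- rar_metrics(counts)
  pd <- m$per_day
  expect_equal(m$m10, mean(pd$m10))
  expect_equal(m$l5, mean(pd$l5))
  expect_equal(m$ra, (m$m10 - m$l5) / (m$m10 + m$l5), tolerance = 1e-12)
  expect_true(m$is >= 0 && m$is <= 1)
  expect_true(m$iv >= 0)
  expect_true(m$m10 >= m$l5)
  expect_equal(tidy(m)$value, c(m$is, m$iv, m$m10, m$l5, m$ra))
  expect_equal(glance(m)$n_days_used, 7)
})

test_that("relative amplitude handles its boundary cases", {
  expect_equal(relative_amplitude(10, 0), 1)
  expect_true(is.na(relative_amplitude(0, 0)))
  expect_error(relative_amplitude(1, 2), "at least")
})

test_that("too few usable days errors unless explicitly overridden", {
  p <- rhythm_params(mesor = 3, amplitude = 30)
  e <- simulate_epochs(p, seed = 9)
  expect_error(rar_metrics(e, min_days = 8), "insufficient days")
  expect_warning(m <- rar_metrics(e, min_days = 8, allow_insufficient = TRUE),
                 "insufficient days")
  expect_equal(m$n_days_used, 7)
})

test_that("days with missing hours are excluded and reported, partial hours tolerated", {
  p <- rhythm_params(mesor = 3, amplitude = 30, n_days = 8)
  counts <- simulate_epochs(p, seed = 10)$counts
  # day 3, hour 6: 20 missing minutes -> hour invalid -> day excluded
  counts[(2 * 1440) + (6 * 60) + (1:20)] <- NA
  # day 5, hour 2: 10 missing minutes -> hour still valid
  counts[(4 * 1440) + (2 * 60) + (1:10)] <- NA
  m <- rar_metrics(counts, min_days = 7)
  expect_equal(m$n_days_used, 7)
  expect_equal(m$days_excluded, 3)
  expect_false(any(is.na(c(m$is, m$iv, m$m10, m$l5, m$ra))))
})

test_that("metrics are scale invariant and window values scale linearly", {
  counts <- simulate_epochs(rhythm_params(mesor = 3, amplitude = 30), seed = 12)$counts
  m1 <- rar_metrics(counts)
  mk <- rar_metrics(3.7 * counts)
  expect_equal(mk$is, m1$is, tolerance = 1e-12)
  expect_equal(mk$iv, m1$iv, tolerance = 1e-12)
  expect_equal(mk$ra, m1$ra, tolerance = 1e-12)
  expect_equal(mk$m10, 3.7 * m1$m10, tolerance = 1e-12)
  expect_equal(mk$l5, 3.7 * m1$l5, tolerance = 1e-12)
})

test_that("a circular whole-hour shift leaves metrics unchanged and shifts onsets", {
  day <- 2 + pmax(0, 30 * cos(2 * pi * ((0:1439) / 60 - 14) / 24)) +
    rep(runif(48, 0, 2), each = 30)
  x <- rep(day, 7)  # identical days -> series is 24 h periodic
  shift <- 180L
  day_s <- c(day[(shift + 1):1440], day[1:shift])
  xs <- rep(day_s, 7)
  m1 <- rar_metrics(x, wrap = TRUE)
  m2 <- rar_metrics(xs, wrap = TRUE)
  expect_equal(m2$is, m1$is, tolerance = 1e-9)
  # IV differs only in which day-boundary transition the finite series omits
  expect_lt(abs(m2$iv - m1$iv), 1e-3)
  expect_equal(m2$ra, m1$ra, tolerance = 1e-9)
  expect_equal(m2$m10, m1$m10, tolerance = 1e-9)
  expect_equal(m2$l5, m1$l5, tolerance = 1e-9)
  expect_equal(m2$per_day$m10_onset,
               (m1$per_day$m10_onset - shift) %% 1440L)
  expect_equal(m2$per_day$l5_onset,
               (m1$per_day$l5_onset - shift) %% 1440L)
})

test_that("wrap-allowing windows recover activity blocks that span midnight", {
  day <- rep(0, 1440)
  day[c(1:300, (1440 - 299):1440)] <- 10  # 600 active minutes across midnight
  nowrap <- m10_l5_by_day(day)
  wrapped <- m10_l5_by_day(day, wrap = TRUE)
  expect_lt(nowrap$m10, 10)
  expect_equal(wrapped$m10, 10)
  expect_equal(wrapped$m10_onset, 1140)
})

test_that("hour-resolution windows agree with minute resolution on hour-constant data", {
  day <- rep(runif(24, 0, 20), each = 60)
  x <- rep(day, 2)
  pm <- m10_l5_by_day(x)
  ph <- m10_l5_by_day(x, resolution = "hour")
  expect_equal(ph$m10, pm$m10, tolerance = 1e-12)
  expect_equal(ph$l5, pm$l5, tolerance = 1e-12)
})

test_that("estimated relative amplitude recovers the generator's amplitude ordering", {
  set.seed(91)
  amps <- runif(200, 5, 60)
  ras <- vapply(seq_along(amps), function(i) {
    p <- rhythm_params(mesor = 3, amplitude = amps[i], phase_jitter_sd = 1,
                       frag_rate = 0.01, burst_sigma = 1.2, noise_sd = 1.5)
    rar_metrics(simulate_epochs(p, seed = 5000 + i))$ra
  }, numeric(1))
  expect_gt(cor(amps, ras, method = "spearman"), 0.8)
})
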