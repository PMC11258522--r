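#' Simulate a minute-epoch activity series
#'
#' Draws a rest-activity series of `n_days * 1440` one-minute acti-counts
#' from the process described in [rhythm_params()]: a rectified-cosine
#' diurnal envelope with day-to-day phase and amplitude jitter, multiplied by
#' a two-state rest/active Markov chain and lognormal burst noise, plus
#' additive noise, truncated at zero. The same `(params, seed)` pair always
#' yields an identical series; the caller's RNG state is left untouched.
#'
#' @param params A [rhythm_params()] object.
#' @param seed Integer seed.
#' @param start Start timestamp (minute-aligned, at local midnight). Default
#'   a fixed Monday midnight, UTC.
#' @return A tibble with columns `time` (POSIXct, one row per minute) and
#'   `counts` (nonnegative activity units/min).
#' @export
#' @examples
#' e <- simulate_epochs(rhythm_params(mesor = 3, amplitude = 30), seed = 7)
#' nrow(e)  # 7 * 1440
simulate_epochs <- function(params, seed,
                            start = as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) {
  counts <- simulate_epoch_counts(params, seed)
  tibble(
    time = start + 60 * (seq_along(counts) - 1),
    counts = counts
  )
}

# bare numeric fast path used by simulate_epochs() and the cohort generator
simulate_epoch_counts <- function(params, seed) {
  stopifnot(inherits(params, "rhythm_params"))
  withr::with_seed(as.integer(seed), {
    nd <- params$n_days
    n <- nd * 1440L
    tod <- rep(seq.int(0L, 1439L), nd) / 60
    acro_d <- params$acrophase + rnorm(nd, 0, params$phase_jitter_sd)
    amp_d <- pmax(0, params$amplitude + rnorm(nd, 0, params$amp_jitter_sd))
    env <- pmax(0, cos(2 * pi * (tod - rep(acro_d, each = 1440L)) / 24)) *
      rep(amp_d, each = 1440L) + params$mesor
    state <- cumsum(rbinom(n, 1L, params$frag_rate)) %% 2  # 0 = active
    mult <- 1 - state * (1 - params$rest_level)
    burst <- if (params$burst_sigma > 0) {
      exp(rnorm(n, -params$burst_sigma^2 / 2, params$burst_sigma))
    } else {
      1
    }
    noise <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
    pmax(0, env * mult * burst + noise)
  })
}

#' Simulate a raw tri-axial accelerometer recording
#'
#' Emits tri-axial samples in g-units: a constant gravity offset on the z
#' axis, movement bursts (one-second band-limited oscillations in roughly
#' 0.8-2.8 Hz whose occurrence probability follows the same envelope-times-
#' fragmentation process as [simulate_epochs()]), and wideband sensor noise.
#' Intended as input for the [derive_counts()] preprocessing chain.
#'
#' @param params A [rhythm_params()] object.
#' @param sample_rate Samples per second (integer Hz, >= 10 so the 0.5-3 Hz
#'   movement band is representable; below 6 Hz is rejected as aliasing).
#' @param seed Integer seed.
#' @param duration_minutes Length of the recording; defaults to the full
#'   `n_days * 1440`. Short recordings are useful for testing the
#'   preprocessing chain without gigabytes of samples.
#' @param burst_rate Scale of the per-second burst occurrence probability
#'   (0 disables movement entirely).
#' @param burst_amp Peak acceleration of a movement burst (g).
#' @param accel_noise_sd Sensor noise standard deviation (g; 0 disables).
#' @param start Start timestamp.
#' @return A tibble with columns `time`, `ax`, `ay`, `az`, carrying the
#'   sampling rate in the `"sample_rate"` attribute.
#' @export
simulate_accel <- function(params, sample_rate = 30, seed,
                           duration_minutes = NULL,
                           burst_rate = 0.6, burst_amp = 0.08,
                           accel_noise_sd = 0.003,
                           start = as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) {
  stopifnot(inherits(params, "rhythm_params"))
  if (sample_rate < 6) {
    abort("`sample_rate` below 6 Hz aliases the 0.5-3 Hz movement band")
  }
  if (sample_rate != round(sample_rate)) {
    abort("`sample_rate` must be a whole number of Hz")
  }
  sample_rate <- as.integer(sample_rate)
  dur <- as.integer(duration_minutes %||% (params$n_days * 1440L))
  stopifnot(dur >= 1)
  withr::with_seed(as.integer(seed), {
    nd <- params$n_days
    tod <- (seq_len(dur) - 1) %% 1440L / 60
    day_of <- (seq_len(dur) - 1) %/% 1440L + 1L
    acro_d <- params$acrophase + rnorm(nd, 0, params$phase_jitter_sd)
    amp_d <- pmax(0, params$amplitude + rnorm(nd, 0, params$amp_jitter_sd))
    env <- pmax(0, cos(2 * pi * (tod - acro_d[day_of]) / 24)) * amp_d[day_of] +
      params$mesor
    state <- cumsum(rbinom(dur, 1L, params$frag_rate)) %% 2
    intensity <- env * (1 - state * (1 - params$rest_level))
    # per-second burst process
    n_sec <- dur * 60L
    p_burst <- pmin(0.95, burst_rate * rep(intensity, each = 60L) /
                      (params$mesor + params$amplitude + 1e-12))
    is_burst <- rbinom(n_sec, 1L, p_burst) == 1L
    freq <- runif(n_sec, 0.8, 2.8)
    phase <- runif(n_sec, 0, 2 * pi)
    theta <- runif(n_sec, 0, 2 * pi)
    z <- runif(n_sec, -1, 1)  # uniform direction on the sphere
    dir <- cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
    n <- n_sec * sample_rate
    tau <- rep(seq.int(0L, sample_rate - 1L), n_sec) / sample_rate
    a_s <- ifelse(is_burst, burst_amp, 0)
    osc <- rep(a_s, each = sample_rate) *
      sin(2 * pi * rep(freq, each = sample_rate) * tau + rep(phase, each = sample_rate))
    noise <- if (accel_noise_sd > 0) {
      matrix(rnorm(3 * n, 0, accel_noise_sd), ncol = 3)
    } else {
      matrix(0, nrow = n, ncol = 3)
    }
    out <- tibble(
      time = start + (seq_len(n) - 1) / sample_rate,
      ax = osc * rep(dir[, 1], each = sample_rate) + noise[, 1],
      ay = osc * rep(dir[, 2], each = sample_rate) + noise[, 2],
      az = 1 + osc * rep(dir[, 3], each = sample_rate) + noise[, 3]
    )
    attr(out, "sample_rate") <- sample_rate
    out
  })
}

#' Simulate a two-group cohort with linked clinical scores
#'
#' Draws per-participant rhythm parameters from the group distributions of a
#' [cohort_spec()], simulates each participant's minute-epoch series, and
#' assigns Barthel Index and (where administered) 4AT scores through the
#' spec's score links. Barthel Index increases with the participant's
#' standardised diurnal amplitude and day-to-day stability; 4AT decreases
#' with the standardised relative amplitude of the participant's noiseless
#' envelope. Scores are rounded and clipped to instrument ranges.
#'
#' Child seeds are derived deterministically from `spec$seed`, so the cohort
#' (including every epoch series) is byte-identical across runs.
#'
#' @param spec A [cohort_spec()], e.g. [paperlike_spec()].
#' @param epochs_as `"tibble"` (default) stores each participant's series as
#'   a minute-epoch tibble; `"counts"` stores bare count vectors, which every
#'   metrics function also accepts — useful in large simulation studies.
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   `barthel_index`, `four_at` (NA where not administered), the latent
#'   generator values `true_mesor`, `true_amplitude`, `true_phase_jitter`,
#'   and a list-column `epochs` of minute-epoch tibbles.
#' @seealso [compute_cohort_metrics()], [run_study()]
#' @export
simulate_cohort <- function(spec, epochs_as = c("tibble", "counts")) {
  epochs_as <- match.arg(epochs_as)
  stopifnot(inherits(spec, "cohort_spec"))
  gnames <- names(spec$groups)
  n <- spec$n_per_group
  draw_group <- function(gi) {
    g <- spec$groups[[gi]]
    purrr::map(seq_len(n), function(i) {
      idx <- (gi - 1L) * n + i
      withr::with_seed(child_seed(spec$seed, idx), {
        mesor <- max(0.3, rnorm(1, g$mesor_mean, g$mesor_sd))
        amplitude <- max(5, rnorm(1, g$amplitude_mean, g$amplitude_sd))
        acrophase <- rnorm(1, g$acrophase_mean, g$acrophase_sd) %% 24
        pj <- max(0.2, rnorm(1, g$phase_jitter_mean, g$phase_jitter_sd))
        list(
          participant_id = sprintf("P%03d", idx),
          group = gnames[gi],
          params = rhythm_params(
            mesor = mesor, amplitude = amplitude, acrophase = acrophase,
            phase_jitter_sd = pj, frag_rate = g$frag_rate,
            rest_level = g$rest_level, burst_sigma = g$burst_sigma,
            noise_sd = g$noise_sd, n_days = g$n_days
          ),
          sim_seed = child_seed(spec$seed, idx + 10000L),
          four_at_given = isTRUE(g$four_at)
        )
      })
    })
  }
  people <- c(draw_group(1L), draw_group(2L))
  mesor <- vapply(people, function(p) p$params$mesor, numeric(1))
  amplitude <- vapply(people, function(p) p$params$amplitude, numeric(1))
  pj <- vapply(people, function(p) p$params$phase_jitter_sd, numeric(1))
  # latent envelope relative amplitude, from the noiseless daily envelope
  ra_env <- vapply(seq_along(people), function(i) {
    env <- envelope_minutes(mesor[i], amplitude[i],
                            people[[i]]$params$acrophase)
    o <- window_scan(env)
    relative_amplitude(o$m10, o$l5)
  }, numeric(1))
  zs <- function(x) {
    s <- sd(x)
    if (s < 1e-12) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  link <- spec$score_link
  scores <- withr::with_seed(child_seed(spec$seed, 999983L), {
    bi <- link$bi_intercept + link$bi_amplitude * zs(amplitude) +
      link$bi_stability * zs(-pj) + rnorm(length(people), 0, link$bi_noise_sd)
    fa <- link$fourat_intercept + link$fourat_ra * zs(ra_env) +
      rnorm(length(people), 0, link$fourat_noise_sd)
    list(
      bi = pmin(100L, pmax(0L, as.integer(round(bi)))),
      fa = pmin(12L, pmax(0L, as.integer(round(fa))))
    )
  })
  four_at <- ifelse(vapply(people, `[[`, logical(1), "four_at_given"),
                    scores$fa, NA_integer_)
  epochs <- purrr::map(people, function(p) {
    if (epochs_as == "tibble") {
      simulate_epochs(p$params, seed = p$sim_seed)
    } else {
      simulate_epoch_counts(p$params, seed = p$sim_seed)
    }
  })
  out <- tibble(
    participant_id = vapply(people, `[[`, character(1), "participant_id"),
    group = vapply(people, `[[`, character(1), "group"),
    barthel_index = scores$bi,
    four_at = four_at,
    true_mesor = mesor,
    true_amplitude = amplitude,
    true_phase_jitter = pj,
    epochs = epochs
  )
  attr(out, "spec") <- spec
  out
}

# noiseless one-day envelope at minute resolution
envelope_minutes <- function(mesor, amplitude, acrophase) {
  tod <- seq.int(0L, 1439L) / 60
  mesor + amplitude * pmax(0, cos(2 * pi * (tod - acrophase) / 24))
}
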