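#' Rest-activity rhythm parameters for the simulator
#'
#' Bundles the parameters of the simulated rest-activity process. A day of
#' simulated activity is the sum of a rectified-cosine diurnal envelope
#' (`mesor + amplitude * max(0, cos(2*pi*(t - acrophase)/24))`, so nights sit
#' on a true floor at `mesor`), multiplied by a two-state rest/active Markov
#' chain at one-minute resolution (fragmentation) and by heavy-tailed
#' within-minute burst noise, plus additive sensor noise. Counts are truncated
#' at zero.
#'
#' @param mesor Mean activity level of the envelope (activity units/min, >= 0).
#'   The envelope equals `mesor` throughout the night, so `mesor` sets the
#'   nocturnal activity floor.
#' @param amplitude Peak-to-mesor height of the diurnal modulation (same
#'   units, >= 0).
#' @param acrophase Clock time of the daily activity peak (hours in `[0, 24)`).
#' @param phase_jitter_sd Day-to-day standard deviation of the acrophase
#'   (hours, >= 0). Drives interdaily stability down as it grows.
#' @param amp_jitter_sd Day-to-day standard deviation of the amplitude
#'   (activity units, >= 0). Defaults to `0.15 * amplitude`.
#' @param frag_rate Per-minute probability of switching between the rest and
#'   active states of the fragmentation chain (`[0, 1]`). The chain starts in
#'   the active state; `frag_rate = 0` keeps it there.
#' @param rest_level Multiplier applied to the envelope while the chain is in
#'   the rest state (`[0, 1]`; 1 disables fragmentation contrast).
#' @param burst_sigma Log-scale standard deviation of the lognormal
#'   within-minute burst multiplier (>= 0; the multiplier has mean 1, and 0
#'   disables it). Actigraphy counts are strongly right-skewed; this is the
#'   knob that reproduces that.
#' @param noise_sd Additive within-minute noise standard deviation (activity
#'   units, >= 0).
#' @param n_days Number of recorded days (integer >= 7; the rhythm indicators
#'   are defined over at least one week of recording).
#'
#' @return An object of class `rhythm_params` (a validated named list).
#' @seealso [simulate_epochs()], [simulate_accel()], [cohort_spec()]
#' @export
#' @examples
#' p <- rhythm_params(mesor = 4, amplitude = 40)
#' epochs <- simulate_epochs(p, seed = 1)
rhythm_params <- function(mesor = 5,
                          amplitude = 40,
                          acrophase = 14,
                          phase_jitter_sd = 1,
                          amp_jitter_sd = NULL,
                          frag_rate = 0.01,
                          rest_level = 0.3,
                          burst_sigma = 1.8,
                          noise_sd = 1.5,
                          n_days = 7) {
  amp_jitter_sd <- amp_jitter_sd %||% (0.15 * amplitude)
  chk_num <- function(x, nm, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
      abort(sprintf("`%s` must be a single finite number in [%s, %s]", nm, lo, hi))
    }
  }
  chk_num(mesor, "mesor")
  chk_num(amplitude, "amplitude")
  chk_num(acrophase, "acrophase", 0, 24 - 1e-9)
  chk_num(phase_jitter_sd, "phase_jitter_sd")
  chk_num(amp_jitter_sd, "amp_jitter_sd")
  chk_num(frag_rate, "frag_rate", 0, 1)
  chk_num(rest_level, "rest_level", 0, 1)
  chk_num(burst_sigma, "burst_sigma")
  chk_num(noise_sd, "noise_sd")
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days != round(n_days)) {
    abort("`n_days` must be a whole number")
  }
  if (n_days < 7) {
    abort("insufficient days: `n_days` must be at least 7 for rhythm analysis")
  }
  structure(
    list(
      mesor = mesor, amplitude = amplitude, acrophase = acrophase,
      phase_jitter_sd = phase_jitter_sd, amp_jitter_sd = amp_jitter_sd,
      frag_rate = frag_rate, rest_level = rest_level,
      burst_sigma = burst_sigma, noise_sd = noise_sd,
      n_days = as.integer(n_days), epoch_len = 1L
    ),
    class = "rhythm_params"
  )
}

#' @export
print.rhythm_params <- function(x, ...) {
  cat("<rhythm_params>\n")
  for (nm in setdiff(names(x), "epoch_len")) {
    cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  }
  invisible(x)
}

group_spec_fields <- c(
  "mesor_mean", "mesor_sd", "amplitude_mean", "amplitude_sd",
  "acrophase_mean", "acrophase_sd", "phase_jitter_mean", "phase_jitter_sd",
  "frag_rate", "rest_level", "burst_sigma", "noise_sd", "n_days", "four_at"
)

#' Specification of a simulated two-group actigraphy cohort
#'
#' Describes how a synthetic cohort is drawn: per-group distributions over
#' [rhythm_params()] hyperparameters, and the linear links that tie the
#' clinical scores to the generating rhythm. The Barthel Index is increasing
#' in the participant's (standardised) diurnal amplitude and day-to-day
#' stability; the 4AT delirium score is decreasing in the participant's
#' envelope relative amplitude. Scores are rounded and clipped to their
#' instrument ranges (BI 0-100, 4AT 0-12).
#'
#' @param n_per_group Participants per group (positive integer).
#' @param groups Named list of exactly two group specifications. Each is a
#'   list with fields `mesor_mean`, `mesor_sd`, `amplitude_mean`,
#'   `amplitude_sd`, `acrophase_mean`, `acrophase_sd`, `phase_jitter_mean`,
#'   `phase_jitter_sd`, `frag_rate`, `rest_level`, `burst_sigma`, `noise_sd`,
#'   `n_days`, and `four_at` (logical: is the 4AT administered to this group).
#' @param score_link List with fields `bi_intercept`, `bi_amplitude`,
#'   `bi_stability`, `bi_noise_sd`, `fourat_intercept`, `fourat_ra`,
#'   `fourat_noise_sd`. Noise SDs must be nonnegative and finite.
#' @param seed Root seed (integer). Per-participant child seeds are derived
#'   deterministically from it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [paperlike_spec()], [simulate_cohort()]
#' @export
cohort_spec <- function(n_per_group, groups, score_link, seed = 1L) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1 ||
      n_per_group != round(n_per_group) || n_per_group < 1) {
    abort("`n_per_group` must be a positive whole number")
  }
  if (!is.list(groups) || length(groups) != 2 || is.null(names(groups)) ||
      any(names(groups) == "")) {
    abort("`groups` must be a named list of exactly two group specifications")
  }
  for (g in names(groups)) {
    missing_f <- setdiff(group_spec_fields, names(groups[[g]]))
    if (length(missing_f)) {
      abort(sprintf("group '%s' is missing fields: %s",
                    g, paste(missing_f, collapse = ", ")))
    }
    extra <- setdiff(names(groups[[g]]), group_spec_fields)
    if (length(extra)) {
      abort(sprintf("group '%s' has unknown fields: %s",
                    g, paste(extra, collapse = ", ")))
    }
  }
  link_fields <- c("bi_intercept", "bi_amplitude", "bi_stability", "bi_noise_sd",
                   "fourat_intercept", "fourat_ra", "fourat_noise_sd")
  missing_f <- setdiff(link_fields, names(score_link))
  if (length(missing_f)) {
    abort(sprintf("`score_link` is missing fields: %s",
                  paste(missing_f, collapse = ", ")))
  }
  sds <- c(score_link$bi_noise_sd, score_link$fourat_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("degenerate score_link covariance: noise SDs must be finite and >= 0")
  }
  if (!all(vapply(score_link[link_fields], function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1)))) {
    abort("`score_link` coefficients must be single finite numbers")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         score_link = score_link[link_fields], seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' The shipped "paperlike" cohort specification
#'
#' A frozen two-group inpatient cohort design: a stroke-like group with a
#' raised nocturnal activity floor (higher mesor, higher rest-state level)
#' and a control-like group with a deeper night trough. Daytime peak activity
#' (M10) is matched between groups in expectation, so a group contrast on the
#' resulting metrics is expected to flag L5 and relative amplitude but not
#' M10. The hyperparameters were calibrated once against published inpatient
#' rehabilitation actigraphy medians (IS ~ 0.5, IV ~ 1, L5 ~ 4 vs ~ 2,
#' RA ~ 0.75 vs ~ 0.9) and are not meant to be tuned.
#'
#' @param n_per_group Participants per group (default 25).
#' @param seed Root seed.
#' @return A [cohort_spec()].
#' @export
#' @examples
#' spec <- paperlike_spec(n_per_group = 4, seed = 1)
#' cohort <- simulate_cohort(spec)
paperlike_spec <- function(n_per_group = 25, seed = 1L) {
  grp <- function(mesor_mean, mesor_sd, amplitude_mean, amplitude_sd,
                  phase_jitter_mean, frag_rate, rest_level, four_at) {
    list(
      mesor_mean = mesor_mean, mesor_sd = mesor_sd,
      amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
      acrophase_mean = 14, acrophase_sd = 0.8,
      phase_jitter_mean = phase_jitter_mean, phase_jitter_sd = 0.3,
      frag_rate = frag_rate, rest_level = rest_level,
      burst_sigma = 1.8, noise_sd = 1.5, n_days = 7L, four_at = four_at
    )
  }
  cohort_spec(
    n_per_group = n_per_group,
    groups = list(
      stroke_like  = grp(9, 2.2, 52, 26, 1.4, 0.007, 0.45, four_at = TRUE),
      control_like = grp(3.5, 1.4, 70, 26, 1.4, 0.009, 0.22, four_at = FALSE)
    ),
    score_link = list(
      bi_intercept = 40, bi_amplitude = 12, bi_stability = 9, bi_noise_sd = 16,
      fourat_intercept = 3, fourat_ra = -1.8, fourat_noise_sd = 2.8
    ),
    seed = seed
  )
}

# deterministic child seed (< 2^31) for participant i under a root seed
child_seed <- function(root, i) {
  as.integer((as.double(root) * 1000003 + as.double(i) * 7919) %% 2147483647)
}
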