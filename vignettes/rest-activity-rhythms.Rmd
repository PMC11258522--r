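---
title: "Nonparametric rest-activity rhythm analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric rest-activity rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

## The problem

Hospitalised patients — particularly after stroke — frequently show
disrupted circadian rest-activity rhythms: fragmented nights, blunted
day-night contrast, irregular day-to-day timing. Because overall mobility
is low in rehabilitation wards, conventional actigraphy sleep/wake scoring
is unreliable in this population; the nonparametric rest-activity rhythm
(RAR) indicators sidestep sleep scoring entirely and work directly on the
distribution of movement across the 24-hour day. `actirhythm` implements
the complete analysis: deriving minute activity counts from raw wrist
acceleration, computing the indicators, and comparing them between groups
and against clinical scores.

## From acceleration to acti-counts

The preprocessing chain mirrors standard research actigraphy firmware:

1. **Gravity removal and combination.** Each axis has its quasi-static
   component removed with a centred 10-second moving mean (truncated at
   the recording edges), and the residuals are combined into the
   per-sample Euclidean norm. Removing gravity *before* the norm keeps the
   subsequent frequency filtering meaningful: the norm of raw
   gravity-laden axes is dominated by orientation, whose spectrum has no
   clean separation from movement.
2. **Bandpass.** The magnitude is filtered with a 4th-order Butterworth
   bandpass, 0.5–3 Hz, applied forward and backward (zero phase, double
   stopband attenuation). This band retains voluntary limb movement while
   rejecting postural drift and high-frequency sensor noise. Edge samples
   are kept rather than trimmed, which simplifies length bookkeeping; the
   affected region is under half a filter settling time at each end.
3. **Thresholded integration.** The filtered signal is rectified, samples
   at or below a threshold (default 0.01 g, configurable) are zeroed,
   surviving samples are summed in consecutive 2-second segments, and each
   minute's acti-count is the mean of its thirty segment sums. Device
   documentation for this step is typically ambiguous; both the threshold
   and the segment length are exposed as parameters, and the default
   reading (2-s sums, minute mean) makes the count scale linearly with
   movement amplitude — the property the metrics downstream rely on.

Counts are therefore nonnegative, minute-resolution, and in arbitrary
device units: only within-pipeline comparisons are meaningful, which is
all the nonparametric indicators require (IS, IV and RA are scale
invariant; M10 and L5 are compared between groups measured identically).

## The indicators

All five indicators are computed from whole calendar days (local midnight
boundaries), by default requiring at least 7 days — below that, day-level
estimates of the daily template are too noisy to interpret.

With hourly averaged counts \(X_i\) (\(N\) in total, \(p = 24\) per day),
daily template \(\bar X_h\) and grand mean \(\bar X\):

\[
IS = \frac{N \sum_{h=1}^{p}(\bar X_h - \bar X)^2}{p \sum_{i=1}^{N}(X_i - \bar X)^2},
\qquad
IV = \frac{N \sum_{i=2}^{N}(X_i - X_{i-1})^2}{(N-1)\sum_{i=1}^{N}(X_i - \bar X)^2}.
\]

IS is the fraction of variance explained by the average 24-hour profile:
1 for a perfectly repeating rhythm, and approximately \(1/d\) for
unstructured noise over \(d\) days (the suite verifies the 7-day value by
simulation). IV is a normalised mean squared successive difference:
\(\approx 2(1-\cos(2\pi/24)) \approx 0.07\) for a smooth 24-h sinusoid,
\(\approx 2\) for white noise, and 4 in the limit of strict hour-to-hour
alternation. A constant series has no rhythm variance and both indicators
refuse it with an explicit error rather than returning a number.

M10 and L5 are found per day by scanning all 600-minute (300-minute)
windows fully contained in the day with a moving average and taking the
maximum (minimum); ties go to the earliest clock time, so results are
deterministic. The composite values are the across-day means, and
\(RA = (M10 - L5)/(M10 + L5)\) is computed **from the composites** — not
as the mean of daily RA values — because that is how the published
composite worked examples combine (e.g. M10 = 38.91, L5 = 9.67 gives
RA = 0.60 at two decimals).

Two deliberate options:

- **No midnight wrap by default.** Windows are confined to each 24-hour
  block, matching how per-day M10/L5 markings are conventionally drawn;
  `wrap = TRUE` allows circular windows for cohorts whose main sleep
  period straddles midnight.
- **Minute-resolution windows by default.** The scan runs over all 841
  (M10) and 1141 (L5) minute starts; `resolution = "hour"` restricts to
  hourly steps for comparability with coarser implementations.

**Missing data** must be explicit (`NA` minutes). An hour with fewer than
45 valid minutes is invalid; a day containing any invalid hour is excluded
from *all* indicators and reported — never silently dropped. Both
thresholds are configurable; the defaults are conservative because no
principled imputation exists for missing wear time at this resolution.

## The synthetic cohort generator

The generator exists so every stage has a ground truth. A participant's
minute counts are

\[
c_t = \max\!\big(0,\; E(t)\, m_t\, B_t + \varepsilon_t\big), \qquad
E(t) = \text{mesor} + A_d \max\!\big(0, \cos\tfrac{2\pi (t - \phi_d)}{24}\big),
\]

- **Envelope** \(E(t)\): a *rectified* cosine, so nights sit on a true
  floor at `mesor` rather than dipping below it — acti-counts are
  nonnegative and inpatient nights are near-zero. Day-to-day jitter enters
  through \(\phi_d \sim \mathcal N(\text{acrophase}, \sigma_\phi^2)\) and
  \(A_d\) (amplitude jitter); \(\sigma_\phi\) is the dial that drives IS
  down.
- **Fragmentation** \(m_t\): a symmetric two-state Markov chain at minute
  resolution (switch probability `frag_rate`, rest-state multiplier
  `rest_level`, starting active). It produces rest/active bouts with mean
  dwell `1/frag_rate` minutes and is the dial that drives IV up — exactly
  the transitions IV is designed to measure.
- **Burst noise** \(B_t\): lognormal with mean 1 (`burst_sigma`). Real
  acti-counts are strongly right-skewed — a minute is either quiet or
  contains a large movement burst — and this skew is what keeps IV in the
  empirically observed range (~1) for inpatients; purely additive noise
  averages out of hourly means almost completely. \(\varepsilon_t\) is a
  small additive sensor floor.

`simulate_accel()` generates the corresponding *raw* signal (gravity on
z, per-second movement bursts as 0.8–2.8 Hz tones with random
orientation, occurrence probability proportional to the same
envelope-times-fragmentation intensity, plus wideband noise) so the
preprocessing chain can be exercised end to end. Burst counts integrate
approximately additively while bursts are sparse; at high burst densities
adjacent bursts merge and the count per burst drops, so linearity checks
are run in the sparse regime.

### The shipped two-group design

`paperlike_spec()` freezes a two-group inpatient design calibrated once
against published rehabilitation-ward medians (IS ≈ 0.5, IV ≈ 1,
stroke L5 ≈ 4.3 vs control ≈ 1.8 units/min, RA ≈ 0.74 vs ≈ 0.88):

| parameter | stroke-like | control-like |
|---|---|---|
| mesor (night floor) | N(9, 2.2) | N(3.5, 1.4) |
| amplitude | N(52, 26) | N(70, 26) |
| rest_level | 0.45 | 0.22 |
| frag_rate (/min) | 0.007 | 0.009 |
| phase jitter (h) | N(1.4, 0.3) | N(1.4, 0.3) |
| burst_sigma / noise_sd | 1.8 / 1.5 | 1.8 / 1.5 |

The stroke-like group gets its raised nocturnal floor from a higher mesor
and rest level; amplitudes are set so the *daytime peak* (M10) is matched
between groups in expectation. The design therefore predicts a group
difference in L5 and RA but not in M10 — and the test suite confirms the
pipeline flags exactly that pattern in at least 80 % of replicate cohorts
of 25 + 25, while holding a ~5 % false-positive rate when both groups use
identical parameters.

Clinical scores are linked linearly to *latent* generator quantities (not
to the estimated metrics, so recovery is a genuine estimation test):
Barthel Index increases with standardised amplitude and day-to-day
stability (BI = 40 + 12·z(amplitude) + 9·z(−phase jitter) + N(0,16),
rounded, clipped to 0–100); 4AT decreases with the relative amplitude of
the participant's noiseless envelope (4AT = 3 − 1.8·z(RA) + N(0,2.8),
clipped to 0–12) and is generated only for the stroke-like group,
mirroring how delirium screens are administered in practice. The
coefficients were chosen to give population correlations of roughly
0.3–0.45 in magnitude; they reproduce a sign structure, not any measured
effect size.

What the generator does *not* emulate: sleep architecture, medication
effects, nonwear, device calibration. Passing tests on synthetic cohorts
therefore demonstrate that the estimators and tests recover the structure
the generator encodes — not that any particular clinical effect size is
real.

### Randomness

A cohort is driven by one root seed; per-participant child seeds are
derived deterministically (`(root · 1000003 + i · 7919) mod (2^31 − 1)`),
so cohorts are byte-identical across runs and participants could be
generated in parallel without changing results.

## Statistical layer

Group contrasts use the Mann-Whitney U test: exact two-sided p by full
enumeration when the combined sample is ≤ 12 without ties, otherwise the
normal approximation with midrank tie correction and continuity
correction. The reported statistic is min(U₁, U₂) (stated in the output,
since conventions differ). Quartiles use linear interpolation between
order statistics (R type 7); the convention is documented because
published tables rarely state theirs. Correlations use Spearman's ρ
(exact permutation p for n ≤ 7 without ties, t-approximation otherwise);
categorical tables use Pearson chi-square without continuity correction,
switching to the two-sided point-probability Fisher exact test for 2×2
tables with any expected cell under 5. Shapiro-Wilk screening is
reported descriptively, but the pipeline's comparisons remain
nonparametric regardless — with skewed, bounded activity metrics in small
groups that is the defensible default. No multiplicity adjustment is
applied by default (five comparisons, reported transparently); Holm
adjustment is available with `adjust = "holm"`.

All of these delegate to the corresponding base R tests; the test suite
verifies every branch against independent full-enumeration oracles.

## Numerical choices and degenerate inputs

- Window ties are resolved to the earliest onset using a small relative
  tolerance (1e-9), because cumulative-sum scanning makes exactly-tied
  windows differ by rounding.
- A circular time shift of a periodic recording leaves IS, RA, M10 and L5
  unchanged exactly; IV differs only in which day-boundary transition the
  finite series omits, an O(1/N) effect.
- Constant series, empty groups, zero-variance correlations, zero-margin
  tables and sub-Nyquist band edges all raise explicit errors rather than
  returning numbers.
- `rar_metrics()` refuses recordings with fewer usable days than
  `min_days` (default 7) unless `allow_insufficient = TRUE`, which warns
  and reports what it used.

## Problem sizes used in the test suite

The suite's Monte-Carlo checks use: 1000 replicates for the iid-noise IS
limit (7-day series) and for the null false-positive rate of the group
contrast (25 + 25 cohorts); 200 replicates for IV limits, monotonicity
and the envelope-RA recovery; 100 replicate cohorts for the two-group
significance pattern. These sizes put the Monte-Carlo standard error
comfortably inside each asserted band.

## Known limitations

- Activity units are arbitrary; no device calibration is attempted.
- No nonwear detection: gaps must arrive as explicit `NA` minutes.
- The generator's fragmentation is stationary within a day; real nap
  structure is time-of-day dependent.
- IS/IV are computed on the concatenation of retained days; when interior
  days are excluded, the first difference across the gap joins
  non-adjacent hours (one transition out of ~168 per week).
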