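# actirhythm

Nonparametric rest-activity rhythm (RAR) analysis for wrist actigraphy in
R. The package targets the setting where continuous accelerometry is used
to quantify circadian disruption in low-mobility populations — for example
inpatients in stroke or spinal-injury rehabilitation, where standard
sleep/wake scoring algorithms are unreliable but the day-night contrast of
movement itself is clinically informative.

It covers the full chain:

1. **Preprocessing** — raw tri-axial acceleration to one-minute
   "acti-counts": per-axis gravity removal (10-s moving mean), Euclidean
   combination, zero-phase 0.5–3 Hz Butterworth bandpass, thresholding, and
   2-second integration averaged per minute.
2. **Rhythm metrics** — the nonparametric circadian indicators computed
   from hourly averaged counts `X_i` (N points, 24 per day, template `X̄_h`,
   grand mean `X̄`):

   - interdaily stability
     `IS = N Σ_h (X̄_h − X̄)² / (p Σ_i (X_i − X̄)²)`, in [0, 1];
   - intradaily variability
     `IV = N Σ_i (X_i − X_{i−1})² / ((N−1) Σ_i (X_i − X̄)²)`, roughly 0–2
     for physiological data;
   - per-day and composite **M10** and **L5** (mean activity of the most
     active 10 and least active 5 consecutive hours, found by a
     minute-resolution moving-average scan);
   - relative amplitude `RA = (M10 − L5) / (M10 + L5)`, in [0, 1].
3. **Cohort statistics** — Shapiro-Wilk screening, Mann-Whitney U group
   contrasts (exact for small tie-free samples), chi-square/Fisher for
   categorical tables, and Spearman correlations of the metrics against
   clinical scores (Barthel Index for ADL independence, 4AT for delirium
   screening).
4. **Synthetic cohorts** — a generator for realistic ≥7-day inpatient
   recordings (rectified-cosine diurnal envelope, day-to-day phase and
   amplitude jitter, two-state rest/active fragmentation, heavy-tailed
   burst noise) with clinical scores statistically linked to the rhythm,
   so the whole pipeline is testable without any data download.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` accessors, `autoplot()` / `plot_actogram()` graphics.

## Worked example

```r
library(actirhythm)

# one synthetic participant: 7 days of minute epochs
params <- rhythm_params(mesor = 4, amplitude = 45, acrophase = 14,
                        phase_jitter_sd = 1.2, frag_rate = 0.008,
                        rest_level = 0.4)
epochs <- simulate_epochs(params, seed = 101)
rar_metrics(epochs)
#> Rest-activity rhythm metrics
#>   IS  0.60   IV  0.53
#>   M10 25.13   L5  2.19   RA 0.84
#>   days used: 7
```

IS 0.60 says 60 % of the hourly variance is explained by the average
24-hour profile; M10 = 25.1 and L5 = 2.2 activity units/min give a strong
day-night contrast (RA 0.84). A two-group study over the shipped
"paperlike" cohort design (a stroke-like group with a raised nocturnal
floor vs an activity-matched inpatient control group):

```r
cohort <- simulate_cohort(paperlike_spec(n_per_group = 25, seed = 42))
study  <- run_study(compute_cohort_metrics(cohort))
study
#> Rest-activity rhythm study: control_like (n=25) vs stroke_like (n=25)
#> alpha = 0.05, adjustment: none
#>
#> Group comparison (median (IQR), Mann-Whitney U):
#>   Interdaily stability             0.41 (0.32-0.47)     0.45 (0.36-0.49)     p=0.438
#>   Intradaily variability           0.98 (0.88-1.18)     0.99 (0.85-1.16)     p=0.861
#>   Relative amplitude               0.91 (0.87-0.92)     0.75 (0.72-0.82)     p=2.92e-06 *
#>   Most active 10 continuous hours  32.09 (20.15-36.73)  29.91 (23.21-43.69)  p=0.352
#>   Least active 5 continuous hours  1.50 (1.35-1.77)     4.69 (3.95-5.17)     p=1.42e-09 *
#>
#> Spearman correlations with clinical scores:
#>   barthel_index  ~ is   rho=+0.26  p=0.0719  (n=50)
#>   barthel_index  ~ ra   rho=+0.50  p=0.000247  (n=50) *
#>   barthel_index  ~ m10  rho=+0.42  p=0.00232  (n=50) *
#>   four_at        ~ ra   rho=-0.63  p=0.000785  (n=25) *
#>   ...
```

The stroke-like group differs on L5 (restless nights) and RA (blunted
day-night contrast) but not on daytime peak activity (M10) — the signature
the design encodes. Daytime activity correlates positively with ADL
independence, and relative amplitude negatively with the delirium screen.

A full simulate → metrics → compare run with CSV artifacts and a
provenance sidecar:

```r
run_pipeline(pipeline_config(seed = 1, simulate = list(n_per_group = 25)),
             out_dir = "run1")
```

or from a shell, `Rscript inst/cli/actirhythm.R run --out run1 --seed 1`
(also `simulate`, `preprocess`, `metrics`, `compare` subcommands).

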