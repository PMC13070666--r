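# presmat

Posture, mobility and pressure–time exposure analysis for continuous
pressure-mat monitoring (CPM) in pressure-injury care.

Community patients who spend long periods in bed can be monitored with a
full-body pressure-sensing mattress cover (a grid of "sensels" sampling the
interface pressure in mmHg at 1 Hz). `presmat` turns such recordings into
the indicators clinicians act on:

- **Posture and mobility.** The centre of pressure (COP) in both planar
  axes and the contact area above 20 mmHg are smoothed, differentiated and
  robust z-scored; the Euclidean norm of the three derivative channels is a
  movement signal whose pulses mark large-scale postural changes. Changes
  detected above a `median + 6·MAD` threshold partition the monitoring
  period into static postures, from which movement features follow:
  postures per hour, intervals between changes, and the percentage of time
  static for more than 2 h.
- **Buttock-ROI pressure signatures.** For each static posture a
  30 × 20-sensel region of interest (47.7 × 31.8 cm at 15.9 mm pitch) is
  anchored at the posture's median COP, and per-frame signatures are
  reduced to mean ± SD: peak pressure, peak pressure index
  (PPI — mean of the 10 highest pressures), and peak pressure gradient
  (PPG — largest pressure difference between diagonally adjacent sensels,
  in mmHg/cm).
- **Sigmoid pressure–time exposure.** Each posture's (duration, mean
  signature) point is stratified against three sigmoid boundary curves
  `B_k(t) = F_k + (S_k − F_k)/(1 + e^{α(t − t₀)})` with starting pressures
  `S_k` of 25/35/45 mmHg/cm (PPG) and 70/90/110 mmHg (PPI), yielding
  low / moderate / high / very-high exposure and time-in-category
  fractions per recording.
- **Synthetic sessions with ground truth.** A generator renders scheduled
  posture templates (Gaussian body-loading sites), mean-reverting
  micro-movement, truncated sensor noise and optional alternating-mattress
  modulation, returning the true change times and clean signatures for
  validation.
- **Cohort reporting.** Packaged 17-patient pre/post-intervention tables
  (demographics, injury categories, monitoring length, posture counts)
  with tabulation, quartile summaries and pre/post comparison helpers.

## Worked example

```r
library(presmat)
library(tibble)

# simulate a 1-h session: supine, then a lateral turn after 30 min
sched <- tibble(template  = c("supine", "lateral_left"),
                duration_s = c(1800, 1800),
                offset_col = c(0, 6))
cfg <- sim_config(sched, geometry_profile("foresite_pt"),
                  noise_sd_mmHg = 2, jitter_sd_sensels = 0.2, seed = 42)
sim <- simulate_session(cfg)

an <- analyze_session(sim$sequence)
an
#> <cpm_analysis> 1.00 h monitored, 2 posture(s), 2.00 postures/h, 0% time static > 2 h

an$segmentation$change_times_s
#> [1] 1804

tidy(an)[, c("segment", "duration_h", "ppg_mean", "ppi_mean")]
#> # A tibble: 2 × 4
#>   segment duration_h ppg_mean ppi_mean
#>     <int>      <dbl>    <dbl>    <dbl>
#> 1       1      0.501     9.32     77.1
#> 2       2      0.499    12.3      88.9
```

The detected change sits 4 s after the true turn at 1800 s (within half the
11-s smoothing window plus the 10-s turn transition). The supine posture
shows a mean PPI of ~77 mmHg — above the lowest 70-mmHg boundary at short
durations but below the 90-mmHg one, so it is classed as *moderate*
exposure — while the lateral posture, with its load concentrated over the
trochanter, runs ~12 mmHg higher and crosses into *high*:

```r
dplyr::filter(an$exposure, signature_type == "ppi", fraction > 0)
#> # A tibble: 2 × 4
#>   signature_type category hours fraction
#>   <chr>          <ord>    <dbl>    <dbl>
#> 1 ppi            moderate 0.501    0.501
#> 2 ppi            high     0.499    0.499
```

`plot_movement_signal(an)` and
`plot_exposure(an$signatures, sigmoid_thresholds("ppi"))` draw the
detector trace and the posture markers against the boundary curves.

For the packaged cohort:

```r
movement_report(load_fixture("table2"))
# pre monitoring-length median 19 h; post median 22.5 h, IQR 8.7 h;
# posture frequency 0.06-1.17 /h pre, up to 0.98 /h post
tabulate_pu(load_fixture("table1"), "post")
# 12 of 17 patients healed post-intervention
```

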