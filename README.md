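# bowkin

Kinematic analysis of bow-direction reversals in cello bowing.

During continuous-tone ("legato") bowing, a string player must invert the
bow's direction quickly and precisely at every stroke boundary. Skilled
cellists do this with a flat stroke velocity and a single, large,
consistently timed acceleration impulse, organised proximal-to-distal
along the right arm (shoulder → elbow → wrist → hand → bow: proximal
parts reverse earlier and with smaller normalized acceleration
amplitudes); beginners produce bell-shaped strokes with several smaller
acceleration peaks and no systematic gradient. `bowkin` is for movement
scientists who want to quantify this from 3D motion-capture marker
trajectories — and for anyone who needs a fully validated, synthetic
test-bed for reversal-detection pipelines.

## What it computes

Given marker trajectories (trunk, right arm, hand, cello, bow) the
pipeline produces:

* **Bow kinematics** — bowing velocity `v(t) = ⟨ṗ_tip, û_bow⟩` (the
  signed component of the bow-tip velocity along the line through the two
  bow markers, positive = down-bow) and bow acceleration `a(t) = v̇(t)`,
  via three-point central differences after zero-phase 5th-order
  Butterworth filtering at 20 Hz.
* **Reversal events** — sub-sample zero crossings of `v(t)`, validity
  filtered (flanking movements 0.5–1 s, no missing samples), first 10 per
  direction.
* **Reversal metrics** per event (±375 ms window) — peak acceleration
  `a_peak` and its time `t_peak` relative to the reversal, acceleration
  at the reversal, ±10% and ±50% switch durations, and the number of
  acceleration peaks (> 50% of the window maximum, ≥ 100 ms apart).
* **Arm coordination** — per-marker normalized acceleration profiles
  `‖p̈_m(t)‖ / ‖p_m(t) − p_shoulder(t)‖` along the ordered chain
  elbow → wrist → hand → bow, and joint-angle reversal times relative to
  the bow reversal.
* **Group statistics** — lab-effect removal, Group × Direction
  (× Marker/Joint) mixed repeated-measures ANOVAs with orthogonal
  polynomial trend contrasts on the ordered chain factors, Holm-corrected
  pairwise t-tests, and one-sample t-tests of the relative timing
  measures against zero.

A synthetic generator (`simulate_recording()`, `simulate_cohort()`)
produces expert-like and novice-like cohorts from analytic acceleration
pulses with exact ground truth (reversal times, per-marker peak times and
amplitudes, joint reversal times), plus realistic correlated measurement
noise and dropout. See the methods vignette
(`vignettes/bowkin-methods.Rmd`) for the model and every default.

## Worked example

One expert-like trial, analysed end to end:

```r
library(bowkin)

sim <- simulate_recording(bowing_profile("expert"), n_cycles = 8, seed = 42)
an  <- analyze_recording(sim$recording)
dplyr::select(an$bow_metrics, event, direction, t_peak_acc, a_peak,
              dur_50, n_peaks)
#> # A tibble: 12 × 6
#>   event direction t_peak_acc a_peak dur_50 n_peaks
#>   <int> <chr>          <dbl>  <dbl>  <dbl>   <int>
#> 1     2 down_up    -0.0157    4571.  0.149       1
#> 2     3 up_down     0.0148    4317.  0.151       1
#> 3     4 down_up    -0.0345    4216.  0.150       2
#> 4     5 up_down    -0.000688  4467.  0.150       1
#> 5     6 down_up    -0.0154    4636.  0.152       1
#> 6     7 up_down    -0.0162    4567.  0.152       1
#> # ℹ 6 more rows
```

Each row is one analysed bow reversal: the acceleration peak sits a few
tens of milliseconds *before* the reversal (`t_peak_acc < 0`), reaches
about 4.5 m/s² (`a_peak`, mm/s²), the −50% → +50% velocity switch takes
about 150 ms, and the reversal is accomplished with a single acceleration
peak — the expert signature.

A small group comparison:

```r
cohort <- simulate_cohort(n_experts = 3, n_novices = 3, n_cycles = 8,
                          base_seed = 1)
res <- run_pipeline(cohort)
res
#> <bow_pipeline_result> 6 subjects | movement retention 91.1%
#> ANOVA dependent variables: a_peak, t_peak_acc, t_peak_acc_sd, a_at_rev,
#>   dur_50, dur_10, n_peaks, marker_t_peak_acc, marker_a_at_rev, joint_t_rev

dplyr::summarise(dplyr::group_by(res$subject_bow, group),
  peak_acc = mean(a_peak), n_peaks = mean(n_peaks), dur50 = mean(dur_50))
#> # A tibble: 2 × 4
#>   group  peak_acc n_peaks dur50
#>   <chr>     <dbl>   <dbl> <dbl>
#> 1 expert    4606.    1.24 0.150
#> 2 novice    1791.    4.25 0.308

tidy(res$anova$n_peaks)
#> # A tibble: 3 × 6
#>   stratum              effect          df_num df_den statistic p.value
#>   <chr>                <chr>            <dbl>  <dbl>     <dbl>   <dbl>
#> 1 subject_id           group                1      4     25.5  0.00721
#> 2 subject_id:direction direction            1      4      1.08 0.357
#> 3 subject_id:direction group:direction      1      4      4.46 0.102
```

Experts show roughly 2.5× larger peak accelerations, a single
acceleration peak per reversal versus about four for novices
(Group: F(1,4) = 25.5, p = 0.007 in this toy cohort), and half the
switch time. `plot_reversal_profiles()` and `plot_chain_profile()` draw
the time-locked traces and the proximal-to-distal gradients;
`tidy()`/`glance()` work on every fitted ANOVA.

A thin command-line wrapper over the same functions lives at
`inst/cli/bowkin.R` (`simulate`, `analyze`, `all` subcommands).

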