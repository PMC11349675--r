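# reoxkin

Postexercise muscle reoxygenation kinetics from wearable NIRS during
incremental cycling tests.

## What it is for

Wearable near-infrared spectroscopy (NIRS) reports muscle oxygen
saturation (SmO₂, %) continuously during exercise. When a work interval
ends, oxygen delivery transiently exceeds uptake and SmO₂ recovers toward
rest; the speed of that recovery slows with exercise intensity, differs
between locomotor and accessory muscles, and is delayed by conditions that
impair oxygen delivery or uptake. Because absolute SmO₂ percentages are
device- and tissue-scaled, the recovery *time course* is the robust
outcome.

`reoxkin` is for sport scientists and clinical researchers analysing SmO₂
recordings from incremental multi-stage protocols (5-min work stages, 1-min
rests, workload steps of 0.5 W·kg⁻¹). It provides:

- **protocol** tools — build or load a stage schedule, map time to
  work/rest phase, compute peak workload (Wpeak) with prorated partial
  final stages;
- **preprocessing** — 5-s symmetric moving average and resampling of the
  0.5-Hz device signal to 1 Hz, range checks, jump-artifact flagging;
- **bout extraction** — per rest period: the end-work baseline
  Y_A (mean of the final 30 s of work), the recovery peak Y_B (earliest
  sample with no higher sample within the next 30 s of the recovery
  window), the amplitude Y_B − Y_A, and the **half-recovery time**

  HRT = first t after work end with y(t) ≥ Y_A + (Y_B − Y_A)/2,

  interpolated between samples. Recovery windows run to the next work
  start for locomotor sites (VL, RF), 60 s further for accessory sites
  (PS, DL), and 4 min after the final stage;
- **monoexponential kinetics** — multi-start least-squares fit of
  y(t) = y₀ + A·(1 − exp(−(t − t_d)/τ)), mean response time
  MRT = t_d + τ, acceptance by pseudo-R² ≥ 0.85 and 0 < MRT < t_peak,
  with broom-style `tidy()`/`glance()` methods;
- **reliability battery** — per site × workload: median (Q₁–Q₃) and
  between-participant CV; ICC(2,1) (two-way random effects, absolute
  agreement) with F-based 95 % CI and interpretation bands,
  SEM = √MS_E with chi-square CI, MDC = 1.96·√2·SEM, and
  within-participant CV;
- a **synthetic-recording generator** with known ground truth (per-bout τ,
  delay, amplitude, analytic HRT) emulating work-phase desaturation,
  workload-dependent recovery, participant/trial variability, sensor
  noise, and light/motion dropouts — used to validate every stage.

## Worked example

```r
library(reoxkin)
library(dplyr)

study <- simulate_study(population_config(n_participants = 10, seed = 42))
bouts <- extract_bouts(study)
bout_accounting(bouts)
#> # A tibble: 1 × 3
#>   scheduled unusable unusable_pct
#>       <int>    <int>        <dbl>
#> 1       240        0            0
```

240 bouts were scheduled (10 participants × 2 trials × 4 sites × 3 target
workloads) and none were lost to artifacts. Median HRT per site and target
workload (% of Wpeak):

```r
bouts |>
  filter(status == "OK") |>
  group_by(site, target_pct) |>
  summarise(median_hrt = median(hrt_s), .groups = "drop") |>
  tidyr::pivot_wider(names_from = target_pct, values_from = median_hrt)
#> # A tibble: 4 × 4
#>   site   `50`  `75` `100`
#>   <chr> <dbl> <dbl> <dbl>
#> 1 DL    31.8   32.6  43.2
#> 2 PS    26.3   27.7  41.6
#> 3 RF    15.0   18.5  32.3
#> 4 VL     8.45  12.7  17.7
```

Reoxygenation is fastest in the vastus lateralis (8.5 s at 50 % Wpeak),
slows with workload, and is sequentially slower toward the accessory
sites — the physiological pattern the generator encodes. Test-retest
reliability for the VL:

```r
reliability_summary(bouts) |>
  filter(site == "VL") |>
  select(site, target_pct, n, icc, icc_band, sem_s, mdc_s)
#> # A tibble: 3 × 7
#>   site  target_pct     n   icc icc_band sem_s mdc_s
#>   <chr>      <dbl> <int> <dbl> <chr>    <dbl> <dbl>
#> 1 VL            50    10 0.627 moderate  1.88  5.21
#> 2 VL            75    10 0.801 good      1.59  4.42
#> 3 VL           100    10 0.825 good      2.66  7.37
```

An ICC of 0.80 at 75 % workload means 80 % of the observed variance is
true between-participant variance; the MDC of ~4–7 s is the smallest
change in HRT attributable to an intervention rather than measurement
noise. `plot_hrt(bouts)` and `autoplot()` methods draw the corresponding
figures; `write_bouts()`, `build_reports(dir = ...)` and `write_study()`
export tidy CSVs.

See the vignette (`vignettes/reoxygenation-kinetics.Rmd`) for the signal
model, parameter defaults and numerical choices.

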