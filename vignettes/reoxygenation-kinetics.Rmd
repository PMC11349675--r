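---
title: "Quantifying postexercise muscle reoxygenation from wearable NIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying postexercise muscle reoxygenation from wearable NIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(reoxkin)
library(dplyr)
```

## The measurement problem

Wearable near-infrared spectroscopy (NIRS) reports muscle oxygen saturation
(SmO~2~, %) at the sensor site. During a work interval the muscle
deoxygenates as oxygen uptake outpaces delivery; when work stops, delivery
transiently exceeds uptake and SmO~2~ recovers toward its resting level.
The *time course* of that recovery is the quantity of interest: it is much
less sensitive to the device- and tissue-dependent scaling of absolute
SmO~2~ values than the percentages themselves, and it slows with exercise
intensity and with impairments of oxygen delivery or uptake.

`reoxkin` implements the full analysis chain for an incremental multi-stage
cycling test (5-min work stages, 1-min passive rests, workload starting at
1.0 W·kg^-1^ and stepping by 0.5 W·kg^-1^): protocol segmentation,
device-style signal conditioning, per-bout reoxygenation extraction,
optional monoexponential kinetics, and a test-retest reliability battery.
Because raw recordings from such studies are rarely public, the package
also ships a synthetic-recording generator with known ground truth; every
stage of the pipeline is validated against it.

## Bout definition and half-recovery time

For each analysed stage the pipeline computes, on the smoothed 1-Hz series:

* **Y~A~** — the mean SmO~2~ over the final 30 s of the work interval;
* **Y~B~** — the recovery peak: the *earliest* sample in the recovery
  window with no strictly higher sample within the following 30 s (equal
  values do not disqualify an earlier candidate, so ties resolve to the
  earliest time);
* **amplitude** — Y~B~ − Y~A~, required positive for a usable bout;
* **HRT** — the half-recovery time: seconds from the end of work until the
  series first reaches Y~A~ + (Y~B~ − Y~A~)/2, with linear interpolation
  between the bracketing samples.

The recovery window depends on the muscle's role. Locomotor sites (vastus
lateralis VL, rectus femoris RF) reach their peak within the 60-s passive
rest, so their window runs to the start of the next work stage. Accessory
sites (lumbar paraspinal PS, lateral deltoid DL) keep reoxygenating into
the next stage — restarting pedalling restores venous return before their
local demand catches up — so their window extends 60 s past the next work
start. After the final stage every site gets a 4-min window.

Sub-sample interpolation at the half-crossing is a deliberate choice: with
1-Hz data, reading HRT at the first sample at-or-above threshold would
quantise estimates and bias them up to one second high. Interpolation
removes that bias; on pure ramps it is exact.

A second deliberate choice concerns window-edge peaks. A strictly rising
series has its only admissible peak at the last window sample, where the
30-s lookahead is truncated. Such bouts are accepted (the lookahead that
fits inside the window contains no higher value) and marked
`truncated_lookahead`; discarding them would systematically drop the
slowest recoveries.

## Monoexponential kinetics

Recovery kinetics are classically summarised by the mean response time of

$$y(t) = y_0 + A\,\bigl(1 - e^{-(t - t_d)/\tau}\bigr), \qquad t \ge t_d,$$

with onset delay $t_d \ge 0$ and time constant $\tau$;
$\mathrm{MRT} = t_d + \tau$ is the time to recover ≈63 % of the amplitude,
and the model's half-recovery time is $t_d + \tau \ln 2$. `fit_monoexp()`
fits the curve by Levenberg–Marquardt least squares from a deterministic
multi-start grid ($\tau \in \{2,5,10,20,40,80\}$ s ×
$t_d \in \{0,5,15\}$ s; lowest residual sum of squares wins), which makes
results reproducible and robust to the strong $\tau$–$t_d$ correlation
near the onset.

A fit is *accepted* only if pseudo-R² = 1 − SS~res~/SS~tot~ ≥ 0.85 (SS~tot~
about the segment mean — the conventional definition) **and**
0 < MRT < t~peak~. Real bouts frequently violate monoexponential shape
(biphasic recoveries, drift, motion residue), which is why the
nonparametric HRT is the primary outcome and the fit an optional
cross-check; `conformity_report()` quantifies the rejection fraction. On
noiseless generated bouts the two routes agree to within one sample, so
conclusions should not hinge on the choice of estimator.

## Signal conditioning

Recordings arrive at the device-native 0.5 Hz. Conditioning mirrors the
manufacturer-recommended treatment: a centred moving average of 5-s total
span, then linear interpolation onto a 1-Hz grid. The interpolation scheme
is not specified by the device documentation; linear is the minimal
assumption and is recorded in the output metadata sidecar. Edge windows
shrink rather than truncate so the final-30-s work baseline is never
shortened. Missing samples are excluded from window means; windows with no
usable samples — and interpolated points bracketed by them — stay missing.

Artifact screening marks both endpoints of any sample-to-sample jump above
10 %SmO~2~ (configurable); physiological rest-phase slopes in this context
are an order of magnitude smaller. A bout is declared unusable when more
than half of its baseline or recovery window is missing or flagged. The
screen is idempotent and never repairs data — flagging only.

## The synthetic-recording generator

`simulate_trace()` produces a piecewise-monoexponential trajectory over the
schedule: during work SmO~2~ decays toward a workload-scaled desaturation
plateau (baseline − depth × %Wpeak); during rest it recovers toward the
pre-work baseline with time constant
$\tau(p) = \tau_{50} \bigl(1 + s\,(p - 0.5)\bigr)$, where $p$ is the stage
workload as a fraction of peak workload. Each site's onset delay applies at
*every* phase transition, so long-delay accessory sites continue
reoxygenating into the next work stage — exactly the behaviour that
motivates their extended window. Gaussian sample noise is added and the
signal clipped to the physical 0–100 % range.

Default site profiles were fixed once, from the closed-form HRT of the
noiseless model, to sit near published group medians for trained cyclists
(VL ≈ 8/12/17 s at 50/75/100 % peak workload, slowing in the order
VL < RF < PS < DL; PS and DL converge at maximal workload). Population
structure: a participant effect on log τ **shared across that
participant's sites** (fitness is systemic; SD 0.30, giving
between-participant CVs in the observed 20–50 % range), a smaller
site-specific participant effect (SD 0.15), a trial-to-trial effect
(SD 0.15), and 1.5 %SmO~2~ sample noise. Log-normal variation keeps τ
positive, which is the conventional choice absent a stated generative
model. A counter-based seed scheme gives every trace its own substream, so
enlarging the study never perturbs existing participants' draws.

What the generator does **not** emulate: supra-baseline overshoot (a
parameter exists but defaults to 0), slow baseline drift, adipose-layer
scaling, cadence coupling, or correlated (non-white) sensor noise. Passing
tests therefore demonstrate correctness of the *analysis* under the stated
signal model, not robustness to every failure mode of field recordings.

```{r pattern, message = FALSE}
study <- simulate_study(population_config(n_participants = 10, seed = 42))
bouts <- extract_bouts(study)
bouts |>
  filter(status == "OK") |>
  group_by(site, target_pct) |>
  summarise(median_hrt = median(hrt_s), .groups = "drop") |>
  tidyr::pivot_wider(names_from = target_pct, values_from = median_hrt)
```

```{r plot, fig.height = 3}
plot_hrt(bouts)
```

## Reliability battery

For each site × workload cell, over participants with both trials usable
(listwise deletion, minimum three complete rows):

* **ICC(2,1)** — two-way random-effects, absolute-agreement, single-measure
  intraclass correlation, computed from the two-way ANOVA mean squares
  $(\mathrm{MS_R} - \mathrm{MS_E}) / \bigl(\mathrm{MS_R} +
  (k-1)\mathrm{MS_E} + \tfrac{k}{n}(\mathrm{MS_C} - \mathrm{MS_E})\bigr)$
  with $k = 2$, and the standard F-based 95 % confidence interval.
  Interpretation bands: poor < 0.5, moderate 0.5–0.75, good 0.75–0.9,
  excellent > 0.9.
* **SEM** — $\sqrt{\mathrm{MS_E}}$ from the *same* ANOVA, in seconds, with
  chi-square confidence bounds. The agreement-consistent choice for
  ICC(2,1); the alternative $\mathrm{SD}\sqrt{1-\mathrm{ICC}}$ differs only
  in which variance components it pools and is not used.
* **MDC** — $1.96\sqrt{2}\,\mathrm{SEM}$, the 95 % minimal detectable
  change; the ratio to SEM is exact by construction.
* **CVs** — between participants, 100·SD/mean of per-participant trial
  means; within participants, the root-mean-square of per-participant CVs.

Descriptive tables pool the two trials within participant by mean before
medians and between-participant CVs; this pooling is switch-recorded in the
report metadata since group summaries depend on it. Quartiles use linear
interpolation of order statistics (R type 7) — stated because published
interquartile ranges are sensitive to the quartile rule.

Degenerate inputs behave predictably: duplicated trials give ICC = 1 and
SEM = MDC = 0; a cell with zero total variance returns an undefined ICC
with a warning rather than a spurious number.

## Numerical and design notes

* Time is seconds from recording start, 0-based; all intervals are
  half-open `[start, end)`, so a 300/60-s stage owns exactly 300 work and
  60 rest seconds on a 1-Hz grid.
* Peak workload with a partially completed final stage is prorated linearly
  over the increment to that stage; stage selection matches each target
  %Wpeak to the nearest stage within ±6 percentage points (observed
  workload spreads around the targets are ~1–3 points).
* The default study schedule (7 stages, 70 kg) places stages 3, 5 and 7 at
  exactly 50/75/100 % of peak workload, avoiding tie-breaks in target
  matching.
* Problem sizes used in the validation suite: 21 participants × 2 trials ×
  4 sites for study-level checks (504 scheduled bouts), 1 000 random series
  for the peak-rule oracle, and 500 simulated participants for the
  variance-component recovery of the ICC; these sizes give stable checks
  at interactive runtimes.
* Known limitations: the noise-driven upward bias of the peak rule (the
  earliest-no-higher-sample rule rides local noise maxima) inflates HRT
  slightly for low-amplitude, slow sites; the linear mixed-effects
  modelling of workload and site effects is out of scope and left to
  standard tools (`lme4`/`emmeans`); no motion-artifact *correction* is
  attempted, only flagging.
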