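---
title: "Arm-angle sleep detection: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-angle sleep detection: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcsleep)
```

## The method

Wrist-worn raw accelerometers record the gravity vector whenever the wrist is
still, which makes the orientation of the wrist — not the magnitude of
acceleration — a directly interpretable signal for sleep detection. arcsleep
implements a heuristic detector built on that idea:

1. **Arm angle.** For each sample, the angle of the z axis (perpendicular to
   the skin surface) relative to the horizontal plane is estimated as

   $$\mathrm{angle} = \arctan\!\left(\frac{a_z}{\sqrt{a_x^2+a_y^2}}\right)\cdot\frac{180}{\pi},$$

   where $a_x, a_y, a_z$ are per-axis *rolling medians* over a 5-s window.
   The median removes single-sample spikes; the angle depends only on $a_z$
   and the horizontal magnitude, so it is invariant to rotation about the
   vertical and to swapping the two horizontal axes.

2. **Epochs.** Per-sample angles are averaged into contiguous 5-s epochs
   anchored at the recording start; a trailing partial epoch is dropped.

3. **Sustained-inactivity bouts.** Maximal runs of epochs in which no change
   between successive epochs exceeds 5° and whose span is at least 5 minutes
   are classified as bouts of sustained inactivity — candidate sleep. A
   10-minute minimum span is the standard stricter alternative, and the
   grids 3/5/7/10/15 minutes × 3/5/10 degrees are used for validation.

4. **Nocturnal classification.** A simple sleep log (reported sleep-onset
   and waking clock times per night) separates nocturnal sleep from daytime
   stillness: bouts overlapping the reported sleep window are nocturnal.
   Per night, *sleep onset* is the start of the first nocturnal bout,
   *waking time* the end of the last, *time in bed* their difference, and
   *total sleep duration* the sum of nocturnal bout durations.

No parameter of the detector is fit to data; the thresholds are physical
quantities (degrees, minutes) chosen to pass static postures and reject
posture changes, which is what makes results comparable across devices and
studies.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `median_window_s` | 5 | s | spike rejection; centered, shrunk at edges |
| `epoch_s` | 5 | s | temporal resolution of the detector |
| `angle_threshold_deg` | 5 | deg | largest angle change tolerated within a bout |
| `min_bout_min` | 5 (alt. 10) | min | minimum stillness span counted as candidate sleep |

Threshold comparison is strict — a run breaks only when the adjacent-epoch
change is *larger than* the threshold; equality passes. Only adjacent
differences are tested, so slow drift below the threshold per epoch can
accumulate inside one bout; this is the literal reading of the criterion and
is kept deliberately. Longer minimum windows select a subset of the shorter
window's bouts (identical spans), so estimates under the 10-minute window
are never larger than under the 5-minute window — the deterministic skeleton
behind the empirical observation that sensitivity to sleep favours short
windows and high angle thresholds while specificity favours the reverse.

## Sleep-log handling

Nights are summarized over noon-to-noon windows; a day sleeper (reported
onset before noon *and* waking after noon, strict inequalities) gets an
18:00-to-18:00 window instead. Reported onset clock times from 18:00–23:59
resolve to the night's own date and 00:00–17:59 to the next date; the waking
time is the first occurrence of its clock time after the resolved onset.

Implausible entries are screened against the detected bouts: a night is
flagged when the reported onset and/or waking deviates by more than 4 hours
from the nearest bout start (for onset) or bout end (for waking). Log times
are point events, so they are compared with bout *edges*; measuring distance
to bout bodies (zero if inside) is a documented alternative that would only
loosen the screen. For flagged nights every candidate correction — a 12-h
shift of either time, swapping the two, and their combinations — is applied
hypothetically, and the fix that brings both deviations within the threshold
(smallest total deviation on ties) is *suggested*, never auto-applied:
`apply_log_fixes()` applies only unambiguous single-transform suggestions,
and nights with no qualifying fix are excluded as ambiguous. This mirrors
manual-review practice while keeping the procedure reproducible.

Validity rules per night, in order of precedence: the first and (if present)
ninth night of the protocol are excluded, then nights with less than 16 h of
detected wear time, then nights with missing or ambiguous log entries.
Wear time is evaluated over the full 24-h window, matching the wording of
the wear-time rule. Weekly averages weight weekday (Sunday–Thursday) and
weekend (Friday–Saturday) nights 5:2, and require at least one valid night
in each stratum.

## Agreement statistics

Weekly-average accelerometer estimates are rounded half-up to the nearest
integer hour and collapsed onto the 5-level scale ≤5, 6, 7, 8, ≥9 h (the
tie rule is half-up; the source only specifies "nearest integer").
Agreement with questionnaire sleep duration is summarized by a 5×5 confusion
matrix and weighted Cohen's kappa,

$$\hat\kappa_w = 1-\frac{\sum_{ij} w_{ij}\,o_{ij}}{\sum_{ij} w_{ij}\,e_{ij}},
\qquad w_{ij}=(i-j)^2,$$

with observed counts $o$ and chance-expected counts $e_{ij}=r_i c_j/N$.
The weight scheme was not named in the benchmark source; quadratic weights
were adopted because they reproduce all four published coefficients on the
published matrices (0.32, 0.36, 0.39, 0.18), which simultaneously validates
the implementation — linear weights remain selectable and give visibly
different values. The standard error is the asymptotic (Fleiss–Cohen–Everitt)
large-sample value with a normal-approximation interval; the source does not
state its interval construction, so intervals are reported but not treated
as a benchmark.

```{r kappa}
mats <- cohort_agreement_matrices()
weighted_kappa(mats$time_in_bed_5min)
weighted_kappa(mats$total_sleep_10min)
```

Degenerate margins (all mass in one category) make kappa undefined; the
result is flagged `NA` rather than forced. `stratified_agreement()` computes
one kappa per subgroup and flags strata below a minimum size.

## Polysomnography validation

Against a scored hypnogram, evaluation is restricted to the total sleep
period (lights out until final waking); truth per 30-s scoring epoch is
sleep for any non-wake stage. The detector works on 5-s epochs, so a 30-s
epoch is predicted asleep when at least 4 of its six 5-s epochs lie inside a
bout (majority rule); expanding the scoring labels to the 5-s grid
(`grid = "5s"`) is the documented alternative and agrees with the majority
rule whenever bouts align with the scoring grid. Accuracy, sensitivity
(w.r.t. sleep), specificity (w.r.t. wake) and bias (predicted minus
reference sleep, minutes) are computed per patient and then averaged —
mean ± SD *between* patients, not pooled — because per-patient degeneracies
(a night with no scored wake) must be flagged rather than diluted.
`parameter_sweep()` re-runs detection over the full window × angle grid; the
monotone set-inclusion of bouts guarantees predicted sleep time is
non-increasing in window length and non-decreasing in angle threshold on
*any* input, hence the sensitivity/specificity trends and the falling bias
down each fixed-angle column.

## The synthetic-data generator

Real multi-night raw data cannot ship with the package, so every module is
exercised against a seedable generator that emulates exactly the signal
structure the detector relies on:

* a **piecewise-constant gravity orientation**: posture changes are drawn as
  new orientations whose arm angle moves by 10–60° (always above the 5°
  threshold, so wake is detectable by construction), with a uniform azimuth;
* **wake** dwells ~ Exp(mean 60 s), capped at 240 s — daytime stillness
  never reaches the 5-min bout criterion, reflecting that extended motionless
  wake is what the log window, not the detector, is meant to handle;
* **sleep** dwells of 15 min minimum plus an exponential excess (mean
  20 min) — rare position shifts at least a quarter-hour apart;
* a forced posture change at each sleep/wake transition (falling asleep and
  waking up are movements), so detected bouts align with the true window;
* unit-norm gravity plus Gaussian sensor noise (SD 0.01 g per axis);
* a nightly schedule with onset 23:15 and waking 06:15 (7 h in bed, typical
  of objective measurements in older adults) and night-to-night SD 15 min.
  The 7-h window also keeps a 12-h AM/PM log error unambiguous: a flipped
  onset lands 12 h − 7 h = 5 h from the morning-side bout edges, decisively
  beyond the 4-h screening threshold, whereas an 8-h window would place such
  errors exactly at the threshold and make screening performance a coin
  toss;
* sleep logs as truth plus Gaussian reporting jitter (SD 10 min) with
  optional injected AM/PM flips and onset/waking swaps, bookkept so
  screening can be scored against the injected errors;
* hypnograms as a repeating non-REM/REM stage cycle over the true sleep
  period with wake blocks inserted at a configurable rate;
* optional daytime naps (Poisson per day, default off) that create genuine
  daytime bouts for exercising the nocturnal/daytime distinction.

What the generator does **not** emulate: sleep-stage physiology (stages are
decorative except wake), gradual drowsy movements around sleep onset,
device-specific noise spectra, temperature drift, and non-wear (wear status
is an input flag, per the package's scope). Passing tests therefore show
that the algorithmic chain is correct and well-behaved under the signal
model it assumes — not that the thresholds are optimal for any particular
population.

## Numerical and degenerate-input choices

* Rolling median: centered window, shrunk at the edges (first/last 2.5 s use
  the available samples); centered alignment minimizes phase lag. The
  window slides sample by sample, not strided.
* An all-zero median vector has no direction: the epoch is `NA`. `NA`
  epochs (also from non-wear) terminate runs and belong to no bout; nothing
  is interpolated.
* Epoch averaging uses exact contiguous blocks when the samples-per-epoch
  count is integral and time-based assignment otherwise (e.g. 85.70 Hz).
* A bout straddling a window boundary is assigned to the window containing
  its midpoint.
* Bouts overlapping the log window count at full extent; clipping to the
  window is available as `clip_to_log` but off by default, because the
  night-variable definitions refer to bout starts and ends.
* Duration categories round half-up; negative durations are rejected.
* Log-fix ties are broken by the smallest total deviation.

## Problem sizes used by the test suite

The packaged experiments run at sizes chosen to make their statistical
claims meaningful while staying desk-scale: bout detection is checked
against a brute-force maximal-run scan on 1,000 random series of up to
2,000 epochs; parameter recovery uses 200 simulated nights at the default
50 Hz (total sleep recovered within 15 min of truth on at least 95% of
nights with the 5-min/5° configuration, against the ground-truth sleep
window so the measured error isolates the detector); log screening is
scored on nights with all onsets AM/PM-flipped (all must be flagged with
the flip suggested) and on jitter-only nights (none may be flagged).
Several unit fixtures run the generator at reduced sampling rates
(0.2–10 Hz), which changes nothing about the detector's epoch-level
behaviour.

## Known limitations

* The detector measures *stillness*, not neurological sleep: motionless
  wake inside the log window counts as sleep, and restless sleep is
  truncated. The log window is what bounds the first error; nothing bounds
  the second.
* Cumulative drift within a bout is accepted by design; a slow continuous
  rotation of the wrist over many minutes stays inside one bout.
* The 4-h screening rule cannot flag log errors smaller than 4 h, and its
  power depends on the geometry of the true schedule (see the generator
  notes above).
* Kappa intervals use the asymptotic normal approximation; for very small
  strata prefer the flagged `NA`/small-n indicators over the interval.
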