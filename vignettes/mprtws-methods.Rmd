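---
title: "Methods: band scoring, temporal confirmation, and cohort evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band scoring, temporal confirmation, and cohort evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprtws)
```

## The problem

Early warning scores (EWS) flag hospitalized patients at risk of clinical
deterioration from routine vital signs. The standard NEWS aggregates five
vitals — systolic blood pressure, heart rate, respiratory rate, oxygen
saturation, and temperature — each banded into a 0–3 score, and escalates on
the summed total (≥ 7, or 5–6 for a medium response) or on any single
maximal "Red" parameter. In practice it is computed infrequently, by hand,
once per nursing shift.

Wearable chest-patch monitors change the data regime: nine vitals — the NEWS
five plus diastolic pressure, stroke volume (SV), cardiac output (CO), and
systemic vascular resistance (SVR) — every five minutes for up to 72 hours.
This package implements a warning score built for that regime, the
multi-parameter real-time warning score (MPRT-WS), together with a NEWS
comparator, the evaluation statistics needed to compare them on a cohort,
and a seeded simulator of wearable vital-sign streams so the whole pipeline
is testable without patient data.

## The score

**Per-parameter banding.** Each parameter has an ordered set of intervals
mapping its value to a score in $\{0,1,2,3\}$: 0 for the accepted normal
range, 1 for a slight deviation, up to 3 for a deviation implying immediate
risk. Band tables are data, not code: YAML files with per-parameter
`{lower, upper, score}` lists (`load_band_table()`), validated to be
pairwise disjoint and to cover $(-\infty, \infty)$.

All bands are half-open $[\ell, u)$. Published charts state inclusive
integer limits ("≤ 90"); these are transcribed as $u = 91$ (one unit of the
parameter's printed resolution, 0.1 for temperature). The convention makes
the partition property mechanically checkable — the test suite probes a fine
grid and asserts every value is owned by exactly one band — and makes
scoring a single `findInterval()` lookup on the lower bounds.

The shipped NEWS configuration is the standard published chart. For the
four hemodynamic parameters that NEWS does not cover, the shipped MPRT-WS
configuration bands them around accepted adult normal ranges (DBP 60–90
mmHg, SV 60–100 mL, CO 4–8 L/min, SVR 800–1200 dyn·s·cm⁻⁵) with stepwise
grade-1/2/3 deviations on both sides. These four are engineering defaults,
marked synthetic in the file, and are meant to be replaced by a clinically
validated site configuration; everything downstream is indifferent to the
specific cutoffs.

**Aggregation.** With $n_2$ = number of parameters scoring ≥ 2 and $n_3$ =
number scoring 3, the instantaneous MPRT-WS level is

* `URGENT` if $n_3 \ge 1$ — one immediately dangerous vital suffices;
* `HIGH` if $n_2 \ge 3$;
* `MEDIUM` if $n_2 = 2$;
* `LOW` otherwise — any number of grade-1 deviations never escalates.

The rule statement counts parameters "with a value of 2"; the implementation
counts scores ≥ 2 so that the level is monotone in every score. The two
readings coincide on every one of the $4^9$ possible score vectors (a 3
forces `URGENT` regardless), which the acceptance suite verifies
exhaustively. Missing parameter scores count as 0; a reading missing more
than `max_missing = 3` of the nine is unscorable and carries no level at
all, rather than a level built mostly on imputation.

The NEWS comparator scores only its five parameters and applies the
published aggregate rule (`HIGH` on total ≥ 7 or any Red score, `MEDIUM` on
5–6). Oxygen supplementation and the AVPU consciousness scale are
deliberately out of scope for both tools.

## Temporal confirmation

A single aberrant reading on a wearable is as likely to be a motion artifact
as a physiological event. An alert level is therefore *confirmed* at reading
$t$ only if it is the highest level $L$ such that the last $k$ readings
(including $t$) all have instantaneous level ≥ $L$ **and** span at most $w$
minutes; the defaults are $k = 2$, $w = 10$ at the native 5-minute cadence.
Within a qualifying window the confirmed level is simply the minimum
instantaneous level, so confirmed ≤ instantaneous everywhere, the first
$k-1$ readings of a stream confirm only `LOW`, and a transmission gap wider
than $w$ resets persistence (the span test subsumes the gap test, since any
in-window gap exceeding $w$ forces the span past $w$).

Two consequences matter for evaluation:

* **Spike suppression.** A stream whose only abnormalities are isolated
  single-reading excursions confirms nothing above `LOW` — verified as a
  property on simulated cohorts whose artifact process is the only
  abnormality source.
* **Cadence coupling.** At a 15-minute monitoring interval a literal
  10-minute span can never hold two readings, so *nothing* would confirm.
  The span is read as "two consecutive readings", and
  `confirmation_policy(interval = 15)` widens it to
  $k \times \mathrm{interval}$ = 30 min. The strict-span behaviour is kept
  as a regression test. `URGENT` is confirmed under the same rule as the
  other levels; real-time deployments that want instant urgency can pass
  `min_consecutive = 1`.

Down-sampling to a coarser interval (`resample_stream()`) keeps, for each
interval-aligned grid instant anchored at the patient's first reading, the
nearest reading in time, ties broken toward the earlier one.

## Evaluation statistics

An *event* is one confirmed reading at a level, so event counts are on the
order of total readings, and level *shares* are percentages of the summed
counts over the reported level set, rounded half-up to one decimal
(`round_half_up()`; base R's round-half-to-even is wrong for report
formatting). The Urgent share is reported against the four-level total;
the Low/Medium/High shares against the three-level total, matching EWS
reporting practice where Urgent is a real-time alarm rather than a warning
grade.

A deteriorating patient counts as *identified* when their first confirmed
alert (`HIGH`/`URGENT` for MPRT-WS, `HIGH` for NEWS) falls strictly before
the annotated deterioration time; sensitivity is identified / deteriorated,
and the lead time is the gap in hours, summarized as mean ± sample SD over
identified patients. Distributions are compared by Pearson chi-square on
the 2 × k table of per-reading counts (no continuity correction, k − 1 df)
and identified counts by a two-sided Fisher exact test, both delegated to
the standard `stats` routines; the test suite checks them against direct
$\sum (O-E)^2/E$ summation and exhaustive hypergeometric enumeration on all
small tables.

Per-parameter attribution asks, over the readings confirmed at a level,
how often each parameter is abnormal: score 3 for the `URGENT` panel,
score ≥ 2 otherwise (the grade that actually feeds that level's
definition). Fractions deliberately do not sum to one. Diagnosis-group
segmentation counts per-patient alert readings in which each parameter is
abnormal and summarizes them by median, quartiles, and 1.5 × IQR whiskers.

The published per-reading distribution comparison p-value could not be
reproduced from per-reading counts (the statistic at $n \sim 10^5$ readings
is enormous for even tiny share differences); the package computes and
reports the per-reading test and makes no claim of equivalence to any
published unit of analysis.

## The simulator

`generate_patient()` builds one stream as baseline + stationary AR(1) noise
per parameter: $x_i = \phi x_{i-1} + \sigma\sqrt{1-\phi^2}\, z_i$, with
$\phi = 0.8$ at 5-minute sampling, giving marginal SD exactly $\sigma$ and
smooth, physiologically plausible drift. Defaults: mid-normal adult
baselines (HR 75, SpO₂ 97.5, RR 16, SBP 120, DBP 75, temp 36.8 °C, SV 75,
CO 5.5, SVR 1000) with noise SDs of realistic within-patient wearable
variability (3, 0.8, 1.5, 6, 4, 0.15, 4, 0.35, 60 in the same order);
5-minute cadence; up to 72 h.

Deterioration is a linear ramp: each affected parameter moves from its
baseline to a representative value inside its configured target band
between `onset` and `onset + ramp`, then holds; the annotated deterioration
time is `onset + ramp`, so confirmed alerts during the ramp are genuine
early identification. The representative value is the band midpoint, or for
half-infinite bands the finite edge pushed one median-band-width inward —
deterministic, so noiseless lead times have a closed form that the
acceptance suite checks to within one cadence step. Artifacts are isolated
single-reading jumps into a grade-3 band with immediate return (the
generator enforces non-adjacency); missingness is i.i.d. per value. All
randomness flows from explicit integer seeds — per-patient seeds are drawn
deterministically from the master seed — and the generator restores the
caller's RNG state, so cohorts are reproducible bit for bit.

The named deterioration presets (`chf`, `cva`, `copd`, `ckd`, `arrhythmia`)
give distinct multi-parameter signatures loosely patterned on common
admission diagnoses. They are illustrative: the simulator emulates the
*sampling structure* the score assumes (cadence, persistence, dropout,
artifacts, ramp-like decline), not cardiovascular physiology. SVR and CO
are generated independently rather than derived from pressures and stroke
volume; there are no circadian rhythms, comorbidity mixtures, treatment
responses, or correlated sensor dropouts. Passing tests on synthetic
cohorts therefore validate the *machinery* — banding, aggregation,
confirmation, statistics — not clinical performance on real patients, which
only a validation study can establish.

## Numerical and design choices

* Half-open bands with +1-resolution transcription of inclusive limits
  (see above); band lookup by `findInterval`, validated against brute-force
  grid probing.
* Timestamps are minutes since stream start internally; file I/O accepts
  ISO-8601 and converts per patient. Values round-trip CSV at 8
  significant digits.
* Missing CSV cells are empty or `NA`; missing scores count 0 toward
  aggregation but flag the reading, with unscorability above 3 missing
  parameters.
* Percentages round half-up to one decimal; sensitivities are reported
  unrounded and formatted only at print time.
* Degenerate inputs: empty streams score and confirm to empty results;
  an empty cohort is a validation error for distribution reports; a single
  identified patient has undefined lead-time SD (`NA`, never 0).
* Acceptance-scale checks run on deliberately modest problem sizes — 100
  deteriorating patients at 12-hour streams for the sensitivity property,
  20 patients × 24 h for spike suppression, the full $4^9$ truth table for
  aggregation — chosen so the whole suite runs in well under a minute while
  leaving each property nowhere to hide.

## Known limitations

The four added-parameter band defaults are not clinically validated; the
aggregation constants (2-of-9 for `MEDIUM`, 3-of-9 for `HIGH`) are taken as
given, not re-derived; specificity and ROC analysis are out of scope; and
episode-level alarm logic (merging consecutive confirmed readings into one
clinical alarm, silencing, routing) is intentionally absent — an event here
is a reading, not a page to a clinician.
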