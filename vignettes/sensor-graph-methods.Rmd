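---
title: "Sensor graphs for in-home mobility performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor graphs for in-home mobility performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorgraph)
```

## Why performance, not capacity

Standardized geriatric assessments (SPPB, TUG) are administered a handful
of times a year, under supervision, and measure what a person *can* do.
Day-to-day mobility in the person's own home — what they actually *do* —
is a different construct, and observation itself can inflate test results
(the Hawthorne effect). A network of passive-infrared (PIR) motion sensors,
one or two per room, observes daily life unobtrusively: each firing is a
timestamped `(sensor, instant)` pair, and the sensor hardware enforces a
cool-down (8 s here) during which it cannot re-fire.

`sensorgraph` condenses such an event stream into one number per day — how
far the day's movement pattern sits from the person's own baseline — and
tracks that number over months.

## The model

**Daily graph.** A flat's rooms are the vertices of a weighted directed
multigraph. Scanning a day's events in time order, every consecutive pair
contributes one unit to the edge from the first event's room to the
second's (`apply_edge_update()` adds the single-entry unit matrix). The
adjacency matrix `D` of a day with `m` events therefore has total mass
`m − 1`; same-room pairs accumulate on the diagonal, which dominates in
practice because residents mostly stay put. Direction matters: kitchen →
living room is a different edge than living room → kitchen, and reversing
an event stream transposes the matrix.

**Masking.** Ordered room pairs with no direct door (the floor plan's
*impossible transitions*) get weight 0 (`mask_impossible()`). Counts
landing there cannot be the lone resident walking; they indicate visitors
or missed intermediate firings. Masking is applied to every daily matrix
*before* any aggregation, including the baseline's constituent days — the
alternative (masking only after averaging) differs only on impossible
cells, which are zeroed either way; doing it per-day keeps every
intermediate artifact interpretable on its own.

**Baseline.** `B` is the entrywise mean of the first `k = 7` valid
(present) days (`compute_baseline()`). One week covers the weekly routine
cycle, and a 7-day mean reproduces the characteristic value pattern of the
published reference baseline, whose cells sit on multiples of 1/7 (e.g. a
week of bathroom loops summing to 800 prints as 114.29). `k` is
configurable; the baseline's contributing dates are excluded from the
downstream series so change is measured against the window, not within it.

**Percent difference.** With the weight matrix `W` (`make_weight_matrix()`,
diagonal 1, off-diagonal 1.5 — transitions are walked, hence up-weighted),

$$\mathrm{diff}(B, D) = \sum_{i,j} w_{ij}\,(b_{ij} - d_{ij}), \qquad
pd = \frac{\mathrm{diff}(B, D)}{\sum_{i,j} w_{ij}\, b_{ij}}.$$

`pd` is linear in `D`, zero when the day equals baseline, 1 when the flat
is silent, and **negative when the day is more active than baseline**.
Under uniform scaling `D = (1 − c)·B` the statistic returns `c` exactly,
for any positive weight structure — the identity that makes injected
linear activity trends recoverable in closed form. Subtract-then-weight
and weight-then-subtract are algebraically identical; the implementation
subtracts first.

A note on sign: a *declining* resident produces a *rising* pd series
(growing loss relative to baseline). Reports that quote "activity changed
by −X %" under the opposite orientation are describing the same effect;
this package keeps the formula's orientation throughout and states it on
every output.

**Filtering.** Participants are excluded for death during the study, a
change of living situation, or a mobility-compromising incident
(`filter_participants()`). Days inside declared absence intervals are
removed from the series (`filter_absence_days()`); the intervals are
authoritative metadata, because a low event count alone cannot distinguish
absence from immobility — `detect_absence_candidates()` (default threshold
10 events/day) only *flags* days for record review.

**Trends and comparison.** Per-participant pd series are fitted by
ordinary least squares against days-since-first-valid-day
(`fit_linear_trend()`, via `stats::lm.fit`; an independent closed-form
normal-equations oracle guards it in the tests). Group fits *pool* all
(day, pd) points of a group — the simplest aggregation consistent with
unequal day counts; participants with more observed days weigh more, and a
per-participant-averaging variant is available (`method = "average"`).
Both group lines are evaluated on the common window `[0, L)`, `L` the
shortest participant span, and compared by a Wilcoxon signed-rank test on
the day-paired differences (`compare_group_fits()`): average ranks on
ties, exact null distribution for ≤ 25 untied pairs, otherwise the normal
approximation with tie and 0.5 continuity corrections. Applying a paired
test to two fitted straight lines makes the pairs fully dependent; the
procedure is reproduced as the method defines it, and the package does not
claim more for the resulting p-value than a standardized effect summary.
The unpaired cohort-disposition check (`cohort_bias_check()`) uses a
Mann–Whitney test per metric variable, since the compared cohorts are
independent groups.

## The synthetic cohort

Real PIR studies of frail older adults cannot be shipped with a package,
so the generator is a first-class module with ground truth, not a fixture.

**Resident model** (`resident_model()`). A semi-Markov process: dwell in
the current room for a log-normal time (means per room, e.g. living room
25 min, hallway 1.5 min; sdlog 0.6), then move to a *connected* room with
probability proportional to its attractiveness. The room's sensor fires on
entry and at a Poisson re-trigger rate while occupied (0.3–0.7 events/min
by room); nights (22:30–06:30) are spent in the bedroom at 0.05 events/min.
All emitted events pass through a per-sensor thinning that enforces the
8 s cool-down, exactly as the hardware would. The bedtime walk to the
bedroom follows a breadth-first shortest path over the floor plan, so
consecutive resident events are always topologically possible; visitor
noise (`inject_visitor_noise()`) is the only source of impossible pairs.
These defaults yield roughly 500–600 events per day — a moderately active
lone resident, in the range suggested by published single-day example
matrices.

**Activity trend.** Day `t` scales both movement initiation (1/dwell) and
re-trigger rates by `f(t) = multiplier · max(0, 1 + slope·t)`. Expected
daily event count is then proportional to `f(t)`, and because pd responds
linearly to uniform rate scaling, the expected pd slope is `−slope` — the
closed form every recovery test checks against.

**Reference cohort** (`cohort_spec()`). 15 participants — 9 intervention
with slope −1e−4/day (essentially flat) and 6 control with −1e−3/day — for
310 calendar days, per-participant log-normal rate multipliers
(sdlog 0.3), and Poisson(1.5) absence intervals of mean 5 days
(≈ 7.5 absence days per participant, giving ≈ 302 present days and a ≈ 303
day common analysis window). Monthly SPPB/TUG assessments carry small
linear capacity improvements (+0.16/+0.06 SPPB points, −0.10/−0.08 s TUG
over the study) with rounding and instrument bounds enforced. Everything
derives deterministically from one master seed.

**What the generator does not emulate.** Overlapping sensor coverage and
path-specific sensor placement; door/vibration/power sensors; weekly or
seasonal routine structure; correlated multi-day illness episodes;
nonlinear decline; real visitor behaviour (the noise model is uniform in
time and room). Passing recovery tests therefore demonstrates that the
*pipeline* is correct and sensitive under its stated assumptions — not
that PIR graphs measure mobility in any particular real cohort.

## Numerical and design choices

- **Timestamps** are ISO 8601; offset-less stamps are interpreted in a
  configurable zone (UTC default). Days are civil days in that zone, and
  event pairs spanning midnight form no transition, so each daily matrix
  is a function of that day's events alone.
- **Cool-down violations are reported, never silently dropped**
  (`validate_event_log()`): the 8 s rule describes hardware, so a
  violation flags data trouble rather than defining a cleaning step;
  `drop_cooldown_violations()` exists for explicit cleaning.
- **No maximum gap** between consecutive events: an evening-to-night
  bedroom pair within one civil day counts as a loop.
- **Multiple sensors in one room** collapse onto the room's vertex at
  load time; room granularity matches the published reference matrices.
- **Degenerate inputs**: a day with < 2 events yields the zero matrix; an
  all-zero baseline is an error (pd undefined); trend fits require two
  distinct abscissae; an all-zero paired difference vector returns the
  flagged degenerate comparison with p = 1.
- **Problem sizes.** Recovery tests run the full reference cohort over 20
  master seeds (≈ 4500 participant-days each); construction is verified
  against brute-force tallies on 1000 random streams up to 10 000 events
  and exhaustively on all 3-room streams of length ≤ 6. These sizes give
  the sign/ordering checks ≥ 6 standard errors of margin under the
  model's Monte-Carlo noise.

## Known limitations

- pd compares whole-day mass patterns; it cannot localize *when* in the
  day activity was lost, and two structurally different days can score
  alike.
- Pooled group fits weight participants by observed days; a participant
  with many days and an extreme trend can dominate a small group.
- The signed-rank comparison of fitted lines inherits full serial
  dependence (see above).
- Visitor contamination inside *possible* transitions is indistinguishable
  from resident activity; masking absorbs only the impossible part.
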