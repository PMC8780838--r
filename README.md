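# sensorgraph

Monitoring what older adults actually *do* at home, not just what they *can*
do in a test. Supervised assessments such as the Short Physical Performance
Battery (SPPB) and the Timed Up and Go (TUG) measure mobility **capacity**
under observation; day-to-day mobility **performance** in the person's own
flat can diverge from it. `sensorgraph` quantifies performance from
unobtrusive passive-infrared (PIR) motion sensors: it turns each day's
sensor firings into a room-transition graph, scores the day against a
personal baseline, and fits and compares longitudinal activity trends
between groups (e.g. an exercise-intervention group vs a control group).

## The sensor graph and the percent-difference statistic

A flat with rooms `V = {s0, …, s(n−1)}` is modelled as a weighted directed
multigraph. Every consecutive pair of sensor events adds 1 to the edge from
the first event's room to the second's, so a day with `m` events yields an
n×n adjacency matrix `D` with total mass `m − 1`; motion within one room
accumulates on the diagonal (loops). Ordered room pairs that are physically
impossible in the floor plan (e.g. bedroom → bathroom with no direct door)
are fixed to weight 0 — spurious counts there come from visitors or sensor
glitches, not the resident.

The baseline `B` is the entrywise mean of the first `k = 7` valid days.
With a weight matrix `W` (1 on the diagonal, 1.5 off it, up-weighting
transitions, which are walked and therefore most informative about
mobility), each day is scored by

    diff(B, D) = Σ_ij w_ij (b_ij − d_ij)
    pd         = diff(B, D) / Σ_ij w_ij b_ij

`pd = 0` means a day exactly like baseline, `pd > 0` less activity than
baseline (`pd = 1` is total loss), `pd < 0` more. Per-participant pd series
are cleaned of declared absence days (vacation, short-term care,
hospitalization), pooled per group into a least-squares line
`pd = a·day + b`, and the two groups' fitted daily values are compared with
a Wilcoxon signed-rank test.

Because real study data of this kind is privacy-sensitive, the package
includes a semi-Markov resident simulator (`simulate_participant()`,
`simulate_cohort()`): a lone resident dwells log-normally in connected
rooms, sensors fire on entry and at a Poisson re-trigger rate with an 8 s
cool-down, and group-level linear activity trends, absence calendars and
assessment records are injected with known ground truth — so every recovery
claim is testable.

## Worked example

The reference participant's published one-week baseline matrix `B` and a
random-day matrix `D` (5 rooms: bedroom, bathroom, kitchen, living room,
hallway):

```r
library(sensorgraph)
B <- read_adjacency("baseline.csv")   # or build with compute_baseline()
D <- read_adjacency("day.csv")
W <- make_weight_matrix(5)            # 1 on diagonal, 1.5 elsewhere
graph_diff(B, D, W)
#> [1] -21.1
100 * percent_difference(B, D, W)$pd
#> [1] -1.890850
```

The day carried 21.1 weighted units *more* activity than the baseline
(negative difference), i.e. activity 1.89 % above baseline.

A full synthetic study — 9 intervention participants with a near-flat
injected activity slope (−1e−4/day) and 6 control participants declining at
−1e−3/day over 310 days:

```r
res <- reference_study(seed = 1)
res$slopes
#> intervention      control
#> 9.709713e-05 9.623763e-04
100 * res$fitted_change
#> intervention      control
#>     2.942043    29.160001
res$comparison
#> <group_comparison> W = 132, z = -15.000, p = 7.3e-51, n = 303
```

Both recovered pd slopes are positive (activity loss relative to baseline),
the control group's fitted loss over the common 303-day window is ~29 % of
baseline against ~3 % for the intervention group — a slope ratio of ~10 —
and the paired signed-rank test rejects equality of the fitted group
activity far below α = 0.01.

The end-to-end pipeline with artifacts on disk (per-participant baselines,
difference series, trend report, comparison JSON, manifest):

```r
cfg <- run_config(out_dir = "out", cohort = cohort_spec(seed = 1))
run_pipeline(cfg)
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --simulate --seed 1
--out out/`.

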