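---
title: "From raw GPS logs to behavioural movement metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw GPS logs to behavioural movement metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmetrics)
```

## The problem

Consumer GPS loggers record one fix per second: a timestamp, latitude,
longitude and (optionally) elevation. In a field experiment — say, teams
walking a ~150 m course from a hidden start, past observers, across a
finish line, several rounds in a row — those raw fixes carry rich
behavioural signal: how fast people walk, how much they vary their pace,
how tightly a team clusters, how far they stray from the direct route.
`trackmetrics` extracts exactly those quantities and links them to
self-reported psychological state scores with a mixed model, so the whole
analysis reduces to familiar regression output.

This vignette explains the models and conventions behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable choice existed.

## Geometry kernel

All distances are great-circle (haversine) distances on a sphere of mean
Earth radius R = 6,371,000 m. At the sub-kilometre scale of a field
course, the difference from an ellipsoidal model is far below GPS noise
(centimetres), so the simpler and faster spherical model is used
throughout; there is deliberately no dependence on an external geodesy
library for the kernel, which keeps the package's numerical behaviour
fully specified and testable against independent oracles.

Route deviation rests on the spherical cross-track distance of a point x
from the great circle through a and b:

d_xt = | asin( sin(d(a,x)/R) · sin(θ(a,x) − θ(a,b)) ) | · R

The distance is unsigned: "which side of the route" carries no meaning in
the metric definitions.

Polygon containment and finish-line crossing are evaluated in a local
equirectangular projection (longitude scaled by cos of the local
latitude) centred on the geofence. For extents under ~1 km this planar
approximation agrees with the spherical geometry to well under 0.1%
(verified against oracles in the test suite); polygons wider than one
degree, or spanning the antimeridian, are rejected at construction.
Conventions chosen for determinism:

* polygon boundaries count as **inside** (a fix exactly on the edge opens
  a window);
* speed thresholds and gap thresholds are **strict** inequalities
  ("exceeds" means >, so an exactly-40 km/h step survives);
* a zero-length movement step never crosses a line.

## Data model

Tracks are plain tibbles, one row per fix (`participant_id`, `time` as
UTC POSIXct, `lat`, `lon`, `ele`), sorted with strictly increasing
timestamps per participant. Readers (`read_gpx()`, `read_track_csv()`
with a configurable column/format dialect) sort points, collapse
duplicate timestamps to the first occurrence with a warning, count and
skip unparseable rows, and assume naive timestamps are UTC. Participant
metadata (team, card type) lives in a separate table and is joined with
`attach_metadata()`; the join is idempotent and reports unmatched tracks.

## Quality control

Two fault types dominate consumer-logger data: position jumps from
momentary signal loss, and recording gaps. Cleaning works on *steps* (the
interval between consecutive fixes):

* `mask_unrealistic_speed()` masks steps whose implied speed exceeds
  40 km/h — far above anything a walking (or running) participant can
  produce, so such steps are signal artefacts;
* `mask_time_gaps()` masks steps whose time difference exceeds 1 s, i.e.
  any break in the 1 Hz cadence. The *positions* on either side are kept;
  only the step quantities (distance, speed) become missing. Keeping the
  fix preserves positional continuity for segmentation and intra-team
  alignment — masking hides a measurement, it does not delete a place.
* `drop_dead_sensors()` removes participants with fewer than
  `min_valid_points` clean steps (default 60 — one minute of clean
  walking), the signature of a logger that stopped recording.

A step carries at most one mask reason; the speed rule is evaluated
first, so a step that is both implausibly fast and gapped is reported as
a speed fault. Masking is idempotent and monotone in the thresholds (a
stricter threshold can only mask more). No interpolation is performed
across masked steps — downstream metrics simply treat them as missing.
Speed-masked fixes are additionally excluded from position-based metrics
(route deviation, intra-team distance), because a fix that produced an
impossible speed is itself suspect; gap-masked steps leave their fixes
trusted.

## Segmentation

An analysis window per participant and round is defined by two geofence
primitives: an **entry polygon** (in the motivating study, the area where
teams first became visible to observers) and a **finish line**. The
window opens at the first fix inside the polygon and closes at the first
fix after the step that crosses the line; the alternation
entry → crossing → entry … yields consecutively numbered rounds, and
fixes between a crossing and the next entry (the walk back to the start)
are ignored. A participant who enters but never crosses gets an open
window to the end of the track, flagged and warned about.

Each participant's start point is their own first in-polygon fix, and
their finish point is **interpolated** along the crossing step at the
crossing fraction, so it lies on the finish line itself rather than at
the up-to-one-second-late first fix beyond it. At walking speed that
interpolation removes up to ~1.5 m of bias from the route-deviation
baseline.

## The five movement variables

Per participant × round window (`track_metrics()`):

| variable | definition | units |
|---|---|---|
| speed | mean of clean per-step speeds | km/h |
| speed variation | sample SD (n−1) of those speeds | km/h |
| intra-team distance | time-average of the member's mean distance to co-present teammates at shared timestamps | m |
| route deviation | mean cross-track distance of trusted fixes to the start→finish great circle | m |
| route-deviation variation | sample SD of that series | m |

Choices worth stating explicitly:

* sample (n−1) standard deviations, the default of mainstream statistics
  environments;
* intra-team alignment is by **exact shared 1 Hz timestamps** — no
  interpolation across members; a member in a recording gap simply drops
  out of that second, and members co-present with a teammate at fewer
  than two timestamps get a missing value;
* the per-window scalar for route deviation is the **mean** of the
  per-fix series (the SD is its own variable); the mean is configurable
  ground truth for the regression stage;
* degenerate windows (coincident start and finish) yield missing metric
  fields with a flag rather than an error at table level.

## Outlier screening and the state model

Before model fitting, each outcome's values are screened with Tukey
fences: values outside [Q1 − 1.5·IQR, Q3 + 1.5·IQR] are flagged and
excluded from fitting (but retained in the table). Quartiles use linear
interpolation (`stats::quantile` type 7). The rule is intentionally not
idempotent — re-running it on survivors may flag more values — and it is
applied **once**. Intra-team distance is exempt from screening, an
exemption the motivating analysis adopted to preserve model convergence;
`build_model_table()` hard-codes it as the default. With fewer than four
finite values nothing is screened.

`fit_state_model()` fits, by REML via `lmerTest::lmer()`,

```
metric ~ round + illegal_card + alertness_target + cognitive_self_regulation +
         situational_self_awareness + fright + suppressed_impulses +
         contemplation_hostile_intent + awareness_movement_change +
         (round | team) + (round | team:participant)
```

a maximal random-effects structure for a design with participants nested
in teams measured over rounds: intercepts for team and for participant
within team, and a random slope for round. The grouping notation
"team/participant" is ambiguous about which level carries the round
slope, so the layout is configurable (`random = "both"` (default),
`"team"`, `"participant"`). Predictors enter on their 1–7 questionnaire
scale by default (`standardize = TRUE` rescales them to unit SD). Fixed
effects are checked for rank deficiency before fitting (collinear terms
are named in the error); p-values use the Satterthwaite approximation;
boundary (singular) fits — a variance component estimated at zero — are
reported via `glance()` but are not treated as failures, and in the
zero-variance limit the fixed-effect estimates coincide with ordinary
least squares (a property the test suite asserts). Non-convergence is
reported, never raised.

## The synthetic generator

`simulate_tracks()` emits a correlated random walk per team member at
1 Hz: the heading each second is a circular blend of the previous heading
(weight κ = `heading_persistence`, default 0.7) and the bearing to the
current waypoint, plus wrapped-Gaussian noise (default SD 12°); step
lengths are zero-truncated Normal(1.4, 0.25) m — typical adult walking
speed; a cohesion term pulls each member toward the team centroid by
`cohesion` × 5% of the offset per second. The course is 150 m from start
to finish with the entry polygon at mid-course, matching the scale of the
motivating field setting; after each crossing members loop back outside
the course for the next round, so the emitted log is one continuous 1 Hz
track per participant, exactly what the segmentation stage expects.
Defaults (4 teams × 4 members × 3 rounds) mirror a small field study.

`inject_anomalies()` degrades a clean trackset with the two fault types
QC targets, with exact bookkeeping: a *spike* displaces one fix ~30 m
sideways — note that this necessarily corrupts **both** adjacent steps,
and the truth table records both; a *gap* deletes two consecutive fixes,
leaving a 3 s step. Injection sites are kept at least five fixes apart so
faults never interact, which is what makes exact recovery (every masked
step is an injected one, every injected one is masked) a meaningful test.

`simulate_state_scores()` generates the questionnaire table with a known
linear model: states are drawn first (Normal(4, 1.2) clipped to the 1–7
scale; a Bernoulli(0.5) illegal-card indicator), then the outcome is
built as Σβ·state + team effect + participant effect + residual. Because
the outcome is computed *after* clipping, the planted β is exact, not
attenuated. With β = 0 the outcome is independent of every state — the
basis of the null-coverage test.

What the simulator does **not** emulate: GPS measurement noise per fix
(positions are exact up to the walk's own randomness), satellite-geometry
drift, multipath near buildings or trees, variable logging rates, or
strategic behaviour (evasion, distraction, pursuit). Passing tests on
synthetic data therefore demonstrate the correctness of the *computations*
— masking rules, window logic, metric formulas, model recovery — not that
any behavioural effect exists in real data.

## Problem sizes and numerics

The test suite and the acceptance script run on deliberately modest
sizes: geometry oracles on 1,000 random configurations, QC recovery on
4 teams × 4 members × 3 rounds (~35,000 fixes), and mixed-model recovery
on 100 replicates of a 16-team × 4-member × 3-round design (192 rows per
fit) — large enough for stable rates, small enough to run anywhere.
Numerical conventions: haversine inputs are clamped to [0, 1] before
`asin`; bearings are reduced to [0°, 360°); the boundary tolerance for
"on the polygon edge" is 10⁻⁹ m; parallel segments (determinant below
10·machine-ε) are treated as non-crossing; quantile type 7 everywhere.

## Known limitations

* Spherical Earth only; no ellipsoidal geodesics — irrelevant below a few
  kilometres but wrong for continental tracks.
* Polygons must not span the antimeridian; field sites near ±180°
  longitude would need re-anchoring.
* No map matching, smoothing, or elevation-aware distances.
* Intra-team distance requires exact timestamp alignment; loggers with
  clock skew would need resampling upstream.
* The mixed model assumes Gaussian residuals on the metric scale; heavy
  tails beyond what the Tukey screen removes are not otherwise handled.
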