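---
title: "Tracking art-making dynamics with a statechart: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking art-making dynamics with a statechart: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokechart)
```

## The problem and the model

A drawing session on a tablet produces a stream of low-level digital
observations: pen-down/move/up samples carrying `(t, x, y, pressure)`,
and color/tool selection events. `strokechart` decodes this stream into
timed behavioral states by executing a hierarchical, orthogonal
statechart of the artwork's construction, and derives a per-session
metrics table, visual/textual reports and cohort statistics from the
resulting occupancy trace.

The statechart's shape encodes the analysis assumptions:

* The session is either on or off; all events except the session start
  are rejected while off.
* While on, the creator is in exactly one of three exclusive modes —
  `Idle`, `Materials_Selecting` (entered on an explicit selection event
  and left on the next pen-down) or `Painting` (between a pen-down and
  its pen-up).
* While `Painting`, three regions are simultaneously active: the
  selected materials (one color leaf, one tool leaf), the stroke
  characteristics (velocity, gradient, pressure, running size classes)
  and the page use (quarter; center/boundary part). Concurrency is what
  makes cross sections — e.g. time per (color, tool) pair — well defined
  directly from the trace.

A `Materials_Selecting` period requires an explicit selection event: the
residual gap between strokes is counted as idle, because the recording
carries no other evidence that the sitter was choosing materials. The
two-way drawing/idle split therefore folds selection time into idle,
while `selecting_time` is also reported on its own line.

## Tunable parameters

All thresholds live in `studio_config()` and are serialized into every
session file, so a recording is interpretable without out-of-band
context.

| parameter | default | units | rationale |
|---|---|---|---|
| `velocity_thresholds` | 2, 10 | cm/s | typical session-average velocities in tablet drawing studies fall in 6–12 cm/s; the defaults place such averages in "medium" while separating deliberate tracing from sweeping motion |
| `pressure_thresholds` | 1/3, 2/3 | – | tertiles of the normalized pressure range; no standard exists |
| `size_thresholds` | 2, 10 | cm | "short" marks versus page-scale movements |
| `tool_widths` | 0.3 (eraser 1.2) | cm | nominal rendered widths; erasers are physically wider |
| `raster_cell` | 0.25 | cm | page-coverage grid; see numerical choices |
| `center_fraction` | 0.5 | – | the center part is a centered rectangle with half the page's linear dimensions, i.e. a quarter of its area |

The page default is 28 cm x 16 cm, the scale of a widescreen tablet
active area. Device sampling rate and pixel-to-cm conversion are
properties of the recording, declared in the session header; the package
makes no assumption about them.

## Conventions that matter for reproducibility

**Coordinates and angles.** The origin is the top-left page corner with
y growing downward (screen convention). The drawing direction (gradient)
is `atan2(-dy, dx)` in degrees, range (-180, 180], so 0° is rightward
and +90° is up the page; the compass region discretizes it into eight
45° sectors centered on 0, ±45, ±90, ±135 and 180°. The session-average
gradient is the direction of the length-weighted resultant of all
segment directions (equivalently, of the summed per-stroke
displacements); averaging angles arithmetically would create ±180°
wrap-around artifacts.

**Quarter and part ties.** Points exactly on the vertical midline count
as left, on the horizontal midline as top; points exactly on the center
rectangle's edge count as center. Arbitrary but fixed.

**Occupancy intervals.** The trace assigns each inter-sample interval
the classification computed at the sample opening it. Kinematic leaves
(velocity, gradient, pressure, size) use the trailing two-sample window;
the first sample of a stroke inherits the second's classification, a
single-sample stroke classifies as velocity 0 and angle 0, and a
zero-dt window keeps the previous class. Page-use leaves are instead
evaluated at the midpoint of the *forward* segment — the piece of
trajectory the interval actually covers — so that for streams sampled at
region boundaries (as the generator produces) quarter and part occupancy
match exact geometric clipping, rather than carrying one sample period
of quantization per crossing. On arbitrary streams the residual
quantization is bounded by the sample period per region crossing.

**Eraser accounting.** Eraser strokes are strokes: they count fully in
stroke counts, lengths and kinematics, since erasure re-forms the
composition. In color accounting, erasing is its own pseudo-color row
(`erase`) and eraser time is excluded from the real colors' occupancy;
color switches and the colors-used percentage are likewise counted over
non-eraser strokes only, while tool switches run over all strokes (the
eraser is a tool). Eraser sweeps do count toward `area_used_pct` — the
pen worked that area.

**Crossover naming.** A "horizontal crossover" crosses the *horizontal*
midline (movement between vertically adjacent quarters); vertical
strokes therefore produce horizontal crossovers. A sample pair crossing
both midlines at once increments both counters. Stroke-start crossovers
compare a stroke's first-sample quarter with the *previous stroke's
last-sample* quarter — where the hand last was — and count only
edge-adjacent quarters, not the diagonal pair.

## The synthetic generator and its ground truth

`realize_scripts()` turns stroke scripts — line, polyline, circle-arc
and zigzag primitives traced at constant speed with constant or ramping
pressure — into event streams sampled uniformly along arc length, always
including stroke endpoints, polyline vertices and page-region boundary
crossings. The attached ground truth is computed symbolically from the
script parameters, never from the sampled points: durations and
occupancies from length/speed, switch and crossover counts from the
script sequence and exact path geometry (segment clipping; analytic
arc–line intersections), the average gradient from summed displacements
(exact, because the length-weighted resultant of a polyline's segments
telescopes to its endpoint displacement). This independence is what
makes pipeline-recovery tests non-circular. `area_used_pct` has no
closed form for a union of swept capsules and is deliberately absent
from the ground truth; it is validated against a naive pixel-count
oracle instead.

The random generator (`random_session()`, `generate_cohort()`) draws
stroke counts (Poisson, mean 20), log-normal speeds (median 9.6 cm/s)
and stroke lengths (median 4 cm), Dirichlet-weighted color preferences,
Bernoulli eraser propensity (0.15) and a Beta(6.3, 3.7) idle fraction
(mean ≈ 0.63) — magnitudes chosen once to sit in the range reported for
adult tablet-drawing cohorts. What it emulates is metric coverage: every
region of the statechart gets exercised, and group differences appear
exactly where `cohort_spec()` plants them. What it does **not** emulate
is human motor control: no tremor, no curvature–speed coupling, no
semantic objects, no pen-tilt. Passing tests on generated sessions
therefore validate the *decoding and statistics*, not any claim about
real populations.

## Numerical choices

* **Canonical serialization.** Session files are JSON Lines with sorted
  keys and floats at fixed 1e-6 precision; records round their numeric
  payload to the same precision on construction, so write/read
  round-trips are exact identities and repeated writes are
  byte-identical. One micro-unit (1 µs, 10 nm) is far below tablet
  resolution.
* **Rasterization.** A page cell or pixel is covered when its center
  lies within half the tool width of a stroke segment (capsule test).
  The coverage estimate converges to the analytic swept area as
  `raster_cell` shrinks; 0.25 cm balances fidelity against the cost of
  scanning every segment's bounding box.
* **Deterministic images.** The canvas playback and the visual report
  are composed by a pure-R raster painter and written with
  `png::writePNG`, so identical inputs yield byte-identical files — a
  property graphics devices do not guarantee. The visual report draws
  every painting-region interval of the trace (bands for color, tool,
  quarter, part; wrap-aware line plots for pressure and gradient; gray
  erase epochs; canvas snapshots at stroke-count quartiles).
* **Degenerate inputs.** Sessions with zero drawing time report 0 for
  per-drawing-time percentages and are flagged `degenerate`; truncated
  streams close the open stroke at the last sample with a warning;
  drawing before any selection assumes the first configured color and
  tool, with a warning.

## Statistical design

`compare_groups()` runs a two-sided Welch *t*-test on means — safer than
the pooled-variance form at group sizes like 6 — and a two-sided
Wilcoxon rank-sum on the same values, exact when the combined sample is
at most 20 with no ties, otherwise normal-approximate with tie and
continuity correction. Raw p-values are reported without multiplicity
correction by default, matching exploratory practice in small cohort
studies; Benjamini–Hochberg columns are available behind
`adjust = "BH"` and are clearly marked as an extension. A scan flags a
metric when its mean test is significant (`sig_t`); the subset
significant under *both* tests (`sig_both`) is reported as the
conservative headline set — the two-test convention — and is by
construction no more liberal than either test alone. Note the exact
rank-sum test is conservative at n = 6 + 6: its attainable two-sided
size at nominal α = 0.05 is 0.041. Pooling tasks treats repeated
sessions of one subject as independent observations; this mirrors
common practice in small exploratory cohorts but is a real limitation —
a mixed-effects treatment of the repeated measures is out of scope.

## Validation problem sizes

The shipped test suite validates ground-truth recovery on 25 scripted
sessions sampled at 100 Hz (integer metrics exact; continuous metrics
within 0.5% relative), conservation invariants on 500 random sessions at
50 Hz, dual-path (trace versus direct stroke-derived) occupancy
equality within 1e-9 on the fixtures plus 100 random sessions,
statechart region-consistency on every intermediate configuration, null
calibration of both tests at n = 6 + 6 over 10,000 replicates, power
against a planted 2-SD velocity shift over 1,000 replicates, and
byte-level determinism of all written artifacts. These sizes are the
package's chosen validation scale; all are re-run by
`scripts/acceptance.R` at a user-supplied seed.

## Known limitations

* Native session logs of commercial digital-art applications are not
  parsed; the documented JSONL schema is the ingestion contract, and a
  vendor-specific adapter would sit upstream of it.
* `Client`, `ArtTherapist` (and any music-session analogue) exist as
  structural stubs only; no events drive them.
* Rendering approximates strokes as constant-width capsule sweeps — no
  brush texture, blending or wet mixing; the eraser restores background
  along its sweep.
* Semantic interpretation (recognizing a "house" or a "diamond") is
  narrative, not computational, and out of scope.
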