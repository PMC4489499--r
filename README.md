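# strokechart

Quantitative process analytics for digital art-making sessions.

When a person draws on a tablet, the finished picture hides most of what
happened: how long the hand hovered idle, what was drawn and then erased,
how fast and how hard the strokes were made, which colors and tools were
tried and abandoned, and where on the page the work concentrated.
`strokechart` decodes a raw tablet event stream — timestamped pen
coordinates and pressure plus color/tool selections — into timed
behavioral states and a table of process metrics, for researchers and
art-therapy practitioners who want to study the *construction process* of
an artwork rather than only its end product.

## The model

The tracker executes a **statechart** (a hierarchical state machine with
orthogonal regions) of the artwork's construction over the session's event
stream. At the top, the art-room session toggles on/off. While on, the
creator is in exactly one of three exclusive modes:

```
ArtWork = Idle | Materials_Selecting | Painting
```

While `Painting`, three regions are active *simultaneously*:

* **Materials_Selected** — one leaf per palette color and one per tool;
* **Stroke_Characteristics** — velocity class (low/medium/high, thresholds
  2 and 10 cm/s), drawing direction as one of eight 45° compass sectors
  (0° = rightward, +90° = up the page), pressure class (tertiles of
  [0, 1]), and running stroke-size class (< 2 cm short, > 10 cm long);
* **Page_Use** — the page quarter (Q1 top-left, Q2 bottom-left, Q3
  top-right, Q4 bottom-right) and the center/boundary part.

Executing the statechart yields a timed trace — which states were active
over which spans — from which the per-session metrics table is computed:
drawing vs. idle percentage, per-color and per-tool occupancy (with
erasing as its own pseudo-color), switching counts, stroke kinematics
(total length *L*, average velocity *L*/drawing-time, duration-weighted
pressure, length-weighted circular mean direction), page coverage by
swept-stroke rasterization, and midline/quarter crossover counts.
Cohort comparisons use the two-test convention: a two-sided Welch
*t*-test on group means and a Wilcoxon rank-sum test on medians, flagged
at a chosen α, with the "significant under both" subset reported as the
headline set.

Because raw recordings from such studies are rarely publishable, the
package ships a synthetic session generator: stroke scripts (lines,
polylines, arcs, zigzags at constant speed) are realized into event
streams while the exact metrics they imply are computed symbolically from
the script parameters — so the whole pipeline is testable against
closed-form ground truth, and seeded random cohorts support calibration
and power studies.

## Worked example

```r
library(strokechart)

fx <- bundled_fixtures(sample_rate = 100)   # scripted demo sessions
m  <- compute_metrics(fx$three_object$record)
writeLines(head(textual_report(m), 6))
```

```
=== session ===
session duration (s): 37.943
drawing time (s): 19.943
drawing time (pct): 52.6
idle time (pct): 47.4
selecting time (s): 7.250
```

The `three_object` fixture draws a rectangle, a diamond and a circle, then
a fourth object that is removed by six eraser strokes; the tracker reports
13 strokes, 144.5 cm of total stroke length, an average velocity of
7.25 cm/s, and 25.1% of drawing time spent erasing. Playback
(`render_canvas(record, t)`) at the session end is pixel-identical to a
session in which the erased object was never drawn.

A cohort with a planted velocity difference is recovered by the group
comparison:

```r
spec <- cohort_spec(groups = c("F", "M"), subjects_per_group = 6,
                    tasks = c("positive", "negative", "htp"),
                    params = session_params(stroke_count_mean = 8),
                    group_overrides = list(F = list(speed_median = 19.2)),
                    seed = 2024)
coh   <- generate_cohort(spec, sample_rate = 25)
frame <- aggregate_sessions(coh$records)
compare_groups(frame, "avg_velocity", "gender")
```

```
        metric n1 n2 mean1 mean2       p_t       p_w sig_both
1 avg_velocity 18 18  17.4 8.055 2.207e-09 4.503e-07     TRUE
```

The command line mirrors this:
`Rscript inst/cli/strokechart.R track session.jsonl`,
`... report session.jsonl --out dir/`,
`... simulate --seed 1 --out dir/`,
`... compare --dir dir/ --group gender`.

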