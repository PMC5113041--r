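---
title: "elegansim: model, numerics and validation conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{elegansim: model, numerics and validation conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elegansim)
```

## The model and its assumptions

`elegansim` simulates early *C. elegans* embryogenesis as a set of cell
agents in an ellipsoidal eggshell. The model is deliberately *descriptive*:
division timing, division direction and migration endpoints are read from
tables of per-cell observations (means and standard deviations), not
derived from mechanism. The assumptions this entails:

* **Invariant lineage.** Each cell's identity is its name; the direction
  table fixes which two daughters every dividing cell produces. Stochastic
  timing never changes the topology, only when divisions happen.
* **Two-phase movement.** A cell is either in its *split phase* (the first
  90 s after its birth, while the sister pair separates) or in *interphase*
  (target-seeking migration). There is no mechanical interaction between
  cells: no pushing, adhesion, or volume exclusion beyond the eggshell.
* **Gaussian timing noise.** A cell's realized division time is
  `60 * (divTime + e)` seconds with `e ~ Normal(0, divSd)` in minutes. An
  SD recorded as `-1` ("unavailable") is carried as `NA` and contributes
  zero noise — the only choice that adds no information the table does not
  contain.
* **No death, no fate change.** The population is non-decreasing and each
  division adds exactly one cell; cells without a direction-table row are
  terminal and simply persist.

Each agent also carries an opaque `extension_state`-style slot in spirit:
the agent table is a plain data frame, so future per-cell annotations
(gene lists, fate labels, interaction state) can be added as columns
without touching the engine. No such mechanism is modeled or validated
here.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `div_cycle_time` | s | 90 | duration of the daughter-separation phase |
| `out_time_resolution` | s | 60 | snapshot cadence of the nuclei output |
| `tick_length` | s | 1 | the only granularity at which 90 s and 60 s are both whole numbers of ticks |
| `sd_policy` | — | `"div_time"` | perturb absolute division times; validation compares absolute born/divided times, so this is the column whose noise the comparisons see. The `"cycle"` policy (birth + perturbed cycle) is the fallback when `divTime` is unavailable, and vice versa |
| `size_rule` | — | `"halve_volume"` | daughter diameter = parent × 2^(−1/3), conserving total volume; `"inherit"` keeps the parent diameter (under Eq-1 kinematics, sibling separation at split-phase end always equals the *daughters'* assigned diameter, so `"inherit"` makes it equal the parent diameter) |
| `deterministic` | — | `FALSE` | forces all SDs to 0; runs become seed-independent |

Schedule tables are in minutes (their natural observational unit); the
engine works in seconds. The ×60 conversion is applied exactly once, when
a concrete division time is drawn.

## Numerical choices

* **Kinematic readings.** The split-phase update adds
  `direction * (size/2) / div_cycle_time` per tick, so the whole phase
  displaces each daughter by half its diameter. The interphase update is
  read as a *displacement*, `(target − position)/(div_time − clock)` added
  to the current position: this is the dimensionally consistent reading
  under which repeated application lands the cell exactly on target at its
  division tick (an invariant the test suite checks to 1e-9).
* **Tick grid and rounding.** Drawn division times are rounded to the 1 s
  tick grid, half up, when assigned. The division test is `clock >=
  div_time`, checked before movement, so a cell divides on the first tick
  at or past its schedule and the interphase denominator always counts
  whole ticks.
* **Within-tick ordering.** Dividing cells are processed in lexicographic
  name order, and RNG draws for daughters are consumed in daughter order
  within each division. This makes runs bit-reproducible for a fixed seed
  (a deliberate departure from platforms that randomize agent order).
* **Eggshell.** Containment is the closed inequality
  `sum(((p - c)/a)^2) <= 1`; an escaped cell is projected radially onto the
  surface (idempotently, with a one-ulp guard so the projected point always
  tests inside). When no eggshell is supplied, semi-axes default to 1.1 ×
  the per-axis extent of the target positions about their centroid — wide
  enough that tabulated destinations are never clipped.
* **Degenerate inputs.** A terminal cell whose division time has passed is
  held at its target; a terminal cell with no schedule row simply stops
  after its split phase. A dividing cell missing from the schedule or
  position tables is an error, surfaced by the table lint before a run
  starts.

## Snapshot format and lineage quantization

The output dialect has 20 comma-separated fields: five linkage fields
(per-time-point index, a validity flag fixed at 1, predecessor index, two
successor indices with −1 for "none"), then x, y, z, diameter, name, then
ten reserved fields written as zeros except the blank fifteenth. Time
points are separated by `# time <s>` headers; numbers are written with
enough digits that `read_snapshot(write_snapshot(x))` is exact.

`build_lineage()` tracks cells through predecessor indices. A cell's
`born`/`divided` times are therefore quantized to the 60 s snapshot grid:
daughters born at engine time 754 s first appear in the 780 s snapshot,
which becomes both their `born` time and the parent's `divided` time.
Cycle-length
comparisons against exact schedules consequently carry up to one snapshot
interval of error per endpoint; tests bound this at two intervals plus
realized timing noise. Two divisions inside one snapshot interval on the
same branch cannot be represented (the format allows at most two
successors) and raise a structural error; fixture cycle lengths are kept
well above the snapshot interval so this cannot occur there.

## Validation conventions

* **Count sampling.** Counts are paired every 5 minutes. Preference order
  at each target minute: exact match in both series; nearest minute with
  data in both (ties to the earlier time); otherwise the
  minimum-time-difference pair, in which case the two sampling times may
  differ. Candidates are confined to one interval-wide window per target.
* **Two RMSE variants.** The count and cycle comparisons use
  `sqrt(sum(d^2)/(n-1))`. The per-axis dividing-position aggregates in the
  bundled reference are reproducible only as `sqrt(sum(d^2))` — with the
  n−1 divisor the x-axis aggregate would be 0.0018 rather than the
  recorded 0.0059. Both variants sit behind `rmse(use_bessel = )`; the
  position report defaults to the no-divisor variant so the recorded
  aggregates are reproducible, and the inconsistency is documented rather
  than silently "fixed".
* **Reference deviations are data.** In the bundled dividing-position
  table, one row's recorded per-axis deviation differs from the
  recomputed `|sim − obs|` of the same row's coordinates (cell C, x axis:
  recorded 0.0004 vs recomputed 0.0067). The aggregate statistics
  therefore operate on the recorded deviation columns as-is;
  `position_report()` recomputes deviations only for fresh data.
* **Cycle SD propagation** is the quadrature `sqrt(born_sd^2 +
  divided_sd^2)`, and the headline pass criterion counts cells whose cycle
  deviation is below 0.6 × that propagated SD.

## What the fixture generator emulates — and what it does not

`make_fixture()` produces a complete binary lineage with `a`/`p`-suffixed
names, per-cell schedules accumulated root-to-leaf, random unit division
directions, and targets rejection-sampled inside 0.9 × the eggshell (the
margin leaves room for split-phase excursions without clipping). Defaults
are chosen to resemble a wild-type early embryo: four founders, ~15 min
mean cycles with ±3 min cell-to-cell spread, 0.5 min timing SDs, an
eggshell of semi-axes 25 × 15 × 15 units, 8-unit founders. Cycle draws are
floored at 150 s so every cycle comfortably exceeds the 90 s split phase.

What fixtures deliberately do *not* emulate: real wild-type geometry (the
stereotyped positions of the ~350-cell stage), correlated division-axis
patterns, asymmetric cycle lengths between sisters, or observational
artifacts such as tracking dropouts. Passing fixture-based tests therefore
demonstrates that the *mechanics* — arrival on target, sibling separation,
topology recovery, seed determinism, SD recovery — are correct, not that
simulated embryos are biologically accurate; biological accuracy is
exactly what the wild-type reference comparisons quantify.

## Problem sizes used by the test suite

The suite favors small, fast configurations: 4-founder/2-generation
fixtures (28 cells) with ~5 min cycles for end-to-end runs, 20 seeded
replicates for topology recovery, and 1000 seeded single-division runs for
Monte-Carlo recovery of the tabulated SD (relative tolerance 10%, against
a sampling error of ~2.2% at n = 1000). The full suite completes in a few
minutes on one CPU.

## Known limitations

* No cell–cell forces, adhesion, polarity signaling, fate regulation or
  cell death; these are reserved extension points, not modeled behavior.
* Movement is straight-line target interpolation; real interphase nuclei
  meander and respond to neighbors.
* The eggshell correction is a radial projection — cells do not slide
  along the shell, they stop at it.
* Lineage times rebuilt from snapshots are quantized to the output
  resolution; analyses needing exact division times should read the
  division log of `simulate_embryo()` instead.
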