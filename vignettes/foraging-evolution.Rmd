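---
title: "An event-driven model of evolving foraging decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An event-driven model of evolving foraging decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forevol)
```

## The model

`forevol` simulates foragers on a square lattice of resource items. Behavior
is *pause-travel* (intermittent) search: movement, scanning and eating are
mutually exclusive actions that each take time, so an individual must decide,
on completing one action, what to do next. The model is event-driven — the
individual with the earliest action-completion time acts next — rather than
stepped on a global clock.

Four actions exist:

* **MOVE** — turn by the heritable angle `a_t` (side chosen at random), step
  `d_m` metres in `t_m` minutes. Realized speed is capped at 0.1 m/s
  (360 m/h) by extending the duration, so evolving a long step cannot buy
  free speed. At the field edge the forager draws a fresh random heading.
* **FOODSCAN** — search for `t_fs` minutes over a sector of radius `d_fs`
  and full angle `a_fs` about the heading. Items are only detectable within
  2 m; each candidate item is independently detected with probability
  `1 − exp(−r·t/A)`, where `t` is the scan time in seconds, `A` the sector
  area `π·d_fs²·a_fs/360` in m², and `r = 1 s⁻¹m⁻²`. The form saturates,
  rises with scan time, and falls with the area over which the effort is
  spread; scanning beyond the 2-m detection cap enlarges `A` without adding
  detectable items, which is precisely the cost of over-long scan radii. The
  closest detected item is chosen (ties at random).
* **MOVETOFOOD** — approach a chosen item that lies beyond the 0.9-m reach,
  stopping half a reach (0.45 m) short, in 10 s.
* **EAT** — consume the item in 10 s for 2 energy units.

Decision making is a small state machine over the last action and — in one
model variant — the last scan's outcome. After MOVE, the forager repeats
MOVE with probability `p_mm`, otherwise scans. After a scan that found food
it eats (or first approaches). After EAT or after a scan that found nothing
it scans again with a heritable probability, otherwise moves. The
**restricted** architecture has a single such probability `p_ss`, so the
decision to rescan is blind to whether the last scan succeeded; the
**extended** architecture splits it into `p_se` (after eating) and `p_sn`
(after finding nothing), and additionally lets the approach probability
`p_mtf` evolve (the restricted model always approaches). This one-bit
difference in usable memory is the package's central comparison.

## Energetics, demography, evolution

Metabolism drains 1 unit/min (charged exactly, at each individual's events);
an empty store is death. At 100,000 units the store halves and the other
half founds a single offspring, so birth intervals shorten with intake and
selection emerges purely from competition over shared, depletable resources
— no fitness function is prescribed. Background mortality is 0.1/year
(compounded continuously per elapsed interval); maximum age is 10 years.

Offspring inherit each gene with mutation probability 0.05, the new value
drawn normally around the mother's with a step of roughly 20% of the gene's
reasonable range (0.4 min for durations, 2 m for distances, 72° for angles,
0.2 for probabilities) and clamped to the bounds (durations 0.167–1.99 min,
distances ≥ 0, angles 0–360°, probabilities 0–1). Clamping rather than
resampling keeps the operator simple and monotone; the choice matters only
at the bounds, where the attractors of interest sit anyway (e.g. `p_se → 1`).

Evolutionary runs start from a deliberately non-viable "zero" state (all
genes at their lower bounds) with a rescue rule: while the population has
never yet doubled the 10-head floor, any shortfall below the floor is filled
by births whose mothers are drawn with probability proportional to energy.
Rescue offspring receive the standard offspring endowment (half the birth
threshold). Pure halving of the mother's store would defeat the rule's
purpose — once the founders' stores drain, halved inheritances are zero and
every rescue child would starve within one action — so the endowment is
fixed; ordinary births transfer the halved store. Once the living population
reaches twice the floor the rescue rule is permanently retired; a doubled
floor rather than a single crossing avoids flapping when the population
hovers at 10–11.

Two engine conventions worth knowing: equal completion times resolve by
ascending individual id (determinism), and an EAT whose item was taken by a
competitor during the 10-s handling fails gracefully — the forager registers
a "no food" outcome and decides from there. Newborns and founders begin with
a FOODSCAN.

## Environments

The reference field is 5660 × 5660 m (1-m lattice, 32,035,600 cells). In the
*patchy* layout 8000 circles of radius 20 m are dropped uniformly at random;
every covered cell holds 2 items, overlap does not stack (the first-placed
patch claims the cell), giving ≈ 17.15 million items. The *uniform* layout
places one item per cell with probability 0.535 — chosen to match the patchy
total. Every item reappears once a year at a fixed random time (all items of
a patch share one time); all placed items are present at the start of a run,
so the first scheduled "appearance" acts purely as a renewal. A *mixed*
layout combines half of each budget, a cell claimed by both taking the patch
count.

Cells are unit squares with integer-coordinate centers; positions are
continuous; distances are measured center-to-point.

## Scaled-down experiment presets

The reference experiments (1000 years, 10 replicates, ~125 individuals) are
far beyond a desktop test budget, so the package ships presets that scale
them differently depending on what must be preserved:

* `preset_evolution_mini()` — **space and time scaled**: an 800-m field with
  the patch count scaled by area (160), a 50-day year (36,000 min), and the
  birth threshold scaled by the same factor (13,700 units), run for 80
  years. This keeps the per-minute energy economy, patch geometry, action
  timescales and the depleted-density regime intact while fitting enough
  generations (~1,500 births) for the decision-making attractors to emerge.
  The carrying capacity is ~20 foragers. With 5 seeds per condition a full
  four-condition comparison runs in ~10 minutes.
* `preset_ecology_mini()` — **area-only scaled**, like the reference
  ecological procedure itself (which used a smaller 4000-m field at its
  carrying capacity of 65): a 1750-m field, full 262,800-min year, 765
  patches, and a fixed population of 20 — the size at which steady-state
  depletion falls inside the 0.01–0.05 items/m² band that evolving
  populations forage in. Scaling time here would inflate per-area forager
  density several-fold and distort competitive rankings, so the year is
  left whole.
* Landscape scans use the evolution-mini environment with one genotype pair
  per grid point and ~40 individual-year samples per point.

The vignette-level caveat: at these scales the *decision-making* attractors
(`p_se → 1`, no repeat scanning for the restricted uniform specialist,
intermediate repeat scanning with full-circle search for the restricted
patch specialist) reproduce reliably, but slowly-selected quantitative
features do not always converge within 80 years — `p_sn` in the uniform
environment and the extended patch specialist's long move step are
weakly-selected, late-converging traits in the reference results as well,
and some seeds are still mid-transient when the run ends. Passing the
scaled-down tests therefore demonstrates the mechanisms, not equivalence
with the full-scale quantitative outcomes.

## Synthetic specialists

Downstream comparisons need one representative evolved genotype per
model-by-environment combination. The exact evolved parameter tables of the
original experiments are not available to this package, so
`specialist_genotypes()` ships *synthetic* stand-ins fixed once from the
qualitative descriptions of the attractors: both extended specialists with
`p_se = 1, p_sn = 0`; R-Patchy with intermediate `p_ss = 0.45`, the shortest
step (1 m) and a full-circle scan; R-Uni with `p_ss = 0.02` and a 2-m step;
Ext-Uni stepping 1.35× further than R-Uni; Ext-Patchy with the longest step
(8 m), the only repeat-MOVE (0.35) and turning (25°); all scan radii at
2.2 m (within the reported 2–2.5 m convergence band) and durations at the
0.167-min minimum. Conclusions that depend on fine placement of these
values — in particular printed percentage contrasts between specialists —
should not be read off runs made with them.

## Analyses

`yearly_intake()` counts ate-events per individual-year.
`segment_patch_visits()` is deliberately *eat-anchored*: a patch visit opens
at the first EAT inside a patch disc and closes at the last EAT there before
an EAT elsewhere, so pass-throughs without feeding are not visits; an
inter-patch travel is the interval between consecutive visits to distinct
patches, and the inter-patch travel rate is the inverse mean travel
duration. Patch size is measured as available items at visit entry, which
captures the effectively smaller patches produced by partial depletion. The
engine accumulates the same visit statistics internally (per individual and
calendar year) so that landscape scans do not need event logs.

`movement_summary()` flags two-scale movement by splitting log-displacements
between consecutive eats with 1-d k-means and comparing the cluster gap with
the pooled within-cluster spread (flag at gap ≥ 4 pooled s.d. and ≥ 10% mass
in each cluster). Unimodal samples split artificially at ~2.5–3.5 s.d., so
the default threshold separates the regimes with margin on constructed data;
it is an indicator, not a test statistic.

## Numerical and engineering notes

* The event queue is a binary heap with lazy invalidation; ties break by id.
* Renewal walks a per-year pointer over cells sorted by appearance time —
  O(renewals), independent of field size.
* The engine's spatial query scans only the ≤ (2·ceil(r)+1)² neighborhood of
  lattice cells; the R-level `visible_items()` is the same contract
  implemented vectorized, and the test suite proves both equal to a
  brute-force all-cells filter on small worlds.
* The C++ engine carries three independent RNG streams (behavior,
  demography, mutation) seeded from the user seed, so runs are reproducible
  bit-for-bit; pure-R reference implementations of every behavioral
  operation back the engine in the test suite.
* World construction at the reference scale (32 M cells, 17 M items) takes a
  few seconds and ~0.5 GB transiently.

## Known limitations

* Activity is not restricted to daylight; the 720-min day is an accounting
  unit (the year is 365 × 720 min), as in the reference configuration.
* No movement energetics, learning, or memory beyond the one-bit scan
  outcome; no recombination.
* The mixed-environment layout and the intermediate-patchiness configuration
  are available as specs but have no shipped acceptance checks.
* Scaled-down runs under-converge weakly-selected traits (see above); the
  full-scale configuration is available behind the same interfaces for
  anyone with the patience.
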