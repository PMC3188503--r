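# forevol

An event-driven, spatially explicit individual-based model of foraging, for
studying how local decision making shapes large-scale movement patterns and
how both evolve under pure resource competition. It is aimed at evolutionary
ecologists and movement modellers who want a fast, reproducible simulator of
*pause-travel* (intermittent) search with heritable behavior.

## The model in brief

Foragers on a lattice resource world alternate four mutually exclusive,
time-consuming actions — MOVE, FOODSCAN, MOVETOFOOD, EAT — scheduled by an
event queue (whoever finishes first acts next). A FOODSCAN over a sector of
radius *d_fs* and angle *a_fs* detects each available item within 2 m
independently with probability

P(detect) = 1 − exp(−r·t/A),  A = π·d_fs²·(a_fs/360),  r = 1 s⁻¹m⁻²,

and the forager eats the closest detected item (reach 0.9 m; otherwise it
first approaches to within 0.45 m). Decision making is a state machine with
heritable transition probabilities; the package's central comparison is
between a **restricted** architecture, whose probability of repeating a
FOODSCAN (*p_ss*) is blind to the scan outcome, and an **extended**
architecture that conditions it on whether the last scan found food (*p_se*
after eating, *p_sn* after finding nothing). Eating yields 2 energy units,
metabolism drains 1 unit/min, a full 100,000-unit store halves into a single
offspring, and genes mutate at 0.05 per gene with ~20%-of-range normal
steps. Worlds are uniform (per-cell probability 0.535) or patchy (8000
circles of radius 20 m, 2 items per covered cell) on a 5660 × 5660 m lattice
with annual item renewal at fixed random times; selection emerges from
depletion alone.

## Worked example

```r
library(forevol)

w <- toy_world("toy-patchy-200", seed = 1)     # 200-m patchy fixture
w
#> <resource_world> patchy mode, 200 x 200 lattice
#>   occupied cells: 10264  items placed: 20528  available: 20528
#>   patches: 10

g <- specialist_genotypes()[["Ext-Patchy"]]    # synthetic patch specialist
cfg <- sim_config(year_length = 5000)          # toy 5000-min year
s <- simulate_foraging(w, list(g, g), years = 2, config = cfg, seed = 1,
                       demography = FALSE, log_trajectory = TRUE)
s
#> <forevol_sim> 2 simulated years, 2 alive
#>   births logged: 2  items consumed: 17711

seg <- segment_patch_visits(s$trajectory, w)
nrow(seg$visits); mean(seg$visits$eats); mean(seg$travels$duration)
#> [1] 456
#> [1] 38.7      # items eaten per patch visit
#> [1] 22.3      # minutes of inter-patch travel
```

Two foragers consumed 17,711 items over two 5000-minute years (placement,
depletion and renewal all conserved in `s$counters`), in 456 eat-anchored
patch visits averaging ~39 items each, with ~22 min between patches. The
same trajectory run through `movement_summary()` flags the two-scale
(within- vs between-patch) displacement structure that patchy worlds induce.

Larger experiments use the drivers: `run_evolution()` (zero-state founders,
rescue rule, mutation, lineage archive, then `trace_ancestors()` and
`evolved_genotype()` to read off attractors), `run_ecology()` (fixed
populations of competing genotypes sharing one world) and `run_landscape()`
(two-parameter adaptive-landscape grids reporting intake, inter-patch travel
rate, patch visit time and patch size). Scaled-down presets
(`preset_evolution_mini()`, `preset_ecology_mini()`) make these desk-sized;
the vignette explains exactly what each preset preserves of the reference
configuration and what it gives up. A thin command-line front end is in
`inst/cli/forevol.R`.

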