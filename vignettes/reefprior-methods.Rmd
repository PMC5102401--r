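---
title: "Methods: factorial reserve-selection experiments on synthetic reefscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial reserve-selection experiments on synthetic reefscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reefprior` studies how three properties of prioritisation inputs —
planning-unit size, thematic resolution of reef classes, and spatial
variability of socioeconomic cost — individually and jointly shape marine
reserve designs. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data can
and cannot show.

## The synthetic reefscape

Real exercises of this kind use satellite-derived geomorphic reef maps and
census-derived fisher populations. The generator emulates the *statistical*
structure of such inputs on a raster so that every downstream stage is
testable without any map data.

A reefscape is a `grid_rows x grid_cols` raster of square cells
(`cell_size_km`, default 0.2 km, chosen so a 1 km² planning unit is exactly
5 × 5 cells). Reef is grown as `n_patches` 4-connected patches by seeded
random accretion until `reef_fraction_target` of the cells are reef. Cells
on a patch boundary (those with a non-reef 4-neighbour inside the grid)
receive a partial reef fraction drawn uniformly from [0.25, 0.95],
emulating the clipped, partially-reef edge cells of a mapped reefscape;
interior cells are fully reef. The grid border itself is not treated as a
reef edge, so a fully-reef configuration has fraction 1 everywhere and all
structural quantities (unit areas, nesting counts) are exact — the basis of
several tests.

Classes are assigned top-down by recursive spatial subdivision: the reef
cell set is split into the level-1 classes, each level-1 class into its
level-2 children, and so on. A split orders a region's cells along the
longer axis of its bounding box and cuts at weight-proportional quantiles,
which makes classes blocky and spatially coherent, as geomorphic zones are,
rather than salt-and-pepper. Child weights are drawn from a
Gamma(`rarity_skew`) distribution; the default shape 0.8 produces the
strongly skewed extent distribution typical of reef classifications — many
restricted classes, a few extensive ones. `classes_per_level` defaults to
(2, 11, 25, 43, 120), a profile typical of a national-scale hierarchical
reef classification; the desk-scale experiments use
(2, 4, 8, 12, 20) so that every class retains enough cells on a 150 × 150
grid.

Level 4 is deliberately *not* uniquely hierarchical: real geomorphic
classifications reuse level-4 labels under several level-3 parents. The
generator interprets `classes_per_level[4]` as the number of
(level-3 parent × level-4 child) branches and relabels a `level4_sharing`
fraction of them (default 0.3) to reuse a label from a different parent.
Shared level-4 classes are therefore more widespread than their position in
the hierarchy suggests, which is what lets level-4 scenarios occasionally
find cheaper solutions than level-3 ones.

### Cost surfaces

The uniform cost of a planning unit is its reef area exactly, so "cost"
reduces to "amount of reef". The variable layer is a proxy for opportunity
cost to fishers: `simulate_fishers()` places population centres near reef
with log-normal sizes (median `mean_pop = 500`), and each cell's cost is

    cost(cell) = sum_j pop_j * max(1e-6, 1 - d_j / decay_radius_km)

with `d_j` the Euclidean centre-to-centre distance in km. The linear decay
with a floor is a declared stand-in — the census-weighting details of the
original cost surfaces are not public — and the function is isolated so an
alternative decay can be swapped in. `decay_radius_km` defaults to the grid
diagonal so the surface never truncates to the floor inside the grid. The
per-unit variable cost is the reef-area-weighted sum of cell costs; the
uniform layer is recovered as the special case of a constant
surface, which the tests assert. Whether a mean, sum, or centroid sample is
the "right" aggregation is genuinely open; the area-weighted sum was chosen
because it keeps uniform cost a special case and scales with reef content.

## Tessellation

Two square grids aligned to the raster origin: small units of 1 km²
(5 × 5 cells) and large units of 25 km² (25 × 25 cells), so 25 small units
nest in each large one. Grid dimensions must be divisible by the large-unit
span — ragged tiling is refused rather than silently truncated. Units are
trimmed to reef: a unit's area is the summed reef fraction of its cells
times cell area, zero-reef squares are dropped before the solver ever sees
them, and units whose footprint is not fully reef are flagged as edge
units. Feature tables record the reef area of each class in each unit at
each thematic level; by construction the amounts at every level sum to the
total reef area, and summing level-5 amounts by their level-1 ancestor
reproduces the level-1 table (both asserted in tests).

## The solver

The minimum-set objective is

    score(S) = sum_{i in S} c_i + sum_f spf_f * max(0, T_f - R_f(S)) / T_f

with targets `T_f = 0.30 x` each class's total extent (the 30% objective
used across all scenarios). The penalty is the *normalised* shortfall,
which makes penalty factors scale-free across thematic levels; the
established solver's internal penalty is instead a greedy cost-to-represent
estimate, but since both are calibrated until targets are met the two forms
are operationally equivalent, and the normalised form is simpler to reason
about. The boundary-length modifier is fixed at zero: solution compactness
is not part of this design.

Annealing starts from a random selection (each unit with probability 0.5),
proposes uniformly random single-unit flips, accepts improvements always
and deteriorations with probability `exp(-delta/T)` under geometric cooling
(defaults: 10^5 iterations; `t_initial`/`t_final` scale to 10 and 10^-5
times mean unit cost when not given). The best state visited is tracked,
and strict-descent iterative-improvement sweeps (seeded random order, first
improving flip taken, up to 50 passes) polish it. The solver is implemented
in C++ with its own counter-based RNG, so a run is a pure function of
(problem, schedule, seed), byte-identical across platforms and independent
of R's RNG state. On random 10–18-unit problems with binding targets the
annealed objective matches the exhaustive optimum in ~100% of runs at the
default schedule (asserted as ≥ 95% within 5%, never below the optimum).

Desk-scale experiments use a 10^4-iteration schedule: on problems of a few
hundred units it loses nothing measurable against the default and keeps a
full factorial under half a minute.

### Penalty calibration

`calibrate_spf()` starts every penalty factor at the mean unit cost, runs
`R_cal = 10` replicates, doubles the factor of any class whose minimum
achieved proportion of target is ≤ 0.999, and repeats. The cap is 50
rounds. The cap matters: edge-trimmed units carry sliver amounts of some
classes, so meeting the last 0.1% of a target can require a penalty ~2^15
times the mean unit cost, and because a marginal class fails only in some
rounds its factor is doubled intermittently — convergence is reliable but
can take ~30 rounds at the finest thematic level. Each round costs
milliseconds. `run_scenario()` re-checks the criterion on the full 100
reported replicates and continues doubling if any solution misses, so the
published property — every solution of every scenario achieves minimum
proportion met > 0.999 — holds for the replicate set itself, not just the
calibration sample.

## The factorial experiment

`enumerate_scenarios()` crosses {S, L} × {1..5} × {U, V} in a stable order
(size, level, cost), coded `S1U` … `L5V`. Each scenario is calibrated and
run for `R = 100` replicates — 2000 solutions per experiment. Seeds follow
a two-level plan: scenario seed = hash(experiment seed, code), replicate
seed = scenario seed + replicate index, so any single solution is
reproducible in isolation. The per-solution summaries are reserve extent
(summed reef area of selected units) and cost proportion (solution cost
over the total cost of *all* units under the same layer, making uniform-
and variable-cost scenarios directly comparable).

The desk-scale study condition is a 150 × 150-cell reefscape
(30 × 30 km, ~580 small and ~30 large units after clipping), reef fraction
0.55 in 4 patches, levels (2, 4, 8, 12, 20). The size was chosen once, for
a structural reason: with many fewer large units the large-unit choice set
collapses (a handful of units, nearly all forced into every solution), the
uniform- and variable-cost solutions coincide, and cost-layer contrasts
cannot be expressed at coarse thematic levels. ~30 large units is the
smallest configuration in which all the qualitative contrasts of the full
design are identifiable.

## Statistics

Solutions are treated as community data: rows are solutions (or scenarios),
columns are small planning units, entries are selection indicators (or
selection frequencies 0–100). Large-unit solutions are first broadcast to
their component small units — a large unit with frequency 50 contributes a
value of 50 to each of its ≤ 25 components — so everything is compared at
small-unit resolution.

The matrix is Hellinger-transformed (square root of row-relative
abundance; each row then has unit norm), which makes Euclidean distance
well-behaved on sparse, zero-rich matrices; distances between
presence/absence rows are bounded by √2. Clustering is average-linkage
(UPGMA) on that distance. The constrained ordination regresses the
column-centred matrix on the dummy-coded factors (cost, size, level,
additively; rank deficiency is an error naming the aliased terms) and
eigen-decomposes the fitted covariance; reported quantities include the
constrained eigenvalues, linear-combination site scores, factor-level
centroids, and the share of constrained variance on the first two axes.
The variance partition (constrained + residual = total) closes to 10⁻⁹
relative and the implementation agrees with the vegan package to 10⁻⁹ on
random data — vegan serves as the independent cross-check, never the
implementation.

The permutation test uses a *sequential* (type-I) decomposition in the
fixed order cost, size, level — the order mirrors the conventional
presentation of these designs and reproduces the familiar df column
(1, 1, 4). Per term, `F = (SS_term/df_term)/(SS_resid/df_resid)`;
significance comes from freely permuting the rows of the response
(`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so p can never fall below
`1/(1+n_perm)`). Permuting rows of the response rather than residuals under
a reduced model is a deliberate choice: it is exact under the global null,
simpler to specify, and its size is verified by simulation (empirical
type-I error at α = 0.05 within the binomial 95% interval over 200 null
datasets). Marginal (type-III-like) testing is the main alternative; with
the balanced factorial designs produced here the two coincide for the
first term and differ little for the rest.

## Nestedness and incidental representation

High-priority sets are units selected in at least 50 (or 75) of 100
replicates, with large-unit frequencies broadcast to small units first.
Nestedness of a fine test scenario within a coarse one is the percentage of
the *test* set's units that fall inside the coarse set — the denominator is
always the test set, so the measure is deliberately asymmetric, and an
empty test set is an error rather than a 0. The default comparison grid is
the ten large-unit scenarios against S5U and S5V at both thresholds.

Incidental representation converts a coarse scenario's selection
frequencies to probabilities `P = freq/R` and sums `P ×` contained class
area over units, giving each fine class's expected protected area; this is
reported alongside the percentage of the class total, the rarity
`100 × (1 − class extent / planning extent)`, and a flag for meeting the
30% objective. Full precision is kept throughout; rounding to 3 decimals
happens only at export. Smoothed trend curves over the rarity axis are left
to the plotting layer (`plot_representation()` draws the raw scatter and
the objective line).

## What the synthetic experiments do and do not show

Passing tests on generated reefscapes demonstrate that the machinery is
correct (conservation identities, oracle agreement, calibration
postconditions) and that the package reproduces the qualitative structure
expected of such designs: reserve extent grows with thematic resolution,
large units are less efficient than small ones, variable-cost solutions
are cheaper as a proportion of maximum cost, and fine-resolution priorities
nest poorly in coarse priorities computed with a different cost layer.
They do not certify quantitative values for any real region: the generator
does not model real geomorphology (no atolls, shelves, or depth structure),
its cost surface is a smooth distance decay rather than census-derived
fishing pressure, and a ~30-large-unit region is two orders of magnitude
smaller than a national planning domain. Headline percentages from real
case studies are functions of those real inputs and are not reproduction
targets here; only printed worked examples and design constants are.

## Known limitations

* Single cost aggregation per unit (area-weighted sum); centroid or mean
  summaries would need a one-line extension.
* No boundary-length modifier, zoning, or probabilistic features in the
  solver.
* The class-subdivision splitter guarantees spatial coherence but not
  contiguity of every class when patches are fragmented.
* `brute_force_optimum()` is capped at 20 units by design; it exists as an
  oracle, not a solver.
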