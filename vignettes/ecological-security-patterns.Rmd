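---
title: "Ecological security patterns from ant-colony corridor delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological security patterns from ant-colony corridor delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antscape)
```

## The problem

Karst mountain counties combine high biodiversity value with extreme
ecological fragility: thin soils over carbonate bedrock, rocky
desertification, karst collapse and soil erosion fragment the habitat
patches that supply the region's ecosystem services. An *ecological
security pattern* (ESP) organises such a landscape into **sources** (the
patches supplying the dominant services), **corridors** (the bands through
which organisms and material actually move between sources) and
**restoration points** (the places where corridor continuity breaks and
intervention pays off most).

The classical minimum-cumulative-resistance (MCR) analysis produces
corridor *centrelines* but no width; circuit-theory maps need a width set
by expert judgement. `antscape` implements the alternative this package is
built around: stochastic ants traverse the corridor's search region on the
resistance surface, and the spatial density of the pheromone they deposit
*is* the corridor — its width emerges from the interplay of the resistance
pattern and the walkers instead of being asserted.

## Pipeline stages and their models

### Ecosystem services (per-cell operators)

Five services are scored per cell from user-supplied rasters:

* gas regulation, as net primary productivity `NPP = APAR × ε`;
* habitat maintenance, as InVEST-style habitat quality
  `Q = H (1 − D^z / (D^z + k^z))` with half-saturation `k` (default 0.5)
  and exponent `z` (default 2, configurable since the InVEST family treats
  it as a model default);
* soil conservation, as the RUSLE overlay `A = K R LS (1 − C P)`;
* water supply, as the annual balance `W = P − ET − Q` (mm). Negative
  balances are *kept* and counted — clipping would hide inconsistent
  inputs — with clipping available as an option;
* food supply, by spreading each administrative region's reported grain
  output over its cropland cells in proportion to NDVI, which conserves
  the regional total exactly.

Deriving these inputs (CASA light-use efficiency, InVEST threat distances,
RUSLE factors from climate and terrain) is out of scope; the operators
consume rasters.

### Sources: top quantile, Gi\*, minimum area

Each service's top 20% of cells are its "chief patches". The per-cell
count of services in which a cell is top-20% (`service_richness`, 0–5) is
the merged dominance surface; hotspot analysis is run on this merged
surface (running Gi\* per service before merging is also possible — the
merged-first order is the default reading). The Getis-Ord Gi\* statistic
with binary distance-band weights (self included) turns it into z-scores;
cells with `z ≥ 1.65` (90% confidence, the conventional GIS default — the
method itself prescribes no cut-off) form hotspot patches, 8-connected
components below a minimum area are discarded (`≥` keeps a patch exactly
at the threshold, since it is patches *smaller* than the threshold that
are removed), and each survivor becomes a source whose centre — its
maximal-z cell — is the ant terminal. The shipped county-scale default
minimum area is 6.26 km²; the synthetic pipeline uses 1 km², proportionate
to its 20 km landscape.

The top-quantile mask cuts at the `⌊qn⌋`-th largest value, so with
distinct values the selected fraction is exactly `q`; ties at the cut are
all kept (one tie group may push the fraction above `q`, and a constant
surface selects everything).

### Resistance: entropy-weighted overlay plus sensitivity correction

Six factors (land cover, slope, altitude, vegetation coverage, soil
thickness, bedrock type) are classified to basic resistance coefficients
(5–100) by a shipped classification table and combined as a weighted sum.
The shipped weights are entropy-method weights for the karst study
setting; `entropy_weights()` recomputes them from any cells-by-factors
sample when asked. Interval classes are left-closed and right-open, the
top class closed — the printed class bounds overlap at their endpoints, so
a convention had to be fixed.

The ecological sensitivity index combines rocky desertification, karst
collapse and soil erosion indices (each already rescaled to [0, 1]) as
`ESI = 0.483 RDI + 0.282 KCI + 0.235 SEI`, is min-max standardised, and
corrects the basic surface as a ratio to the regional mean:

```
R_i = R × ESI_std / mean(ESI_std)
```

so cells of exactly average sensitivity keep their basic resistance, and a
uniform rescaling of all indices changes nothing. With a spatially
constant index the standardisation is undefined; the correction then
degrades to a warning-carrying no-op (`R_i = R`), which is the only
behaviour consistent with "average cells keep their resistance". The raw
(unstandardised) ESI numerator is selectable.

One numerical consequence matters downstream: the least-sensitive cell has
`ESI_std = 0`, hence `R_i = 0`, and zero resistance is not traversable by
a cost accumulation that requires positive weights. The pipeline therefore
floors the corrected surface at 1% of the mean basic resistance
(`resistance_floor`, configurable) before any path computation.

### MCR corridors

Accumulated cost uses the standard GIS cost-distance convention: a step
between 8-adjacent cells costs `d (R_a + R_b)/2`, with `d` the cell size
orthogonally and `cell size × √2` diagonally. Any strictly increasing
transform of accumulated cost has the same minimisers, so the monotone
link in the MCR formulation is taken as the identity. Dijkstra
accumulation is delegated to igraph on the lattice graph; backlink tracing
recovers least-cost paths from the accumulated surface.

The corridor *network* is the union of the cost-weighted minimum spanning
tree over source terminals and each terminal's 2 nearest-by-cost
neighbours (`k_neighbors`). The MST guarantees connectivity; the k-nearest
augmentation produces the ring-like topologies seen on roughly symmetric
source layouts. Paths sharing ≥ 90% of their cells are merged as
geometric duplicates.

### The modified ant colony

Each corridor is an independent colony run (the decomposition of the
overall optimisation into per-corridor sub-problems), restricted to a
search region: the 1500 m buffer of the least-cost centreline. Within the
region, an ant at a cell considers its unvisited in-region 8-neighbours
whose direction is within 90° of its previous step (all of them on the
first step); each candidate is chosen with probability

```
p ∝ τ^α × (1/R)^β        α = 1, β = 2
```

— the canonical ant-system rule with inverse resistance as the heuristic;
the package's contribution is the constraint set, not the kernel. If every
admissible neighbour is "higher resistance" (above the region's 0.9
resistance quantile, `jump_threshold`) or the ant is boxed in, the
candidate set becomes every unvisited region cell within a Chebyshev
radius of 3 cells (`jump_radius`): the *jump* rule that frees ants from
local traps. Jumps reset the direction memory.

Per iteration 200 ants walk from the start terminal until they enter the
end cell's 8-neighbourhood or exhaust their step budget (30× the terminal
separation by default). Then the field evaporates globally,
`τ ← (1 − ρ) τ` with `ρ = 0.1`, and every *successful* ant deposits
`Q/L` on each cell it visited, where `L` is its accumulated step cost —
cheap, direct paths deposit more per cell. Failed ants deposit nothing:
the global update is read as applying to completed paths. Fifty iterations
are run; pheromone concentration stops growing well before that. The
initial uniform pheromone `τ₀` defaults to the per-cell deposit of one
ideal straight-line ant (`Q/L_straight`), which puts the prior and the
reinforcement on the same scale regardless of cell size or resistance
units; exact evaporation and deposit constants are not prescribed by the
method, so all of `α, β, ρ, Q, τ₀` are parameters. All randomness flows
through R's RNG: a seed makes the field bit-reproducible.

### From pheromone to corridor scope

Cells whose pheromone strictly exceeds the mean over visited cells become
weighted points ("strictly" means a perfectly flat field yields no points,
with a warning). Kernel density with the GIS-conventional quartic
(biweight) kernel — Gaussian selectable — and a bandwidth of 10 cells
turns them into a density surface whose positive cells are split into 9
equal-count quantile grades (rank-based, ties to the higher grade, so a
constant surface collapses into grade 9 with a warning). Grades 7–9 are
the **main corridor** (polygonised 8-connected); the rest of the search
region is the **potential corridor**. Classing is per corridor by default;
a global classing across merged corridors is an alternative reading.

Restoration points come in three kinds: midpoints of runs (≥ 3 cells) of
centreline not covered by the main corridor (discontinuities); strict
local maxima of resistance along the centreline above the region's 0.9
quantile (resistance mutation points — the operational definition of a
"mutation" is this package's choice, as none is prescribed); and crossings
of two centrelines outside sources. Points within one bandwidth of an
already retained point are dropped.

## The synthetic landscape

No deposited dataset accompanies the method, so the generator *is* the
study condition. `landscape_spec()` defaults describe a 200 × 200 grid of
100 m cells — a 20 km × 20 km mountain county subregion — with:

* terrain around 1280 m elevation (±400 m, Gaussian-filtered white noise
  with a 15-cell autocorrelation length), slope derived from the terrain
  gradient;
* a karst share of 75% of the area (the typical share in the karst
  counties this setting emulates), carrying carbonate bedrock classes and
  elevated desertification/collapse/erosion indices;
* a patchy land-cover mosaic (forest, grassland, cultivated valley floors,
  garden pockets, waters, construction);
* three source patches placed greedily on low-resistance terrain with a
  minimum separation of one third of the grid side, so corridors are long
  relative to their width;
* one planted channel between sources 1 and 2: a 9-cell (900 m) wide
  valley floor whose factor values sit in the minimal resistance classes.
  Background altitude is floored at 850 m so the channel (700 m) undercuts
  every natural cell and is *strictly* the cheapest route — the planted
  truth against which corridor recovery is measured. Corridor widths of
  several hundred metres to a kilometre match the per-corridor areas the
  method reports at county scale.

What the generator does **not** emulate: real geomorphology (drainage,
aspect-dependent vegetation), anthropogenic linear barriers (roads),
seasonal dynamics, and classification error in the input rasters. Tests
passing on these landscapes show the machinery is correct and the
behavioural regimes hold; they do not show that any particular county's
corridors are right.

Scenario builders (`make_fig7_scenario`) realise the five local regimes a
corridor can encounter — uniformly high or low corridor resistance, a
low→high traverse with a single gap, a high block in a low field, and a
fragmented mosaic with low seams — as exact constant-valued constructions,
so behavioural assertions (gap-seeking, concentration ordering, seam
convergence) are not confounded by noise.

## Numerical choices and degenerate inputs

* Step costs and buffer/bandwidth arguments are metres of the projected
  CRS throughout; rasters without a CRS are refused at read time.
* Nodata is `NA` internally; any nodata cell in any stacked factor is
  nodata in every derived surface.
* Backlink tracing accepts a relaxation match within `1e-7` relative
  tolerance; scale equivariance of Dijkstra makes this safe.
* Zero-resistance cells are an error for cost accumulation; the pipeline's
  floor (above) prevents the sensitivity correction from creating them.
* Quantile-grade collapse (fewer distinct positive densities than grades),
  constant Gi\* fields, empty hotspot sets, unreachable sources and
  trapped ants all produce explicit warnings or errors rather than silent
  degradation.
* The `6.26 km²` minimum source area ships as the county-scale default;
  nothing in the method derives it, so it is a plain threshold.

## Problem sizes

The shipped tests and the acceptance script run the default 200 × 200
landscape (40 000 cells) end to end, colonies of 200 ants × 50 iterations
on scenario grids of 80 × 120 to 100 × 100, oracle comparisons on 4 × 4
and 5 × 5 grids, and a 100 × 100 null-calibration field — sizes at which
every behavioural check is comfortably reproducible on a single CPU.

## Worked example

```{r example, eval = FALSE}
spec <- landscape_spec(seed = 1)
result <- run_esp_pipeline(spec, out_dir = "esp_artifacts")
glance(result)   # sources, resistance means, corridor areas, points
tidy(result)     # one row per corridor
autoplot(result) # corrected resistance + sources + centrelines + points
```

## Known limitations

* The transition rule, evaporation and deposit constants are canonical
  choices, not fitted ones; corridor widths therefore inherit a mild
  dependence on `β`, `ρ` and the KDE bandwidth (all exposed).
* Human-disturbance corrections (night-light, impervious surface) are not
  implemented.
* Reprojection is not bundled: all layers must already share a projected
  CRS, and `align_stack` only resamples within it.
* Corridor pairing reproduces ring-like networks via MST ∪ k-nearest; the
  method itself does not prescribe a pairing rule, so the topology is
  configurable rather than canonical.
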