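---
title: "Methods: green-space-aware growth scenarios and their ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: green-space-aware growth scenarios and their ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greengrowth)
```

This vignette documents the models implemented by `greengrowth`, the
assumptions behind them, the parameters that matter, and the places
where the design was genuinely open and a choice had to be made.

## The raster carrier

Every layer is a `grid()`: a numeric matrix plus a cell size in metres,
a nodata sentinel and a kind tag (categorical / continuous / binary).
Grids are abstract — row-major, origin top-left, 1-based indices — and
all modules inherit this single convention. Georeferencing metadata read
from a file is carried opaquely and never used in computation, because
every computation here is grid-local. Rasters are read and written as
ESRI ASCII grids, a plain-text dialect that keeps every fixture and
artifact human-readable and diff-able; CSV carries all tabular output.

## Synthetic landscapes

The generator (`generate_stack()`) emulates the statistical structure
the analysis assumes rather than any particular geography:

- **Urban growth**: binary urban masks at four epochs with fractions
  0.0425 → 0.051 → 0.065 → 0.0794 of the landscape. The two end
  fractions are the observed regime being emulated; the two
  intermediate values are interpolations, since per-epoch values in
  between are not available. New urban cells are drawn 80% by edge
  accretion around existing urban and 20% scattered, which exercises
  all four growth rules during calibration; masks are monotone across
  epochs by construction.
- **Roads**: random spanning trees over waypoints, rasterized one cell
  wide, densifying over the first three epochs then static. A spanning
  tree guarantees the connectivity that road-influenced growth needs.
- **Slope**: uniform gentle noise (0–8%) plus one contiguous steep
  region (above the critical slope, default 21%) covering 5% of the
  landscape, so the slope gate has something to reject.
- **Land cover**: six classes (agriculture, forest/vegetation, wetland,
  urban, bare, water). Green space forms 12 patches with areas spread
  over an order of magnitude, elliptical with random elongation, joined
  in a random chain by one-cell-wide connectors — guaranteeing cores,
  edges and bridge structures at the default edge width.
- **Population**: allocated to the four cardinal zones proportional to
  zone urban area with a configurable skew (default north 1 / west 1.2
  / south 1.5 / east 2), so green-per-capita ratios differ across zones
  and the equity weighting is non-trivial by default.

What the generator does **not** emulate: spectral realism, realistic
road hierarchies, autocorrelated slope fields, or any particular city's
geometry. Passing tests therefore demonstrate correctness of the
algorithms and the direction of mechanistic effects (e.g. that
protecting cores in the exclusion layer reduces core loss), not
calibrated magnitudes for a real region.

All randomness flows from a single seed through named substreams
(`child_seed()`), so every stage is reproducible in isolation and
identical seeds give bit-identical stacks.

## Morphological segmentation

`mspa_segment()` classifies foreground cells of a binary mask:

- **core**: Euclidean distance to background (off-map counts as
  background) strictly greater than the edge width (default 1 cell,
  i.e. 90 m);
- **islet**: foreground component containing no core;
- **edge / perforation**: non-core cells within the edge-width-fold
  8-neighbour dilation of core — perforation where they rim a hole
  (a background component not reaching the map border) and are not
  within reach of the outer background, edge otherwise;
- **bridge / loop / branch**: the remaining connector cells, grouped
  into components; a component reaching two distinct core components is
  a bridge, one core component at two or more separate attachment
  regions a loop, and one attachment a branch.

The connector subdivision is deliberately skeleton-free: components are
attributed to the core components their neighbourhood reaches (through
the edge ring, via nearest-core attribution) instead of computing
geodesic skeletons. At 90 m resolution connectors are a few cells wide
and this component-level analysis reproduces the canonical classes; its
known simplification is that a spur hanging off a bridge component is
absorbed into the bridge. The edge width and connectivity (default 8)
are parameters because reference implementations differ and no single
setting is canonical.

One geometric consequence of the strict Euclidean core rule is worth
knowing: a one-cell hole inside a large patch converts only its four
orthogonal neighbours to perforation — the diagonal neighbours are
√2 > 1 cells from any background and remain core. Similarly, a thin
connector attached to a patch edge shields the attachment cells and can
deepen the local core. The tests encode these consequences explicitly.

## Connectivity importance

Core patches (by default the union of core, edge and perforation — the
classes retained for protection) are labeled, and each patch gets a
representative point (the cell nearest its centroid). The patch graph
uses edge-to-edge distances: the minimum distance between cell centres
of two patches minus one cell size, floored at zero, so adjacent
patches are at distance 0. Direct dispersal probability is negative
exponential, `p = exp(-ln 2 · d / d_half)`, with a half-distance
default of 500 m — the standard kernel convention; the half-distance is
exposed because it is a species- and planning-question-dependent
choice, not a constant of nature.

`PC` sums `aᵢaⱼp*ᵢⱼ/A_L²` over all ordered pairs including `i = j`
(with `p*ᵢᵢ = 1`), which is what makes a single patch covering the
whole landscape reach the `PC = 1` upper bound. Maximum-product path
probabilities are shortest paths under weights `-log p`; the
implementation builds the complete graph with explicit weights so that
certain steps (`p = 1`, weight 0) remain edges. Removal importance
re-solves paths on the reduced graph; `dPC` is reported in percent.
Patch importance is painted onto the patch raster rescaled linearly to
0–255 over the observed range; when all patches tie, everything is
painted 255 — equal importance should maximally resist urbanization
rather than vanish in a degenerate rescale.

## Corridor current

The conductance surface assigns a base value per land-cover class
(forest highest, then wetland, water, agriculture, road, urban, bare)
and overrides connector cells with values above forest, increasing
islet < branch < loop < bridge. Only this ordering is fixed by the
method; the default magnitudes (forest 100 … bridge 250) are documented
configuration.

Current maps solve the lattice Laplacian on the 4-neighbour grid with
edge conductance the mean of the two cells, one unit of current
injected per focal pair. Voltages come from a sparse Cholesky
factorization of the Laplacian restricted to the connected component of
the pair with one node grounded; the factorization is reused across all
pairs in a component. Per-cell current is half the sum of absolute
incident branch currents, with the two terminals reported as exactly 1.
Pairs beyond a budget (default 200) are subsampled with a seeded draw.
Conservation at interior nodes holds to 1e−8 of the injected current
and currents are invariant to rescaling all conductances, both asserted
by tests against dense direct solves.

## Exclusion layers

Resistance to urbanization lives on a 0–100 scale; 100 is an absolute
veto and intermediate values reject urbanization attempts with
probability `resistance/100`. The base layer combines binary constraint
masks by cellwise maximum. The green-informed layer maps importance and
current from 0–255 to 0–100 (linear, with optional floor/ceiling
clamps) and combines them with the base, again by maximum. Maximum
rather than weighted sum is the conservative reading of "overlay": it
preserves hard constraints exactly and guarantees the dominance
property (informed ≥ base everywhere) that makes the protection
mechanism auditable; a capped sum is available as configuration.

## The growth automaton

One annual step applies four rules in order — spontaneous seeding, new
spreading centres, edge growth, road-influenced growth — each attempt
passing an exclusion gate and a slope gate (reject outright at or above
the critical slope, else accept with probability
`((critical − slope)/critical)^(slope_resistance/25)`). The family of
models this follows specifies the coefficients but leaves several
internals open; every such constant here is explicit and configurable:

- spontaneous attempts per step: `round(D_M · diffusion · diagonal)`,
  with `D_M` the diffusion multiplier;
- each rule-1 recruit becomes a spreading centre with probability
  `breed/100`, urbanizing up to 2 neighbours;
- edge growth urbanizes non-urban cells with ≥ 3 urban 8-neighbours,
  with probability `spread/100`;
- road trips number `round(breed/100 · n_new)`; the road search radius
  is `road_gravity/100 · (rows+cols)/16` and the road walk runs for
  `max(1, round(0.05 · attempts))` steps.

Self-modification (boom/bust adaptation of coefficients during a run)
is deliberately excluded: coefficients stay constant, which keeps every
run a pure function of its seed and makes calibration deterministic per
seed. Each rule in each year of each Monte-Carlo run draws from its own
seed substream, which yields two useful properties asserted in tests:
identical seeds reproduce runs bit-for-bit, and extending the horizon
replays the shared prefix, making likelihood monotone in years
simulated.

The diffusion-multiplier sweep simulates the observed period with
diffusion 100 and all other coefficients at 1, for each value of the
arithmetic sequence (default 0.001 by 0.003 to 0.124 — 42 runs), and
scores the cluster fractional difference against the observed final
urban map's 8-connected cluster count; the best multiplier minimizes
its magnitude.

Calibration is an exhaustive grid search in three stages (default steps
25/10/5 with 6/8/10 Monte-Carlo runs, the usual coarse/fine/final
practice), scoring eight fit metrics against the observed epochs:
`compare` (ratio of final urban counts), r² across control years of
urban count, edge count, cluster count and the urban centroid
coordinates, r² of mean slope of urbanized cells, and a class-match
score on cells that changed in either map. Constant series score 1 when
identical and 0 otherwise — the defined limit of r² for degenerate
histories. The product of the eight ranks candidates; after each stage
the top three survive and the next stage spans their hull at the finer
step. Validation restricts to cells non-urban at the seed year and
reports ROC area (via `pROC`), precision–recall area (step integration
with tied scores grouped) and the figure of merit
`hits/(hits + misses + false alarms)` at a likelihood threshold of 50.

## Scenarios

Demand is `persons × 450 m²/capita`, the observed stable per-capita
built-plus-infrastructure footprint: 530,000 additional residents imply
23,850 ha, and the deliberately compact variant takes 10% of that
(2,385 ha). The compact coefficient transform halves diffusion, breed
and road gravity and multiplies slope resistance by 1.5 (capped at
100), leaving spread unchanged. Halving odd values is ambiguous in the
published coefficient table (one row floors, another rounds up);
round-half-up is the default with floor available, and only the
unambiguous anchors are asserted in tests.

Social-equity weighting divides the landscape into four cardinal
quadrants about the grid centre (diagonals tie-broken clockwise from
north: NE→north, SE→east, SW→south, NW→west). Per zone, two
provisioning ratios are computed — green area within 1 km of urban per
urban area, and green area per resident — min-max normalized and
averaged; zones ranked best to worst receive weights 0.4/0.3/0.2/0.1,
steering growth toward the zones that can best absorb it. A zone with
no urban area ranks last; full ties resolve in the fixed order north,
west, south, east. Suitability is likelihood times the zone weight
normalized by the maximum weight, preserving the 0–100 scale.

Polygon selection thresholds suitability at 50, labels 8-connected
components, drops those under 30 ha, and ranks the rest by mean
suitability (ties by larger area, then label). `top_n` keeps the first
n; `area_cap` accumulates ranked polygons under the cap and tops up the
remainder with the highest-suitability cells of the next polygon — the
pixel-level mechanism used for the compact demand level. Mean
suitability is the ranking key because it is stable under polygon size.

The eight scenarios are the full factorial of exclusion variant ×
coefficient variant × weighting variant.

## Impact metrics and ranking

Per scenario: the percentage of high-current and high-importance cells
(> 150 on the 0–255 scale) captured by the selection, the percentage of
core area covered, and mean perimeter-area ratio (PARA_MN, metres per
hectare — a 90 m cell scores 444.4) and mean Euclidean nearest-
neighbour distance (ENN_MN) computed twice: over core patches within
1 km of the selection, and over the selected polygons themselves.
ENN uses the cell-centre convention (two cells five columns apart at
90 m are 450 m apart); conventions that measure shifted cell edges
differ by one cell size, and the choice is configurable in principle
but fixed here for comparability. Empty selections report zero
percentages and flag the patch metrics as absent, and criteria that
carry no information (all-zero or absent) are excluded from the
ranking.

TOPSIS uses vector normalization `x/√Σx²` — the canonical form —
followed by weighting, per-criterion ideal and anti-ideal points,
Euclidean distances and the closeness coefficient `d⁻/(d⁺+d⁻)`; min-max
normalization is available for sensitivity checks. The robustness
analysis re-ranks under perturbed weights: each iteration (20,000 by
default) moves 5% of one randomly chosen criterion's weight to another,
rejecting moves that would carry any weight beyond ±50% of its initial
value. Iterations perturb the initial weights independently — keeping
them exchangeable — rather than accumulating a random walk; the walk
variant is available behind a flag because the sequential reading of
"shift until the threshold is reached" is also defensible. Weight moves
conserve the unit sum by construction.

## Problem sizes

The package's own test and demonstration scale is the 200×200 shrink of
the reference 1000×1000 grid (the `shrink()` helper divides dimensions
while preserving all fractional targets), with demand levels scaled by
the area ratio so a shrunk run asks for the same fraction of its
landscape. The bundled acceptance script runs the full pipeline at
200×200 with a calibration search of three values per coefficient
capped at 300 combinations per stage, two Monte-Carlo runs in the sweep
and calibration and four in prediction; unit tests use 60–100-cell
grids. These sizes were chosen so the whole suite exercises every stage
end-to-end in minutes; the algorithms themselves are resolution-
agnostic, and a full-scale run only changes wall time.

## Known limitations

- The morphological connector subdivision is component-based, not
  geodesic; mixed connector components take the dominant role's class.
- Circuit solves use pairwise injection with a pair budget rather than
  all simultaneous pairs; corridor maps at very small budgets can
  under-sample peripheral node pairs.
- Calibration metrics with two control years make the r² family
  degenerate (any two distinct points fit perfectly); three or more
  observed epochs are needed for those metrics to discriminate.
- The automaton's rule internals (walk length, search radius, slope
  exponent) follow documented defaults, not any particular legacy
  binary; results are comparable in mechanism, not bit-identical to
  other implementations.
- Synthetic landscapes validate mechanisms and directions of effects,
  not site-specific magnitudes.
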