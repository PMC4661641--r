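---
title: "Landscape ecological risk assessment and Markov-CA simulation with landriskr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape ecological risk assessment and Markov-CA simulation with landriskr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landriskr)
```

# The problem

Rapid land-use and land-cover change — urban expansion, conversion of
farmland to aquaculture, reclamation of open land — reshapes landscape
structure and with it the ecological functioning of a region. `landriskr`
implements a complete, desk-testable pipeline for quantifying that pressure
on categorical land-cover rasters:

1. **Change accounting** — cross-tabulation of two dated rasters into a
   transition matrix (hectares moving from every class to every class), the
   dynamic degree index (converted area as a share of total area), net
   gains/losses, and conversion summaries.
2. **Landscape pattern metrics** — splitting index (SPLIT), patch density
   (PD), contagion (CONTAG), Shannon's diversity (SHDI) and the
   perimeter–area fractal dimension (PAFRAC), at class and landscape level,
   for the whole landscape or per analysis zone (e.g. towns).
3. **Ecological risk** — a disturbance-by-vulnerability index per zone and
   date, classified into five categories.
4. **Suitability learning** — one least-squares support vector machine
   (LSSVM) per conversion type maps spatial driver variables to conversion
   suitability.
5. **Markov-CA simulation** — a cellular automaton allocates
   Markov-determined conversion quantities to cells by suitability and
   neighbourhood contiguity.
6. **Scenario analysis** — farmland-protection, ecological-conservation and
   urban-development policies expressed as masks, suitability multipliers
   and class-area floors, projected forward with risk trajectories.

A synthetic-data module generates seeded landscapes, drivers, zones and a
ground-truth transition process so every stage is testable without external
GIS data.

# The risk model

For one analysis unit (a zone or the whole landscape) with classes
$i = 1..n$:

**Disturbance** per class combines normalized fragmentation and diversity
metrics,

$$D_i = w_1\,\mathrm{SPLIT}'_i + w_2\,\mathrm{PD}'_i + w_3\,\mathrm{SHDI}',$$

with default weights $(0.3, 0.5, 0.2)$. SHDI carries no class subscript: it
is the unit-level landscape value shared by all classes of the unit, exactly
as the equation's subscripts imply. Metrics are min–max normalized **across
every (unit, class, date) observation passed in one call**, so risk values
are comparable across dates; per-call (rather than per-date) normalization
is the package default because temporal comparison is the point of the
analysis. A metric that is constant across the cohort carries no relative
signal and maps to 0, with a warning.

**Vulnerability** is an ordinal grade per class — built-up 1 (most stable,
intensively managed), forest 2, farmland 3, aquaculture 4, water 5, other
open land 6 (most fragile) — normalized by default as $V_i =
g_i / \sum_k g_k$ (grades 1..6 give $1/21 .. 6/21$). This keeps every class
strictly positive so the risk index stays sensitive to built-up expansion;
min–max normalization (which zeroes the lowest grade) is available via
`vulnerability_index(..., "minmax")`.

**Risk** is the area-weighted geometric coupling

$$R = \sum_i \alpha_i \sqrt{D_i V_i},$$

with $\alpha_i$ the class area share in the unit. Since $\alpha$ sums to one
and $D, V \in [0,1]$, $R \in [0,1]$; it is classified low (0–0.2],
relatively low (0.2–0.4], medium (0.4–0.6], relatively high (0.6–0.8], high
(0.8–1]. Bins are right-closed, with 0 in "low".

## Metric conventions

The cited landscape-metrics formulas leave several conventions open; the
package fixes them as the standard tools do and validates them by
brute-force oracle (the original study rasters are not available, so the
published spatially dependent metric values cannot be used as checks):

* **Patches** are 8-connected by default (4-connectivity available).
* **Perimeter** counts every cell edge adjoining another class, nodata, or
  the grid boundary.
* **CONTAG** uses 4-neighbour adjacencies, double-counted (each internal
  edge from both sides), like-adjacencies included, nodata and the outside
  excluded. One quirk worth knowing: a strict two-class checkerboard is
  *not* the metric's minimum — its adjacency distribution is perfectly
  concentrated on unlike pairs and scores 50, whereas random interspersion
  approaches 0. The tests assert the monotone interspersion response with
  random scrambling for this reason.
* **PAFRAC** is $2/b$ with $b$ the OLS slope of $\ln(\text{area})$ on
  $\ln(\text{perimeter})$ across patches. The regression direction matters
  and is fixed; with fewer than two distinct patches the value is undefined
  and flagged rather than invented.
* **SPLIT** at class level uses the full landscape area $A$ in $A^2/\sum
  a_j^2$ (the standard definition), so it is scale-free.
* **Zonal metrics** delineate patches inside the zone mask only; patches
  truncate at zone borders, because zones are evaluated as independent
  landscapes.

# Suitability learning

Each conversion type $i \to j$ (all 36 ordered pairs, persistence included)
gets a binary LSSVM trained on a stratified sample: up to 500 cells observed
making the conversion (+1) and an equal number of same-source cells that did
not (−1), drawn without replacement under a seed. Training solves one linear
KKT system

$$\begin{bmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & K + \gamma^{-1} I
\end{bmatrix} \begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ y \end{bmatrix},
\qquad K_{mn} = \exp\!\left(-\frac{\lVert x_m - x_n \rVert^2}{2\sigma^2}\right)$$

on standardized features (standardization statistics travel with the model,
so predictions are invariant to feature scaling). Every fit records its KKT
residual; the tests require it below $10^{-8}$.

Defaults are $\gamma = 1$ and $\sigma = \sqrt{d}$ for $d$ features. The
$\sqrt{d}$ width is the standard dimension-aware heuristic: squared
distances between standardized $d$-dimensional points concentrate around
$2d$, so a fixed $\sigma = 1$ makes the kernel effectively local for the
eight drivers used here and the learned surface degenerates toward the
sample points. With the defaults, ranking source cells by suitability
recovers the generator's true conversion-probability ordering with Spearman
$\rho \approx 0.93$ on the default synthetic world (the tests require
$> 0.8$).

Decision values are mapped to $[0,1]$ suitability by min–max over the
source-class mask; a constant decision maps to 0.5, untrained transitions
fall back to a constant-zero surface, and non-source cells are 0. A
logistic squash is available as an alternative mapping.

# Markov-CA allocation

The transition matrix fixes *how much* land converts; the CA decides
*where*. Off-diagonal areas become cell-count demands apportioned equally
over the iterations (default 18, i.e. half-year steps across a nine-year
calibration period), remainders to the earliest iterations
(largest-remainder rule), so totals are conserved exactly. Per iteration
and ordered pair, candidate cells (current source class, not under an
immutable mask) score

$$\text{score} = \text{suitability}_{i \to j} \times
(\varepsilon + \text{neighfrac}_j),$$

where neighfrac is the fraction of valid neighbours in the (default 3×3)
window already in the target class and $\varepsilon = 0.1$ is a floor that
keeps isolated but highly suitable cells convertible. Each pair nominates
its top-demand candidates; a cell claimed by several pairs goes to the
highest-scoring claim (fixed pair order on exact ties, seeded uniform jitter
within a pair), losers' unmet demand rolls to the next iteration, and any
residue after the last iteration is reported, not force-allocated. The
published description of the original CA tool's internals is incomplete
(neighbourhood size and iteration count only), so this allocator is a
documented, fully testable scheme with the same interface: demands,
suitability, contiguity.

Validation operations compare a simulated map against an observed one by
overall accuracy (fraction matching) and Cohen's Kappa from the cell-level
confusion matrix. On the default synthetic world, simulating the observed
period and comparing against the realized end state gives roughly 70%
accuracy and Kappa ≈ 0.6.

# Scenarios

Four standard policies are encoded as `scenario_spec` transformations:

* **S1** status quo: no constraints.
* **S2** farmland protection: planned permanent farmland is immutable, and
  total farmland may not fall below its baseline area.
* **S3** ecological conservation: suitability of transitions into forest and
  water × 1.2 in the first-grade conservation zone and × 1.1 in the
  second-grade zone (clipped at 1), with forest and water floors at
  baseline. The floors are applied globally (not only inside the zones), the
  more protective reading of the policy.
* **S4** urban development: suitability of transitions into built-up × 1.2
  everywhere.

Floors are enforced *ex ante* by demand capping: when a floored class can
afford to lose fewer cells than its total out-demand, out-demands are scaled
pro-rata with largest-remainder rounding, so the floor holds at **every**
iteration and allocation stays deterministic (no post-hoc reversal).

Projections beyond the calibration period reuse the calibrated transition
matrix rescaled to the horizon — i.e. the calibrated per-iteration
conversion rate is held fixed, consistent with the status-quo assumption
that driver contributions do not change. This is the package's own choice;
how the original study extended demands past its calibration window is not
recorded in the publication. Snapshots default to iterations 4, 14, 24 and
34 (years 2, 7, 12, 17 at half-year steps) with zonal risk and per-zone
change ratios relative to the baseline.

# The synthetic world

`synthetic_spec()` defines the default desk-scale study system: a 150 × 150
grid of 100 m cells (2250 ha), six classes at the mixed agricultural
lake-plain proportions of the packaged class-area table (farmland 44%,
water 20%, aquaculture 12%, built-up 12%, forest and other ~6% each), an
8-cell spatial autocorrelation length, nine Voronoi zones, and the eight
driver surfaces (distances to a highway, railway, road network, town
centers, urban centers and water, plus a fractal elevation field and its
Horn slope).

The ground-truth transition process is a per-cell softmax: the utility of
ending in class $j$ is a persistence bonus (3.0 log-odds, giving ≈ 18%
change over the period) plus a linear term in the standardized drivers
(e.g. built-up gains favour cells near roads and urban centers, aquaculture
favours cells near water on flat ground) plus a mild neighbourhood term
(0.5 × the target-class neighbour fraction). The generator returns the
exact per-cell probabilities alongside the realization, so stochastic tests
compare against closed-form expectations instead of re-simulation.

What the synthetic world does *not* emulate: real geography (lake shapes,
road topology), classification error in the input maps, and temporal
autocorrelation across more than one transition interval. Passing tests
demonstrate the pipeline's internal correctness and statistical behaviour
under known conditions — not the empirical accuracy of any particular
regional application.

# Numerical choices and edge cases

* Nodata cells are excluded from every count, metric, adjacency and demand;
  they never convert, and a cell that is nodata at either date is excluded
  from both marginals of a cross-tabulation so the grand total is constant.
* Classes absent from a unit contribute 0 to its risk; absent-class metric
  values are `NA` with a `defined` flag, never silently 0.
* A class absent at the first date gets a unit self-transition row in the
  probability matrix (row-stochasticity preserved).
* Distance surfaces use an exact two-pass squared-distance transform (no
  chamfer approximation); slope uses Horn's 3×3 method with edge
  replication.
* Demand feasibility is checked when the schedule is built (a pair whose
  rounded cell demand exceeds its source cells is an error naming the
  pair); shortfalls during allocation are rolled forward and reported.
* All stochastic steps (sampling, tie-break jitter, generators) take
  explicit seeds and restore the caller's RNG state.
* Problem sizes in the test-suite: oracle equivalence runs on 200 random
  grids up to 30 × 30; simulation checks use 50 × 50 and 60 × 60 worlds;
  the end-to-end run uses the default 150 × 150 world with 500 samples per
  conversion type and 18 iterations, chosen to exercise the full pipeline
  at desk scale.

# Known limitations

* The CA allocator is a stand-in for the original study's proprietary
  multi-objective module; it reproduces the documented interface
  (Markov-quantified demands, 3×3 contiguity, suitability ranking) but not
  its undocumented internals.
* The published landscape-level CONTAG/SPLIT/PD/PAFRAC values and
  town-level risk means depend on the original rasters, which were never
  deposited; only composition-driven quantities (SHDI, all change
  accounting) can be reproduced exactly from the printed tables, and the
  spatial machinery is validated by oracle instead.
* Rasters are treated as aligned integer lattices; reprojection and vector
  GIS layers are out of scope (alignment is checked, never repaired).
* TIFF output is restricted to integer grids in [−32768, 32767] (16-bit
  samples with a fixed offset, georeference in an ESRI world file); the
  ESRI ASCII grid is the canonical format and supports continuous surfaces
  too.

# A worked example

```{r example, eval = FALSE}
library(landriskr)

# published tables: change accounting
tabs <- ezhou_tables()
dynamic_degree(tabs$table2)              # 15.60 (% of landscape converted)
net_change(tabs$table2)[["farmland"]]    # -16253.91 ha
shdi(tabs$table1["1991", ])              # 1.3304

# synthetic end-to-end run
w <- synth_world(synthetic_spec(seed = 7))
samp <- stratified_sample(w$grid_t1, w$grid_t2, w$drivers, 500, seed = 11)
models <- train_transition_models(samp)
pairs <- subset(expand.grid(i = 1:6, j = 1:6), i != j)
suit <- suitability_stack(models, w$drivers, w$grid_t1,
                          pairs = split(as.matrix(pairs), seq_len(nrow(pairs))))
tm <- cross_tabulate(w$grid_t1, w$grid_t2)
sim <- simulate_lulcc(w$grid_t1, tm, suit, sim_config(iterations = 18, seed = 5))
overall_accuracy(sim$final, w$grid_t2)
kappa_coefficient(sim$final, w$grid_t2)
zonal_risk(list(t1 = w$grid_t1, t2 = sim$final), w$zones)
```
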