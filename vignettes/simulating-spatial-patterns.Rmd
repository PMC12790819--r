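---
title: "Simulating spatial transcriptomics data with stplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spatial transcriptomics data with stplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stplate)
```

## The simulation model

`stplate` builds spatial transcriptomics (ST) data from the inside out. A
*cell plate* is a rectangular (or box-shaped) region on which N cell
coordinates are drawn, i.i.d. uniform per axis by default, or on a regular
lattice. A *neighbourhood graph* over the cells — k-nearest-neighbour with
union symmetrisation, fixed-radius (strict `d < r`), Delaunay (2-D), or
shared-nearest-neighbour — defines which cells are "adjacent". The spatial
pattern of cell types is then characterised by two objects:

* the proportions $\pi = (\pi_1, \dots, \pi_K)$, and
* a row-stochastic transition matrix $P$ whose entry $P_{ij}$ is the target
  probability that a neighbour of a type-$i$ cell has type $j$.

Label assignment minimises
$\lVert P - C^{-1} X^\top A X \rVert_F$ over one-hot matrices $X$ subject to
one label per cell and exact integer per-type counts (largest-remainder
apportionment of $\pi N$, ties to the lowest type index). $X^\top A X$ counts
ordered adjacent endpoint pairs by type; $C$ row-normalises it; rows with no
contacts normalise to zero rows and are flagged rather than treated as
errors.

Because raw contact counts are symmetric, any *achievable* transition matrix
satisfies $C_i P_{ij} = C_j P_{ji}$ (with $C_i$ the total contacts of type
$i$). Targets violating this — e.g. a symmetric high-cross matrix combined
with strongly unequal proportions — cannot be met by any labelling; the
optimiser then returns the closest achievable pattern, which is exactly how
the mixed/compartmentalized/layered two-type phenomenology arises.

## The annealing strategies

The program is combinatorial, so three simulated-annealing heuristics are
provided, all built on the same move: exchange the labels of two cells (or
zones) of different types, which preserves counts by construction.

* **GSA** anneals directly at the cell level. It is the reference strategy
  for small plates and is the one validated against exhaustive enumeration
  in the test suite.
* **LSA** splits the plate into a regular grid (default: about 1000 cells
  per grid cell) and anneals each grid independently against the global
  target, with stream seeds `seed + grid index`; the pieces are concatenated
  and recalibrated to the exact global counts.
* **BSA** partitions the plate into hierarchically shrinking *cell zones*.
  The number of epochs is $M = \max(1, \lfloor \tfrac12 \log_2(N/1000)
  \rfloor + 1)$ — the clamp covers plates below 1000 cells, where the
  formula would be non-positive. The base zone grid has
  $\lceil N^{1/(2d)} \rceil$ zones per axis (about $\sqrt N$ zones in
  total); epoch-$m$ windows measure $l_0 2^{M-m} \times w_0 2^{M-m}$ and
  shrink to the base zone at the last epoch, while the number of swaps per
  annealing iteration grows as $2^m$. Epoch 1 draws one label per zone from
  a multinomial with parameter $\pi$; later epochs inherit each child zone's
  label from its parent. Zone-level annealing runs on the zone contact
  graph: two zones are adjacent iff any inter-zone cell edge exists, contact
  weights count those edges, and intra-zone edges sit on the diagonal, so
  the zone-level energy is an exact coarse-graining of the cell-level
  energy. After the last epoch zone labels are expanded to cells,
  recalibrated to exact counts by randomly switching surplus cells to
  deficient types, and polished by a cell-level annealing pass on the full
  plate (the package runs this refinement globally rather than per zone, so
  boundary cells can cross zone lines).

### Annealing controls

The acceptance rule is Metropolis. The initial temperature defaults to the
mean $|\Delta E|$ of 100 random candidate moves — a standard self-calibration
that adapts to the energy scale of the instance; cooling is geometric with
$\alpha = 0.95$; annealing stops below $10^{-4} T_0$ or after 200
consecutive rejected proposals. The number of proposals per temperature
level defaults to $\max(200, N)$. All of these are exposed through
[`epoch_schedule()`]. The returned labelling is always the best-so-far
incumbent, never the final wandering state, so the result can never be worse
than the initial labelling. The swap loop maintains the contact count matrix
incrementally (a relabelling moves one weighted neighbour-type tally between
two rows/columns); the suite asserts that incremental energies equal full
recomputation to $10^{-10}$.

All randomness flows from a single integer seed through R's RNG, so every
output is bitwise reproducible.

## Predefined patterns

* **attractive** — diagonal `dominant_prob` (default 0.8), off-diagonal
  uniform: each type clusters with itself.
* **repulsive** — the types are partitioned into groups; within-group mass
  `dominant_prob` is split uniformly over the group (including self), the
  residual uniformly over the other groups. This reading of "group partner"
  keeps rows stochastic for any group sizes.
* **layered / gyrus** — cell types occupy strata along one axis; each cell
  draws its layer's dominant type with probability `dominant_prob` (default
  0.8) and any other type uniformly otherwise. The gyrus variant displaces
  the layer boundaries by a sinusoid of the orthogonal coordinate
  (amplitude in coordinate units, configurable frequency) — the simplest
  periodic fold consistent with a "convoluted layered" geometry.
* **TIME presets** (`time_cold`, `time_mixed`, `time_compartmentalized`) —
  two-type tumour/immune microenvironment configurations. The numeric
  matrices are editable package defaults chosen to satisfy the qualitative
  structure of the three phenotypes (cold: few immune cells, self-adherent
  tumour; mixed: high cross-type transitions; compartmentalized: high
  self-transition for both blocks); they are not estimates from any dataset.

`estimate_pattern()` inverts the construction: given any labelled graph it
returns the empirical proportions and the row-normalised contact matrix, so
patterns can also be lifted from labelled reference data and replayed on new
plates.

## Expression and spots

Expression is attached per cell by uniformly sampling (with replacement, so
the plate may exceed the reference) a same-type cell from a labelled
reference. The built-in reference simulator draws negative-binomial counts
(variance $\mu + \mu^2/\theta$) with per-type marker blocks — default 20
markers per type at fold-change 8 over baseline mean 2, dispersion 2 —
package defaults intended to give clearly separable types without being
unrealistically clean. `starmap_like_fixture()` combines these pieces into a
fully synthetic 1234-cell layered-cortex dataset (six types with fixed
counts 141/150/258/198/287/200; the three excitatory types in distinct
strata, the rest dispersed) used throughout the test suite.

Spot aggregation mimics capture arrays: circle or rectangle spots on a
square or hexagonal lattice at pitch equal to the spot diameter/side.
Membership is by cell centre; rectangles use half-open intervals
$[\min, \max)$ per axis so abutting spots never double-count, and circles
use the strict interior, so cells in lattice gaps are dropped and reported.
Spot expression is the integer sum of member-cell profiles, and the per-spot
type composition is emitted as both counts and proportions — exact ground
truth for deconvolution benchmarks.

## Evaluation metrics

ARI and NMI follow their standard contingency-table formulas; NMI uses the
natural logarithm (the arithmetic-mean-normalised ratio is base-invariant)
and defines two trivial single-cluster partitions as perfectly concordant.
The spatial-pattern discrepancies compare two datasets through the Frobenius
norm of their transition matrices (TM), centrality score matrices (CSM:
group degree centrality, mean member clustering coefficient, group
closeness with unreachable nodes excluded and flagged), and
neighbourhood-enrichment z-score matrices (NEM). The NEM null shuffles
labels over the fixed graph; the population (divide-by-$m$) standard
deviation is used so the Monte-Carlo estimator converges exactly to the
exhaustive-enumeration null, and $z = 0$ is reported when $\sigma = 0$ with
the observed count at its null mean. Ripley's
$L(t) = \sqrt{\hat K(t)/\pi}$ uses the unweighted estimator
$\hat K(t) = \frac{|A|}{n(n-1)} \sum_{i \ne j} \mathbf 1[d_{ij} \le t]$ with
no edge correction by default — the curves are used comparatively on matched
geometry, where the shared bias cancels — and a border-corrected variant for
absolute calibration against the CSR baseline $L(t) = t$. SI and RSI compare
ligand-receptor pair sets: overlap over the smaller set, and one minus the
mean normalised rank displacement of the shared pairs.

## Problem sizes and what the tests show

The suite validates the optimiser at three scales, chosen to exercise every
epoch regime while keeping a full run in tens of seconds: exhaustive-oracle
instances (N = 10, all 252 count-feasible labelings enumerated), mid-size
two-type runs (N = 2000, k = 6, where the exact-count constraint and the
mixed/ring/layered join-count ordering are asserted), and a parameter
recovery run (N = 5000, attractive K = 3, per-entry error ≤ 0.05 — observed
about $10^{-3}$). The synthetic generator draws uniform plates and
negative-binomial expression; it does not emulate segmentation noise,
spatially varying density, platform-specific capture efficiency, or
spatially varying transition structure, so passing tests certify the
optimiser and the bookkeeping, not fidelity to any particular tissue.

## Known limitations

* The transition matrix is spatially invariant; boundary dynamics or
  invasion fronts where $P$ varies with position are out of scope.
* Delaunay graphs are 2-D only (no 3-D triangulation backend); kNN, radius,
  and SNN graphs are fully dimension-agnostic, so 3-D plates and multi-slide
  sectioning remain available with those methods.
* Contact-inconsistent targets (violating $C_i P_{ij} = C_j P_{ji}$) are
  approximated, not met; `estimate_pattern()` on the result reveals the
  achievable pattern.
* The annealing heuristics carry no optimality guarantee beyond the
  small-instance oracle checks; for pathological targets the incumbent is
  simply the best labelling encountered.
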