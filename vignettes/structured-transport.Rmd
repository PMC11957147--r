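---
title: "Structure-preserving transport between time points of spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-preserving transport between time points of spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Time-series spatial transcriptomics samples a tissue at two (or more) time
points, but the cells profiled at `t2` are not the same physical cells as at
`t1`. Trajectory inference must therefore estimate an ancestor-descendant
coupling: a nonnegative matrix `T` whose entry `(i, j)` is the mass carried
from cell `i` at `t1` to cell `j` at `t2`. Optimal-transport couplings driven
by expression similarity alone, or by expression plus global geometry, tend
to split spatially contiguous biological units — airway cross-sections,
ovarian follicles, glomeruli — across many descendant units, which is
developmentally implausible: such units drift, grow and branch, but do not
scatter. This package adds a structural-coherence penalty to the fused
unbalanced Gromov-Wasserstein objective so that annotated units are coupled
as units.

## The objective

Given count tables, coordinates and per-cell structure labels at both time
points, preprocessing filters cells with fewer than 10 transcripts,
median-normalizes and log-transforms counts, and projects both datasets onto
one jointly fitted PCA basis (a single basis is required for cross-dataset
expression distances to mean anything; fitting separate bases would make
`|x_i - y_j|` comparisons arbitrary). The solver then minimizes, over
nonnegative `T`,

    alpha * Expr + (1 - alpha) * (Geom + Struct) + Reg + epsilon * Entr

with

* `Expr = sum_ij Dg[i,j] T[i,j]` — squared Euclidean expression distance in
  PC space between ancestors and descendants;
* `Geom = sum_ijkl (D1[i,j]/f1 - D2[k,l]/f2)^2 T[i,k] T[j,l]` — a
  Gromov-Wasserstein term preserving pairwise spatial distances;
* `Struct` — the same quadratic form on binary structure-disagreement
  matrices `S1`, `S2` (entries 0 for same-structure pairs, `fb` otherwise):
  two cells of one structure whose descendants land in different structures
  pay `fb^2`-scale penalty, so contiguous units move as blocks;
* `Reg` — tensorized KL penalties (weights `rho1`, `rho2`) tying the row and
  column marginals of `T` to expected mass vectors `p1`, `p2` (uniform by
  default), which tolerates growth, death and unequal cell numbers;
* `Entr` — a tensorized KL of `T` against the product reference `p1 p2'`,
  the entropic smoothing that makes fast scaling algorithms applicable.

The scale factors `f1 = |D1|_F / |Dg|_F` and `f2 = |D2|_F / |Dg|_F` put the
spatial and structural matrices on the Frobenius scale of the expression
cost. They divide `S1`, `S2` as well, so the raw `fb` is not directly
interpretable across datasets; `fb_on_expression_scale()` converts a
dimensionless choice (1 = effective penalty equal to the mean expression
cost, enough to firmly discourage splitting; 0.01 = barely a bias) into the
corresponding raw `fb`.

### Tensorized KL and its constants

The marginal and entropy penalties use the quadratic (tensorized) divergence
`KL(mu x mu | nu x nu) = 2 m(mu) KL(mu | nu) + (m(mu) - m(nu))^2` of the
unbalanced Gromov-Wasserstein formulation. Near total mass 1 it behaves like
twice the plain KL; any constant-factor convention is absorbed into the
effective `rho` and `epsilon`, which is why those parameters are exposed on
a relative scale rather than fixed to literature values.

## The algorithm

`solve_socs()` uses alternating minimization. At each outer iteration the
two quadratic terms are linearized around the current plan with the
squared-loss decomposition `(a - b)^2 = a^2 + b^2 - 2ab`, which reduces the
quartic contraction to three matrix products per term. The mass-correction
terms of the tensorized KLs are folded into the linear cost as a uniform
offset, so the resulting subproblem — an entropically regularized unbalanced
*linear* transport problem with effective parameters `m * epsilon`,
`m * rho` (`m` the current total mass) — has exactly the stationarity
condition of the full objective at a fixed point. The subproblem is solved
by log-domain scaling iterations (a compiled kernel; log-domain updates keep
small `epsilon` from overflowing the scaling factors), warm-started across
outer iterations. After each subproblem the plan is rescaled to the
geometric mean of the old and new total mass; without this damping the
block updates settle into a period-2 mass oscillation, with it they converge
in a few dozen outer iterations. Convergence is declared when the relative
Frobenius change of `T` drops below `tol` (default `1e-6`, at most
`max_iter = 200` outer iterations); the per-iteration objective trace is
returned and is checked (in the test suite) to be non-increasing.
Initialization is the deterministic product plan `p1 p2'`, so runs are
reproducible without any seed; the seed recorded in `solver_params` only
covers optional downstream sampling.

### Parameter defaults, units, and how they were set

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.4 | weight of expression vs geometry + structure |
| `fb` | via `fb_on_expression_scale(scale = 1)` | structural penalty |
| `rho1`, `rho2` | 1 (relative) | marginal adherence |
| `epsilon` | 0.05 (relative) | entropic blur |
| `d` | 50 | PCA dimensions |
| `tol` | 1e-6 | outer relative-change tolerance |

`rho` and `epsilon` are interpreted in units of the objective's
per-unit-mass cost at the product-plan start (the expression term plus the
linearized quadratic terms). This matters: the quadratic terms live on the
*squared* distance scale, so units tied to the expression cost alone would
leave the marginal penalties orders of magnitude too weak on datasets with
large coordinate ranges. The defaults were chosen on the synthetic studies
shipped with the package — the source literature reports no parameter values
for this solver — as the values at which the structural penalty cleanly
separates its two regimes (couplings that keep structures whole at
`fb`-scale 1, couplings free to split them at `fb = 0`) while the solver
converges in tens of iterations. They are starting points, not universal
constants; `alpha` and `epsilon` in particular should be revisited per
dataset.

## Evaluating a coupling

* **Descendant sampling** (`sample_descendants()`): each `t1` cell draws one
  descendant from its row-normalized transport vector by inverse-CDF
  sampling; rows with zero mass are flagged, never silently defaulted.
* **Geometric consistency** (`geometric_consistency()`): Pearson correlation
  between all pairwise `t1` distances and the distances between the sampled
  descendants; 1 means geometry is preserved exactly, and the measure is
  invariant to rigid motions of either dataset.
* **Mapping profiles and Hill numbers** (`mapping_profile()`): for each
  source category (cell type or structure), the distribution of its cells'
  descendants over target categories, summarized by the order-1 Hill number
  `exp(Shannon entropy)` — the effective number of target categories. A
  structure coupled as a unit has Hill 1; one split evenly over k structures
  has Hill k. Two estimators are available: sampled (from a descendant
  assignment, the documented default and the convention used in the
  evaluation literature) and mass-weighted (directly from `T`,
  deterministic; used by the package's own acceptance checks). Effective
  *ancestor* counts are the same computation on the transposed plan.
* **Maturation classification** (`classify_by_descendant()`): a structure is
  assigned a descendant category when at least 80% (inclusive) of its cells
  map there, otherwise it is ambiguous.

## Morphology and neighborhoods

Structure footprints are convex hulls of member-cell coordinates. The
diameter is the mean, over 180 directions spaced 1 degree apart, of the
longest chord of the hull parallel to each direction — for irregular shapes
this averages long and short axes; for a disc it is the usual diameter. The
chord is computed on the hull (chords of a raw point set are ill-defined),
exploiting that the chord-length profile of a convex body is concave in the
offset, so each direction's maximum sits at a hull-vertex level. Distance to
the tissue border is the mean per-cell minimal distance to a boundary
polygon — a digitized border if available, else the convex hull of all
cells. Densities are counts per polygon area; hand-segmented areas (e.g.
antrum-aware follicle outlines) can replace hull areas. Neighborhoods come
from a Delaunay triangulation with edges longer than a threshold removed;
the threshold defaults to 3 times the median Delaunay edge length, a robust
scale that adapts to cell density (the literature leaves this cutoff
unspecified). Group comparisons use Welch's unequal-variance t-test — the
reported results in this literature are Welch's even where methods text says
"two-sample t-test" — with a pooled-variance variant behind a flag.

## Differential expression

`wald_de()` is a self-contained per-gene Wald test on normalized log
expression: unequal-variance standard error, normal reference, two-sided p,
Benjamini-Hochberg q over all tested genes. This deliberately replaces the
negative-binomial count-model Wald test used upstream in this literature
with a distribution-light equivalent on the already-normalized scale; the
decision structure (statistic, reference, thresholds, consistency calls) is
identical and desk-testable, but effect-size estimates on weakly expressed
genes will differ from a count model's. Fold changes are ratios of
expm1-backtransformed group means. The fold-change threshold is a *required*
argument: published analyses use both 1.5 and 1.25, so the package refuses
to pick silently (the CLI defaults to 1.5). Cross-replicate consistency
keeps genes significant in both replicates with the same fold-change sign.

## What the simulator does and does not emulate

`simulate_pair()` places disk-shaped structures without overlap in a square
domain, plus uniform background stroma. Each structure carries one of a few
expression programs (default 3 program types across 6 structures, 15 marker
genes each at 10-fold elevation, negative-binomial counts with dispersion
0.3 at depth 500) — deliberately fewer programs than structures, so sibling
structures are indistinguishable by expression and the geometric and
structural terms carry real weight, as airways sharing an epithelial
profile do. Between time points structures drift (SD 30 on a 1000-unit
domain), may branch into two equally sized daughters (never merge), and may
mature: switch program, grow by `growth_factor`, and shift toward the
domain center — echoing follicle maturation so that morphology comparisons
have a designed signal. Descendant cells are resampled around their
ancestors' relative positions, and every t2 cell records its true ancestor;
`truth_plan()` turns that record into the oracle coupling whose
structure-level Hill numbers equal the true branching counts exactly.

The simulator does *not* emulate real gene panels, spatial depth gradients,
segmentation errors, batch effects between time points, or irregular
structure shapes. Passing tests therefore demonstrate that the method
recovers plantable, known couplings under controlled noise — not that it is
robust to everything real tissue does.

### Problem sizes in the shipped studies

The package's tests and acceptance script run the simulator at its default
scale — six structures of 30-60 cells plus 100 background cells per time
point (roughly 330 x 330 couplings, reduced to 30 PCs) — and smaller
variants for unit tests. These sizes keep a full study in seconds while
leaving all qualitative regimes (structured vs unconstrained, branching vs
not) clearly separated.

## Numerical choices and degenerate inputs

* Log-domain scaling updates throughout; masses are floored only implicitly
  (log of the strictly positive `p1`, `p2`).
* An expression cost that is identically zero makes the scale factors
  undefined and is rejected, as are non-finite coordinates (reported with
  offending cell indices), negative `fb`, zero-mass plans, and
  self-intersecting boundary polygons.
* Median normalization uses R's convention (midpoint of central totals for
  even cell counts).
* PCA component signs follow a fixed largest-loading-positive convention so
  projections are reproducible across BLAS implementations.
* For an even number of cells in a branching split both daughters get
  exactly the parent's cell count, which is what makes the truth-plan Hill
  number exactly 2 under universal branching.
* Degenerate DE genes (zero variance in both groups, equal means) get
  p = 1 and fold change 1; constant-but-different groups get p = 0.

## Background cells and the structure term

Cells outside any annotated structure are real (stroma, mesenchyme) but the
structure maps are only defined on annotated units. Three policies are
exposed for how such cells enter `S`: `shared` (default) gives all
background cells one shared label, so background-to-structure switches are
penalized like a cell-type constraint while background-to-background
movement is free; `free` zeroes any pair touching background, penalizing
only splits of annotated structures; `singleton` makes each background cell
its own unit, which effectively freezes the background and is rarely what
is wanted. None of these is asserted to be the upstream authors' choice —
their data only labels cells inside structures.

## Known limitations

* Two time points only; no multi-slice joint inference, no growth-rate
  estimation, no GPU path, no low-rank factorization — couplings are dense,
  so memory is `O(n1 * n2 + n1^2 + n2^2)` and a few thousand cells per time
  point is the practical ceiling.
* The solver finds a stationary point of a non-convex objective; different
  parameter scales can select different couplings. The acceptance suite
  pins the regimes that matter (oracle equivalence in the convex `alpha = 1`
  limit, entropy-dominated limit, block-permutation recovery), not global
  optimality.
* Structure labels are inputs; the package neither segments structures nor
  annotates cell types.
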