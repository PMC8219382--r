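---
title: "Growth mechanics and morphometrics of the ovule primordium: models and methods"
author: "ovulegrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth mechanics and morphometrics of the ovule primordium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ovulegrowth)
```

## Scientific scope

The Arabidopsis ovule primordium is a digit-shaped organ that bulges out of
the placenta. Within it a single subepidermal cell, the spore mother cell
(SMC), commits to meiosis. This package implements, in one testable code
base, (i) two complementary 2D mechanical growth models of a longitudinal
median section of the primordium, used to ask which combinations of growth
hypotheses reproduce the organ's digit shape and the emergence of an
enlarged, elongated subepidermal cell; and (ii) the morphometric and
statistical pipeline used to quantify primordium and cell geometry in
simulated or segmentation-derived data, including developmental
canalization statistics for SMC singleness.

## The mass-spring (MS) engine

The tissue is a planar cell complex: polygonal cells bounded by walls
(springs) joining vertices. Each wall carries a linear elastic force in
engineering strain, `k (l - L0)/L0`, and each cell a uniform turgor
pressure `P` (force/length in 2D) loading its walls outward; the pressure
term is implemented exactly as `-P dA/dx`, i.e. `P l/2` on each wall
endpoint along the cell-outward normal. Quasi-static equilibrium is
recomputed before every growth step by minimising the total energy

    E = sum_walls 1/2 k (l - L0)^2 / L0  -  sum_cells P A

over the free vertices (the placenta boundary is pinned). The minimiser is
L-BFGS on the analytic gradient, with two safeguards: a Barzilai-Borwein
descent fallback for configurations near buckling saddles (a compressed
wall is laterally unstable, and quasi-Newton line searches can stall
there), and a soft incompressibility barrier that activates only when a
cell is squeezed below 25% of its birth area — a physical stand-in for
cytoplasm incompressibility that keeps the constant-pressure model from
collapsing cells. Convergence is declared when the largest residual force
component is below `tol` (default `2e-4`, about 0.5% of the typical
spring force at the default stiffness).

Growth has two uncoupled modalities:

* **Signal-based growth.** An abstract growth factor `c` (per cell, in
  [0, 1]) stands in for the cumulative biochemical cues. It diffuses on the
  cell-adjacency graph with an explicit update `c_i += D sum_j (c_j - c_i)`
  restricted to a *competence domain* (see Scenarios), with designated
  source cells re-clamped to `c = 1` after every substep, and it is
  *diluted* by growth (concentration is intensive: it is scaled by the
  inverse areal expansion each step). Walls of signalling cells extend
  their rest length by `g * cbar * ((1 - w) + w |cos(theta)|)` per step,
  where `theta` is the angle between the wall and the cell's polarization
  axis and `w` the anisotropy weight; in the epidermis (L1), growth is
  restricted to periclinal walls. Prescribed growth cannot push: a wall at
  or below zero tension does not extend (a Lockhart-type gate). Without
  this gate, prescribed extension of compressed walls accumulates slack
  rest length and the surface buckles into self-intersecting folds.
* **Strain-based growth.** Walls in competent cells whose elastic strain
  exceeds a yield threshold grow plastically,
  `L0 <- L0 (1 + eta (strain - eps_y))` — the elasto-plastic wall law.
  Growth is irreversible: rest lengths never shrink.

A cell divides when its area reaches its target area (default twice the
birth area), along the shortest wall through its centroid: chord
directions are scanned at 0.5 degrees and locally refined; ties are broken
by the chord whose normal is closest to the cell's polarization, then by
the lowest boundary-parameter anchor. The new wall is born unstrained.
Children receive fresh ids, the parent id is retired, and the lineage is
logged; an SMC's children revert to ordinary identity and target area.

### Default parameters

The reference defaults (`ms_params()`) were calibrated once so that the
reference scenario grows a realistic digit: `k_L1 = 4`, `k_inner = 1`
(stiffer epidermis), `P = 0.004` (about 2% baseline wall strain),
`D = 0.06` with 6 substeps/step (substeps subdivide further automatically
if a cell's neighbour count would violate the explicit stability bound),
`g = 0.035`, `w = 0.85` (a small isotropic component of inner growth lets
the sustained basal signal widen the base, as in the reference organ),
`growth_gate = 0.002` (prescribed growth requires 0.2% wall tension),
`eps_y = 0.03`, `eta = 0.5`, equilibrium tolerance `2e-4`, division scan
at 0.5 degrees. Simulation time is the loop iteration count; no physical
time calibration is attempted, and all scenario comparisons are ordinal
(at matched step or matched cell count), never against wall-clock stage
ages.

## The FEM engine

The continuum counterpart is plane-stress linear (T3) elasticity on a
structured, mirror-symmetric triangulation of the same template geometry,
with the L1 as a boundary strip of elements carrying its own material and
growth flags. Each step applies an eigenstrain increment

    dG = g c ((1 - w) I + w d (x) d)  +  eta * ramp(eps_p - eps_y) resolved
                                         along principal strain directions

(`d` the polarization: vertical in the inner tissue, the local outer
surface tangent in the L1; the signal part is trace-normalised over the
anisotropy weight so that removing growth anisotropy redistributes the
same prescribed areal growth instead of doubling it, and L1 surface
extension is tension-gated as in the mass-spring engine — the inner
tissue, which has no turgor pre-tension in the continuum model, is not
gated), solves the linear elastic problem with the bottom boundary fixed
and other boundaries traction-free, updates the
geometry incrementally (small-strain stepping with geometry update), and
accumulates elastic strain. Material anisotropy is an orthotropic
stiffness, built in the fiber frame and rotated: the material is stiffer
*across* the growth axis (ratio `anisotropy_ratio`, default 5). For the
L1 this is the anticlinal direction, so the anisotropic epidermis resists
thickness changes — switching the material to isotropic thickens the L1,
and prescribing anisotropy in the L1 alone restores it, reproducing the
corresponding model contrasts. Mesh quality is monitored (minimum element
angle) and restored by local, region-preserving Delaunay-style edge flips
with area-weighted field transfer; a general remesher is deliberately out
of scope at this problem size.

Verified mechanical baselines: uniform growth of a free isotropic sheet is
stress-free to 1e-8 (patch test), and a two-layer strip with a lengthwise
growth mismatch bends with the curvature of the classical bilayer
(bimetallic-strip) formula within a few percent at fine mesh.

## Scenario grid

`make_scenario()` encodes the hypothesis grid as machine-readable configs.
Three readings fix the signal geometry for all models:

* `signal_distribution` is the *competence domain* where the signal exists
  and diffuses: the whole L1, the pit-shaped inner stripe (a vertical
  stripe of configurable width centred on the template midline), their
  union, or everything ("broad"). This is what lets the broad-distribution
  model diffuse widely while the reference confines the signal to a pit.
* `fixed_high_conc` picks the Dirichlet sources within the midline stripe
  (its L1 part, its inner part, or both).
* The whole domain starts at `c = 1`; dilution by growth then makes the
  sustained sources matter.

Growth anisotropy is always active in the L1 except in the variant that
specifically removes it there; inner growth anisotropy is off only in
model 3. Material anisotropy exists only for the FEM engine (mass-spring
walls cannot represent it; requesting the corresponding mass-spring model
errors). Model 8 disables strain-based growth. Variants double the SMC
target area, make L1 growth isotropic, or exempt the SMC from division.

## Shared morphometric readouts

`outline_height_width()` is the single organ-shape readout used by both
engines and by synthetic outlines. The outline polyline is resampled
uniformly in arc length, smoothed with a Gaussian window (default 2 um;
3 um on simulation snapshots, where wall-scale notches would otherwise
masquerade as curvature extrema), and signed curvature is computed by
finite differences. The apex is the point farthest from the endpoint
chord; each base point is the first clearly concave local curvature
minimum walking outward from the apex (threshold 0.05/um), falling back to
the most concave flank point and then to the placenta intersections (with
a warning) for flat bumps. Height is the maximal perpendicular distance
from the base chord, width the distance between base points, and the apex
curvature the maximal curvature near the apex. Walking outward from the
apex — rather than taking the globally most concave points — makes the
rule robust to a gentle waist on the digit flank; on smooth single-bump
outlines the two rules coincide.

Cell-level descriptors follow the covariance-eigenvalue convention:
anisotropy indices `sqrt(lambda_i) / sum_j sqrt(lambda_j)` (proportional
to the principal extents; isotropic cells give 1/3 each), sphericity
`pi^(1/3) (6V)^(2/3) / S`, prolate ellipticity `1 - sqrt(l2/l1)` and
oblate ellipticity `1 - sqrt(l3/l2)` — the ellipticity formulas are a
documented convention (bounded in [0, 1], monotone in
elongation/flattening); exact numerical parity with proprietary
segmentation software is not claimed. Surface areas of voxel masks use
the coarea of a Gaussian-smoothed indicator (sigma = 1 voxel), which is
accurate to a few percent for smooth cells, unlike raw face counting
(up to +50% bias). Meshes use exact signed-tetrahedron volume and moment
formulas.

Stage classification keys on the L1 cell-file length above the placenta
(within each stage's reference min-max range), resolving ambiguities by
normalised distance of total cell count and then aspect ratio to the
reference means; out-of-range features return the nearest stage with a
flag.

## Synthetic data: what it emulates and what it does not

`synth_ovule_stack()` builds a dome (superellipsoid cap on a placental
slab, organ axis in the imaging plane) partitioned by Lloyd-relaxed
nearest-seed tessellation, constrained to a one-cell L1 shell, with one
enlarged, tilted, subepidermal SMC of prescribed semi-axes and major-axis
angle. Organ height/width and cell counts are drawn log-normally around
per-stage reference means (the two latest stages' height/width are not
tabulated and are extrapolated from the growth trend: 47/28 and
56/28.5 um); the SMC angle is von Mises. A sub-placental basal tissue
disc (5 um deep) is part of the organ, because at the earliest stages the
tabulated cell counts cannot fit into the dome alone; SMC semi-axes
shrink proportionally at stages whose subepidermal space is smaller than
the default ellipsoid. The fraction of cells allocated to the L1 shell is
calibrated per stage (0.32-0.53) so that the measured median-section L1
file length reproduces the per-stage means; organ size and count
dispersion default to a 4% coefficient of variation — deliberately
tighter than the cross-ovule standard deviations of real populations,
where adjacent stages genuinely overlap — so that recovery tests measure
pipeline fidelity rather than irreducible biological overlap. Default
voxel size is 0.5 um isotropic, which keeps a stack
generation-plus-quantification cycle at a few seconds while leaving the
SMC ~10 voxels across its minor axis; the stored ground truth records
per-cell layers (from the constructed shell and shell contact), the SMC
geometry, and the drawn organ size. The stage features measured back
from a stack are the total cell count, organ height/width above the
slab, and the L1 file length, the latter averaged over four longitudinal
sections (two axis-aligned, two diagonal) to reduce counting noise. Noise
families are the simplest ones matching reported mean/SE structure:
log-normal sizes, von Mises angles, binomial/multinomial counts
(`synth_cell_table()`, `synth_mitosis_scores()`, `synth_classab()`).

These generators emulate the *measurement structure* of segmented ovule
stacks — label rasters, descriptor tables, count tables — not microscopy:
no point-spread function, no staining artefacts, no segmentation errors,
no biological covariance between neighbouring cells' shapes. Passing
recovery tests therefore demonstrates that the pipeline measures what the
generator encodes at realistic geometry and sample sizes; it does not
certify performance on raw microscopy-derived segmentations.

## Statistics

Fisher's exact test on 2x2 tables is two-tailed by the summed-probability
convention (all tables at fixed margins whose probability does not exceed
the observed one, with the customary `1 + 1e-7` float slack) — the common
definition, adopted because no two-sided rule is otherwise specified.
Rank comparisons use the exact Wilcoxon/Mann-Whitney null for small
samples without ties and the tie-corrected normal approximation
otherwise. Mitotic frequency maps normalise reporter-positive counts per
domain by the total over domains, after excluding all-zero ovules; maps
from two genotypes combine into log2 fold-change maps. Class A/B
canalization curves report the per-stage percentage of ovules with two or
more SMC candidates, Fisher contrasts against both the preceding stage and
the first stage (both are reported because either baseline is a
defensible reading of "significantly reduced from stage X"), and the
resolution stage = first significant drop versus the preceding stage. No
multiple-testing correction is applied by default (raw p-values are
reported); a Benjamini-Hochberg adjustment can be applied downstream via
`p.adjust`.

## Numerical choices and degenerate inputs

* Division of a polygon whose centroid lies outside it (pathological
  non-convex case) is deferred with a warning, as is a chord that grazes a
  single edge.
* Chord endpoints within 5% of an existing vertex snap to it, avoiding
  sliver walls.
* Diffusion stability requires `D * max(degree) <= 1`; violating configs
  error rather than silently integrating an unstable scheme.
* Coplanar voxel cells get a clamped zero eigenvalue and a degeneracy
  flag; indices remain defined.
* Determinism: every stochastic element (generators, optional division
  noise) is a pure function of (params, seed); the solver's saddle
  perturbation uses a fixed internal seed and restores the caller's RNG
  state.

## Worked example

A reduced reference run (20 steps, 8x3 template) and its shape readout:

```{r example, eval = FALSE}
cfg <- make_scenario("MS2")
sim <- run_ms(cfg, ms_params(), T_max = 20, n_cols = 8, n_rows = 3)
print(sim)
tail(sim$metrics[, c("step", "n_cells", "height", "width", "hw_ratio")], 3)
plot(sim)
```

The scenario comparisons reported by `scripts/acceptance.R` use 90-step
runs of the 12x4 reference template (one to a few hundred cells) for the
mass-spring grid and 75-step runs on a 48x16 template (1536 elements)
for the FEM grid; these sizes were chosen as the smallest at which the
ordinal contrasts between scenarios are stable. The isotropic variant of
the mass-spring engine divides faster than the reference, so its shape
contrast is evaluated at matched cell count; the emergent-SMC contrast
between the reference and the isotropic variant uses the positional
candidate (the current central sub-apical inner cell), summarised by the
median over the last 30 steps, because the lineage-tracked cell divides
early and single-step values jump when the candidate identity switches.

## Known limitations

* 2D median-section mechanics only; 3D data enter as label stacks or
  descriptor tables for quantification, never as mechanical meshes.
* The mass-spring engine cannot represent material anisotropy (model 1 is
  FEM-only, as in the hypothesis grid).
* No viscoelastic walls, no explicit cell-cycle timing (divisions are
  area-triggered), no contact mechanics; buckling folds that would
  self-contact are prevented only indirectly (tension-gated growth).
* Simulation time units are iterations; absolute stage ages are not
  modelled.
* The outline width rule requires a concave primordium-placenta junction;
  for nearly flat bumps it falls back to the template ends, which inflates
  the width (and deflates H:W) of barely-protruding organs — acceptable
  for ordinal comparisons, not for absolute early-stage widths.
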