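---
title: "Outlet flow splitting and aneurysmal hemodynamic metrics: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlet flow splitting and aneurysmal hemodynamic metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ostium)
```

## The problem

Image-based blood-flow analysis of an intracranial aneurysm starts from a
segmented lumen and a set of boundary conditions. Two of the largest
uncertainty sources are (1) how the total outflow is split among the outlet
vessels and (2) how the lumen was segmented in the first place. `ostium`
implements the computational core needed to study both: five outlet
flow-splitting strategies on vessel trees, the standard intrasaccular flow
and wall-shear metrics on time-resolved fields, and the comparison
statistics (deviation tables, scaled-MAD outlier exclusion, scatter
reductions) used to weigh the two effects against each other. It does not
solve the 3D Navier–Stokes equations; fields come either from a solver
export or from the package's analytic phantoms.

## Flow-splitting strategies

Each strategy assigns outlet $i$ a fraction $f_i$ of the total outflow,
$\sum_i f_i = 1$:

* **bc2 / bc3 (global Murray law).** Flow scales with a power of vessel
  caliber: $f_i = D_i^{\,n} / \sum_j D_j^{\,n}$ with $n = 2$ (square law)
  or $n = 3$ (cube law), applied to the outlet diameters only. The power
  law is often written as a proportionality between $Q_i/\sum Q$ and
  $(D_i/\sum D)^n$; that form does not sum to one over outlets, so the
  normalized form above is what `murray_split()` computes. The
  normalization is not cosmetic: it is what makes a cube-law column
  recoverable from a square-law column via $D_i \propto \sqrt{f_i^{(2)}}$,
  an internal-consistency property the test suite checks against the
  shipped reference table.
* **bc4 (hierarchical squared-diameter).** The square law applied locally
  at every bifurcation, $Q_1/Q_2 = (D_1/D_2)^2$ among the children of a
  junction; an outlet's global fraction is the product of the local
  fractions along its root-to-outlet path. For a tree with a single
  junction this is identical to bc2; with nested junctions it is not,
  because upstream branch calibers re-weight the downstream splits.
  Junctions with more than two children are split jointly in proportion to
  all children's $D^2$ (the pairwise law generalizes naturally; the
  pairwise-vs-joint choice only matters at trifurcations, which are rare).
* **bc5 (hierarchical anatomical area).** The same traversal with
  $Q_1/Q_2 = A_1/A_2$, where $A$ is the *true* luminal cross-section area
  estimated by raytracing (below). For perfectly circular lumens bc5
  coincides with bc4; for real lumens it is the only strategy that sees
  non-circularity, which is why it serves as the reference in comparisons.
* **bc1 (zero-pressure surrogate).** A constant-pressure outlet condition
  does not prescribe a split; the split emerges from the resistance of the
  vascular domain. `zero_pressure_network_split()` emulates this with a 0D
  Poiseuille network: each segment of length $L$ and radius $R$ becomes a
  conductance $G = \pi R^4 / (8 \mu L)$, a unit inflow is injected at the
  inlet, outlets are grounded at $p = 0$, and the nodal linear system is
  solved. This is a deliberate lumped surrogate — it reproduces the
  *character* of the zero-pressure condition (resistance-governed flows,
  strong sensitivity to caliber via $R^4$), not the output of any 3D
  solver, and the package never claims otherwise.

`compute_all_splits()` runs all five and returns a tidy table in the
tree's stable outlet order.

### Raytraced cross-section area

Anatomical sections are closed planar polylines around a centerline anchor.
`polygon_area_raytrace()` casts `n_rays` rays, uniformly spaced in angle,
from the anchor within the section plane; each ray's nearest boundary
intersection becomes a vertex of a fan-triangulated polygon. Choices that
pin the result down:

* The first ray points along the projection of the global $+x$ axis onto
  the plane ($+y$ if degenerate), so results are reproducible.
* Ties (a ray through a polyline vertex) resolve to the nearest
  intersection, which is also what makes non-convex borders well-defined:
  the reconstructed polygon is the star-shaped region seen from the
  anchor, exactly what "rays from the centerline to the border" means.
* The default `n_rays = 64` keeps the relative area error of a circular
  section below 0.1 %; the error decays at second order in the ray count
  (verified in the tests), so doubling the rays quarters the error. The
  ray count of the original tooling is not documented anywhere we know of;
  it is a free parameter here.

Diameters for bc2–bc4 on non-circular sections are *equivalent diameters*
$D = 2\sqrt{A/\pi}$ of the raytraced area — the only choice consistent
with treating the area-based strategy as the refinement of the
diameter-based ones.

## Hemodynamic metrics

Given a `field_series()` (point-centred velocity, cell-centred wall shear
stress, one cardiac cycle of samples), `metrics_report()` assembles:

| metric | definition | units |
|---|---|---|
| `mean_V` | cycle- and volume-mean sac speed | m/s |
| `mean_vorticity` | cycle- and volume-mean $\lvert\nabla\times u\rvert$ | 1/s |
| `KE` | $\tfrac12 \rho V^2$, volume-mean, cycle-mean | J/m³ |
| `KER` | cycle-mean sac KE / cycle-mean parent KE | — |
| `OVI` | $\tfrac12\bigl(1 - \lvert\int_0^T \mathbf{V}\,dt\rvert / \int_0^T \lvert\mathbf{V}\rvert\,dt\bigr)$ | — |
| `TAWSS` | $\tfrac1T\int_0^T \lvert \mathrm{WSS} \rvert\,dt$, area-mean | Pa |
| `nTAWSS` | sac TAWSS / parent TAWSS | — |
| `LSA` | sac area fraction with TAWSS below parent mean − parent SD | — |

Numerical choices, and why:

* **Temporal integrals** use the trapezoidal rule on the supplied samples;
  convergence is second order on smooth signals and testable against dense
  quadrature. The series is taken to span exactly one period — phantoms
  are exactly periodic, and a solver user passes the final cycle.
* **Volume quantities are evaluated per cell** (mean of the cell's point
  samples) and averaged with volume weights; surface quantities are
  area-weighted. Weighting makes results independent of local mesh
  density. Evaluating OVI at cell centres rather than at points matters at
  no-slip walls: wall points carry identically zero velocity, whose OVI is
  defined as 0 (trivially steady), and a per-point average would dilute
  the region value; cell-centred evaluation preserves the exact limits 0
  (steady) and 0.5 (full reversal).
* **OVI uses the velocity vector** in the numerator (magnitude of the
  vector time-average). With the speed scalar instead, the numerator and
  denominator coincide and the index would be identically zero; the 0.5
  bound requires vector cancellation. Cells with identically zero velocity
  over the cycle take OVI 0. No clamping is applied anywhere — the
  $[0, 0.5]$ range holds by construction.
* **Vorticity** comes from weighted least-squares gradient reconstruction
  over point neighborhoods (points sharing a cell, inverse-distance
  weights). Where a neighborhood has at least 12 usable neighbors the fit
  is quadratic, making gradients exact for quadratic velocity fields —
  the parabolic pipe profile is the canonical test — and second-order
  accurate in general; sparse neighborhoods (e.g. box corners) fall back
  to a linear fit, still exact for linear fields such as rigid rotation
  ($\lvert\omega\rvert = 2\Omega$) and simple shear. Coincident mesh
  points (sphere poles) are dropped from neighborhoods; a genuinely
  degenerate neighborhood is an error naming the point.
* **The parent-vessel SD in the LSA threshold** is the area-weighted
  *population-form* SD, consistent with the area-weighted mean in the same
  formula (two equal-area parent patches at 2 and 4 Pa give mean 3, SD 1,
  threshold 2 Pa). The scatter statistic `relative_sd()` by contrast uses
  the sample SD, the convention for small ensembles.
* **`wss_from_velocity()`** (for fields without solver-exported WSS) fits
  the tangential velocity of the nearest mesh points against their
  distance along the wall cell's inward normal and takes
  $\tau = \mu\,\partial u_t/\partial n$ as the slope. The one-sided fit is
  exact for linear near-wall profiles, returns zero for a uniform field,
  and reaches the Poiseuille closed form $4 \mu \bar V / R$ within a few
  percent at moderate near-wall resolution.

## Variability statistics

`deviation_vs_reference(value, reference)` returns
$\operatorname{round}\bigl((\text{value} - \text{reference})/\text{value}\cdot 100\bigr)$
— note the *compared method's own value* in the denominator. The
convention was established by recomputing the shipped reference table: a
cell of 0.002 against a reference of 0.020 prints −900, which forces
division by 0.002. Rounding is half-away-from-zero (it reproduces −1055
from −1054.55, where round-half-even would not). `deviation_table()`
applies this elementwise; zero-valued cells are recorded as `NA` rather
than dropped.

`mad_outliers()` flags values more than three *scaled* MADs
($1.4826 \times$ median absolute deviation, the normal-consistency
scaling used by common statistical toolboxes) from the median. When the
MAD is zero, any strict deviation from the median is flagged — the only
reading under which the rule still partitions the data.

`interplay_experiment()` reproduces the two-part scatter-reduction
analysis on a long table of per-member, per-method parameter values. The
first part ("averaged deviation from the mean before/after excluding
methods") admits more than one reading; we define it as: per ensemble
member, the relative SD of the parameter across methods, averaged over
members — the reading in which excluding two methods changes the value
member-by-member. The second part is the
relative SD across members per method, before and after dropping
MAD-flagged members plus any caller-listed members (segmentations with
visible surface artifacts are a visual judgement and are passed in
explicitly, never auto-detected).

The shipped reference tables (`reference_split_table()`,
`reference_reduction_table()`) are regression fixtures. Two documented
quirks: recomputing the printed reductions from the printed rounded
before/after pairs differs by exactly ±1 in four cells (the source
rounded from unrounded internals); and one printed bc4 column sums to
0.705 rather than 1 — its outlet-5 cell of 0.033 is confirmed by the
printed −1055 deviation, so the fixture keeps the printed values and the
tests document the inconsistency instead of "fixing" it.

## Synthetic data: what it does and does not emulate

* **`make_tree()`** builds deterministic bifurcating trees whose leaves
  carry circular sections with the requested radii; internal radii follow
  the Murray closure $r_p^3 = \sum r_c^3$ and segment lengths are ten
  radii, a typical branch length-to-caliber ratio.
* **`make_ensemble()`** emulates inter-operator segmentation variability
  with three knobs: a global over/under-segmentation factor per member
  (default range 0.92–1.10, bracketing the ±10 % caliber disagreement
  typical of manual lumen segmentation), per-segment radius jitter
  (relative SD 3 %), and smooth radial boundary roughness (Fourier modes
  2–6, 2 % relative amplitude) standing in for the uneven surfaces of
  manual segmentations. One seed, one stream: member 1 is the untouched
  base and a fixed seed reproduces the ensemble bitwise. What it does
  *not* emulate: topological errors (missing branches), neck-specific
  distortion, or any statistical match to a particular patient dataset.
* **`make_phantom()`** produces analytic fields with known metric values
  on structured tube/sphere meshes stored as unstructured cells (volumes
  and areas are assigned analytically, so the mesh tiles the geometry
  exactly). The `prescription` record carries the closed forms:
  rigid rotation → vorticity $2\Omega$; steady Poiseuille → TAWSS
  $4\mu\bar V/R$, OVI 0, KER 1; zero-mean pulsatile → OVI 0.5; the
  sac-on-pipe phantom prescribes KER $= \rho_V^2$ and nTAWSS directly
  through its speed and WSS ratios. Passing round-trip tests on these
  phantoms demonstrates that the metric implementations are correct on
  fields whose answers are known; it does not demonstrate anything about
  solver accuracy, turbulence-like fluctuations, or real aneurysm
  geometry.

Default problem sizes — a 4 mm tube at radial × azimuthal × axial
resolution 8 × 16 × 8 with 17 time samples per cycle, ensembles of 7–10
members, 100 random trees in the property tests — were chosen so every
closed-form check resolves well inside its tolerance while the whole
suite runs in well under a minute; they are the package's test
conditions, and all of them are plain arguments.

## Known limitations

* bc1 is a 0D surrogate; it is suitable for studying the *structure* of
  resistance-governed splits, not for reproducing any particular 3D
  zero-pressure result.
* The raytraced area is star-shaped with respect to the anchor; a border
  so convoluted that parts of the lumen are invisible from the centerline
  point is silently truncated to the visible region (an error is raised
  only when a ray misses the border entirely, i.e. the anchor is outside).
* `wss_from_velocity()` assumes the mesh resolves the near-wall region
  with at least one interior point ring; it is first-order at curved
  walls.
* Mean vorticity is reported as the mean *magnitude* of the vorticity
  vector. Which scalar reduction the field's literature means by
  "mean ω" is not always stated; magnitude is the common choice and the
  one implemented.
* Fields are read and written in the package's documented plain-text
  directory schema, not in solver-native binary formats; converting a
  solver export is the caller's one-off step.
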