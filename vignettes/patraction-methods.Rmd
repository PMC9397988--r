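---
title: "Modelling posteroanterior lumbar traction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling posteroanterior lumbar traction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model: what is being
simulated, which parameters matter, which numerical choices were made and
why, and what the results do and do not show. All lengths are mm, stresses
MPa, forces N (per mm of out-of-plane thickness): a consistent mm–MPa–N
system.

## The physical scenario

A subject lies supine on an automated massage bed. Under the bed mat, a pair
of rigid semi-cylindrical rollers rises in the posteroanterior direction in
nine discrete traction levels; each level adds exactly 62/9 ≈ 6.9 mm, so the
top level TL9 corresponds to 62 mm of vertical travel. The rollers engage
the lower back under the L2–L4 vertebral span. Because the lumbar spine is
lordotic (anteriorly convex), lifting the lumbar soft tissue distracts the
vertebral bodies and produces tensile stresses in the intervertebral discs
that counteract their habitual compressive loading. The quantities of
interest are the per-disc averages of von Mises stress and equivalent strain
as a function of traction level and of BMI class, the BMI-dependent load
shielding by subcutaneous fat, and the margin against published disc damage
thresholds (ultimate stress 2.94 MPa, ultimate tensile strain 21.3 %).

## The synthetic phantom

No subject geometry is shipped; `phantom_spec()` + `build_phantom()`
generate a parametric stand-in for a segmented mid-sagittal section:

* a lordotic base curve `g(x) = depth · sin²(π (x − x₀)/span)`, C¹ at the
  span edges (default depth 25 mm over a 250 mm span — mid-range textbook
  lumbar lordosis; no subject anatomy is published for the reference
  scenario);
* an inner laminate stacked anteriorly from the posterior soft-tissue
  surface: soft tissue (15 mm), paraspinal muscle (30 mm), epidural fat
  (5 mm), CSF (3 mm), cord/dura (8 mm), the vertebral column
  (35 mm deep; seven vertebrae of 30 mm alternating with six 10 mm discs,
  T12 … S), and an anterior soft-tissue layer (15 mm) whose face carries the
  fixed-end boundary condition;
* posterior offset bands following the **true normal offset** of the body
  surface: subcutaneous fat (13/26/52/86 mm by BMI class), skin (1 mm), and
  the bed mat (10 mm, resting 0.1 mm below the skin).

Fat dilation (`dilate_fat()`) reproduces, parametrically, the image-based
procedure of merging fat with skin, dilating isometrically, and recovering
the skin: only the fat and skin bands move (along the normals of the
original surface), every interior vertex is bit-identical, and the operation
composes exactly. A curvature guard rejects offsets beyond the concave-side
curvature radius of the lordosis, naming the offending location.

Because every tissue interface is either a vertical shift or a normal offset
of the base curve, the mesh (`mesh_geometry()`) is generated as a mapped
structured grid whose rows lie exactly on the interfaces and whose columns
conform to the vertebra/disc segmentation; cells are split into triangles
and promoted to straight-sided 6-node quadratic elements. The mesher is
deterministic, conforming by construction, resolves every region boundary
exactly, and conserves region areas to much better than 0.5 % of the
analytic (parallel-curve) areas. At the default 5 mm target edge the normal
phantom has ≈3 500 elements and ≈7 300 nodes; each disc ROI carries ≈75
nodes.

What the phantom does **not** emulate: subject-specific anatomy (vertebral
shape, facet joints, posterior elements), 3D geometry, the annulus/nucleus
substructure of the disc, or gravity preload. Conclusions transfer to real
anatomy only at the level of trends.

## Materials

Each tissue is isotropic linear elastic (the reference setting): skin
160 MPa, muscle 7, soft tissue 23.5, vertebrae 17 000, disc 17, fat 3,
cord/dura 10, all at ν = 0.49; CSF is specified by bulk modulus
K = 2250 MPa at ν = 0.499, converted via E = 3K(1 − 2ν) = 13.5 MPa and
capped at ν = 0.495 in the solver for conditioning (disc ROI results are
insensitive to the cap at this scale). Densities are stored for completeness
but unused by the quasi-static solver. The mat is not specified by the
reference; the default is a firm foam (E = 5 MPa, ν = 0.3, 10 mm),
config-exposed. Six-node triangles avoid the volumetric locking that linear
triangles exhibit at ν = 0.49.

## Actuator and contact

The displacement schedule is exactly `tl × 62/9` so the printed 62 mm
maximum is honoured (nine increments of "approximately 6.9 mm"). The two
active front rollers (radius 25 mm, config-exposed) sit at the quarter
points of the L2–L4 span. The rest position is calibrated so that the
roller surface — the flank can touch a curved mat before the apex — first
touches the mat underside after exactly `initial_clearance_mm` of travel;
the default clearance of four level increments (4 × 62/9 ≈ 27.6 mm) makes
the roller–mat–skin chain engage between TL4 and TL5, reproducing the
observed near-zero disc response for TL4 and below.

Contact is frictionless with a hard (non-penetration) normal law,
approximated by a penalty with a C¹ regularization band of 0.005 mm so that
marginal nodes do not flicker across the contact boundary during Newton
iterations. Three mat models are available (`solver_control(mat_model=)`):

* **`"cushion"` (default)** — the mat rides on the rollers as a compliant
  Winkler layer: the effective roller radius grows by the mat thickness plus
  rest clearance, and the interface stiffness is the series combination of
  the penalty and the mat's through-thickness constrained stiffness
  (E_c/t ≈ 0.67 MPa/mm). The meshed mat body is a geometric spectator. This
  keeps the mat's dominant mechanical role — series compliance between
  roller and skin — while making the quasi-static solve robust.
* **`"deformable"`** — the mat is a meshed elastic strip with the two
  contact pairs of the reference setup (rollers/mat underside, mat
  top/skin). A frictionless soft strip sandwiched between rigid rollers and
  the back has nearly neutral tangential modes: membrane tension
  contributes ≈T/R of stabilizing stiffness against ≈F/R of destabilizing
  load term, and the two nearly cancel. A dynamic-explicit integrator rides
  through such modes with inertia; a quasi-static Newton solver limit-cycles
  on them. The mode is retained for exploration below contact onset and for
  transparency about the architecture choice.
* **`"none"`** — bare rigid rollers against the skin, for fast tests.

The penalty bookkeeping separates the *physical* cushion deflection from the
*numerical* penetration of the hard part; the latter stays below the
0.02 mm budget (peaking at 0.017 mm on the thinnest-fat phantom).

## Solver

`solve_traction()` performs a quasi-static incremental solve: the rollers
rise by half a traction level per increment (18 increments to TL9; adaptive
bisection on non-convergence or element inversion), and a Newton iteration
with a backtracking line search resolves the contact state of each
increment. Kinematics are updated-Lagrangian: geometry advances each
increment, strain increments are small-strain on the current configuration,
and the tangent carries the initial-stress (geometric) stiffness assembled
from the accumulated stresses — without it the membrane tension that builds
along the stretched column and skin is not felt by the iteration matrix.
The roller contact uses the consistent tangent including the curvature term
−(F/r)(I − nnᵀ), which restores quadratic convergence (residuals drop to
~10⁻¹⁰ of the external force near equilibrium); an LU fallback covers
transiently indefinite tangents. Convergence demands an out-of-balance force
below 10⁻⁶ of the external contact force. A strict small-strain single-step
mode (`kinematics = "linear"`) exists for verification against linear closed
forms. An optional stiffness-proportional stabilization (`stabilization`)
can regularize quasi-static limit points, but is off by default: it lets the
solver ride through local fat-crush snaps into states whose strains the
small-strain kinematics cannot represent (inverted elements), whereas
adaptive bisection finds the physical path.

The linear solver is CHOLMOD's sparse Cholesky on the reduced symmetric
system with deterministic ordering; the whole pipeline contains no random
numbers, so repeated runs are bit-identical.

Boundary conditions follow the reference setup: zero translation
(rotation-free) on the anterior-most 10 % of the cranial and caudal end
faces, plus clamping of the mat ends to the bed frame. Gravity/body-weight
preload is not applied.

## Field recovery and summary measures

Stresses and strains are accumulated at the quadrature points, extrapolated
linearly to element nodes and averaged area-weighted across adjacent
elements. Disc ROI averages use **region-restricted** recovery (only
elements of that disc contribute to its nodes), so the stiff vertebral
neighbours do not smear into the ROI — the choice corresponds to
element-restricted nodal extrapolation in commercial post-processors. The
von Mises stress uses the full plane-strain tensor including
σ_zz = ν(σ_xx + σ_yy); the strain scalar is the von-Mises-equivalent
(deviatoric) strain √(2/3 e:e), consistent with the default equivalent
measures of commercial codes. For an isotropic material the two are
proportional through 3G, which the tests exploit as a consistency check
(the published tables show the same ratio: 1.686 MPa / 0.0923 ≈ 18 ≈ 3G for
E = 17, ν = 0.49).

The shielding comparison `percent_reduction()` is
`100 (1 − mean_other/mean_reference)` with the mean over all six discs and
the post-onset levels TL5–TL9. The aggregation convention is anchored
against the published tables: applied to them, severe obese vs normal at TL9
gives ≈79 %, matching the printed headline number.

## Verification

`verify_suite()` runs five analytic problems: a patch test (linear boundary
displacement reproduced to machine precision — exact for straight-sided T6
with 3-point quadrature), a slender cantilever against Euler–Bernoulli
theory (within 5 % at L/h = 20, ν = 0), rigid-cylinder indentation against
the Hertz line-contact closed forms evaluated at the measured load (contact
half-width and peak pressure within 10 %; nodal forces are converted to
pressure with the consistent quadratic-edge weights, since the raw
force/length ratio oscillates ±33 % between corner and midside nodes), a
dense-solver equivalence check at 10⁻¹⁰ on a small mesh, and an energy
balance (external contact work vs stored strain energy within 1 % in the
dissipation-free linear mode).

## What the default study computes

`run_sweep()` solves each BMI phantom once, incrementally to TL9, and
harvests every level on the way up (≈1.5 min for all four phantoms at the
default 5 mm mesh). The mesh-convergence property test halves the edge
length on the normal phantom and finds disc averages within 5 % at TL7;
at TL9 the finer mesh resolves the local fat crush beyond the small-strain
kinematic limit, so the default resolution is documented as adequate at the
highest level both resolutions complete. Reproducible
findings at the defaults:

* disc responses are zero through TL4 and engage at TL5;
* per-disc stress grows monotonically (and super-linearly) with traction
  level;
* at every post-onset level the aggregated disc stress decreases strictly
  with BMI class: −9.6 % (overweight), −25.3 % (moderate obese), −46.0 %
  (extreme obese) against the normal phantom, identical percentages for
  strain (the 3G proportionality);
* all disc means stay below the damage thresholds (max 2.12 MPa and 12.4 %
  at TL9 vs 2.94 MPa and 21.3 %).

## Known limitations

* **Plane strain confines the fat.** At ν = 0.49 the constrained modulus is
  ≈17× the Young's modulus, so the fat cannot escape laterally as it does
  in 3D. The full-scale study reports ≈14/51/79 % shielding; the phantom
  reproduces the overweight figure (9.6 vs 14) but roughly halves the deeper
  ones. The ordering is robust; the magnitudes are geometry-limited.
* **Membrane tension from the pinned ends.** With both anterior end faces
  held (the reference boundary condition) and ≈34 mm of mid-span lift, the
  nearly rigid vertebral column is stretched axially and the stretch
  concentrates in the six soft discs (≈8–12 % strain, uniform along the
  span). The simulated per-disc profile is therefore flat with slightly
  elevated ends, unlike the roller-local mid-span peak (L2-L3 max, T12-L1
  min) of the 3D study, where this artifact is diluted by the third
  dimension. The published-table ranking checks are unaffected (they test
  the analysis arithmetic on the published values).
* Linear elasticity throughout: no hyperelastic stiffening, no annulus/
  nucleus split, no gravity preload, no horizontal actuator scanning, and
  local fat compression near TL9 approaches what small-strain incremental
  kinematics can represent (the solver bisects increments and reports
  inversion if exceeded).
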