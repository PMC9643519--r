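---
title: "Modeling optic nerve tethering during adduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling optic nerve tethering during adduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The mechanical problem

When the eye rotates toward the nose (adduction) past roughly 26°, the
optic nerve (ON) exhausts its slack and straightens into a taut tether
between the back of the globe and the orbital apex, where nerve and sheath
are rigidly anchored. Further adduction then loads the optic nerve head:
the temporal optic disc, the peripapillary sclera, the lamina cribrosa
(LC), the sheath–sclera junction and the retrolaminar neural tissue. This
package reimplements that analysis as a reusable finite-element pipeline:
regional hyperelastic tissue cards, a parametric adducted eye–nerve
geometry, a quasi-static large-deformation solver with follower pressure
loads (intraocular pressure, IOP, on the vitreous side; intracranial
pressure, ICP, in the CSF sleeve), and a sensitivity grid over published
stiff/compliant tissue-property extremes.

## Constitutive model

Each connective tissue is an isotropic reduced-polynomial (Yeoh-family)
hyperelastic solid,

$$U = \sum_{i=1}^{N} C_{i0}\,(\bar I_1 - 3)^i
    + \sum_{i=1}^{N} \tfrac{1}{D_i}\,(J-1)^{2i},$$

with deviatoric coefficients $C_{i0}$ (MPa), volumetric coefficients $D_i$
(1/MPa), $\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^TF)$ and $J=\det F$. The
packaged card file (`inst/extdata/material_cards.csv`) stores one record
per region and stiffness level; the $C_{30}..C_{60}$ columns are printed at
1000× their value and rescaled by the loader. Across every region the
published $D_1$ implies a bulk-to-shear ratio near 25, i.e. an effective
Poisson ratio of about 0.48 — the same value the neural-tissue card states
explicitly — which corroborates the transcription of the card table.
Where a $D_1$ entry is absent or zero the material is treated as nearly
incompressible through a penalty bulk modulus $\kappa = 1000\,\mu$ with
$\mu = 2C_{10}$ (when $D_1>0$, $\kappa = 2/D_1$). The ON neural tissue is
linearly elastic ($E = 0.001195$ MPa, $\nu = 0.48$) and enters the
large-deformation solver as its exactly equivalent compressible
neo-Hookean card.

Stress is the exact push-forward of the energy ($P = \partial U/\partial
F$, $\sigma = J^{-1}PF^T$) and the Newton tangent is the analytic
$\partial P/\partial F$; both are verified against central finite
differences of the energy in the test suite.

One caution surfaced by the package's own curves: the compliant
peripapillary card has a negative $C_{20}$ and its tangent stiffness
$\partial U/\partial \bar I_1$ dips below zero for $\bar I_1 - 3$ roughly
in $(0.077, 0.21)$ — beyond the strain range the tensile fits covered, but
reachable in a concentrated plane-strain field, where it makes equilibrium
non-unique. The fitted polynomial is therefore trusted only where its
deviatoric tangent stiffness is positive: across the deficient band the
slope is floored at 5% of its small-strain value ($0.05\,C_{10}$), the
energy continued linearly, and the polynomial resumed (shifted for energy
continuity) once it recovers. The card is untouched below the onset, which
lies far above the strains of the stable material cases; without the floor
the softening cases land on solver-detail-dependent equilibrium branches.
A full Maxwell convexification was rejected because these cards are
concave from the origin, so the convex hull would alter the fitted
small-strain response itself.

### The ON composite

The nerve interior is a composite: stiff connective septa (honeycomb)
around soft axon bundles in the histologically observed 9:16
connective:neural area ratio, so the connective volume fraction is
$f = 9/25$. The rule of mixtures
$E_{ON} = f\,E_{Connective} + (1-f)\,E_{Neural}$ is implemented in both
directions: inversion recovers the connective modulus from a whole-nerve
measurement, and the forward direction homogenizes the cross-section
model's nerve interior by mixing the two strain-energy functions with
weight $f$ (a Voigt mixture, which reduces exactly to the scalar rule of
mixtures in the small-strain limit). An explicit honeycomb is only
meaningful in three dimensions and is not built here; the homogenized
interior carries the label `on_homogenized`.

## Geometry

All dimensions are the printed anatomical averages: a 24 mm globe with
scleral thickness 0.4 mm at the equator rising to 1.0 mm at the posterior
pole and thinned to 0.5 mm at the scleral canal rim (linear taper over the
adjacent 1 mm, a profile the source does not specify and which is exposed
in the configuration); an LC cap 1.8 mm across and 0.3 mm thick seated in
the canal with its posterior surface flush with the outer scleral sphere;
a nerve tapering from 4 mm at the globe to 3.5 mm at the apex; a 0.74 mm
sheath separated from the nerve by a 0.59 mm CSF sleeve; and an orbital
apex 41 mm from the globe centre.

The model frame puts the origin at the globe centre, +z toward the apex,
+x nasal, +y superior. The reference configuration is the 26°-adducted
pose in which the nerve has just straightened, taken stress-free (zero
pretension). The angular bookkeeping that positions the disc is the one
genuinely derived quantity: with the medial orbital wall taken parallel to
the sagittal plane, the centre–apex axis sits 22° nasal of the primary
visual axis while 26° of adduction has swung the posterior retina
temporally, so the disc centre lands at
$-(22 + 26 - 17) = -31°$ — temporal of the apex axis — and the posterior
geometric pole a further $17 - 5 = 12°$ temporal of the disc. This
obliquity matters mechanically: the taut nerve pulls the disc nasally and
posteriorly (toward the apex), which is what lets the LC migrate nasally
relative to the globe during further adduction. Scleral zones are
classified peripapillary within 4 mm geodesic of the disc centre, then
anterior (< 60° polar angle from the corneal pole), equatorial (60–120°)
and posterior — the zone bounds are not printed in the source and thirds
by polar angle is the simplest defensible split, exposed in the
configuration.

## Mesh

The analysis mesh is the horizontal cross-section (the hemi-symmetry
plane) built of 6-node quadratic triangles under a plane-strain contract:
scleral ring, LC cap, oblique nerve strip and two sheath strips are
meshed as transfinite patches whose interface nodes are generated from
shared station lists, so patch merging is exact. Midside nodes are placed
on the mapped geometry, so curved boundaries are quadratically resolved.
Density is controlled by two target edge lengths — `fine` (default 0.25 mm)
around the LC/canal/junction zone and `coarse` (default 2.2 mm) far away —
with geometric grading between. The defaults give roughly 1200 elements
and 5400 unknowns, a deliberate desk-scale choice — the coarsest level
whose cross-case ordering structure agrees with the next refinement; the convergence study
(below) quantifies what resolution does to the whole-model stress
measures.

Three-dimensional 10-node tetrahedral meshing is provided for the
spherical-shell primitives (cube-sphere construction, degeneracy-free at
the poles), which carry the solver verification: shell volume against a
quadrature oracle and the pressurized thick-walled sphere against the
closed-form inflation relation. The coupled eye–nerve assembly itself is
a cross-section model; a full 3D assembly with explicit honeycomb is out
of scope here.

Two plane-model artifacts deserve explicit statement. First, a plane
strip cannot carry hoop stress, so an unbalanced ICP in the CSF sleeve
would bow the free sheath span outward — an artifact, since the real
dural tube carries that pressure in hoop tension. The sheath wall is
therefore loaded by ICP on both faces (net zero transverse wall load)
while the nerve surface, the exposed peripapillary annulus and the
translaminar faces keep their one-sided loading. Second, the ring is
hoop-stiffer than a doubly-curved shell patch, so absolute stress levels
are not expected to match a full 3D solve; the sensitivity *orderings*
across material cases are the robust claims, and the quantitative outputs
are reported as scaled-down anchors.

## Boundary conditions and loading

The nerve and sheath are fully fixed at the apex. Adduction is imposed as
a prescribed rigid rotation of every shell node within 60° of the corneal
pole, about the globe centre, +6° beyond the reference pose (the rotation
centre is the fixed globe centre; the globe does not translate). IOP
(15 mmHg normal, 40 mmHg extreme) acts as a follower pressure on the
inner scleral surface including the anterior LC face; ICP (10 normal, 4
extreme) on the CSF sleeve. Pressures convert at 1 mmHg = 133.322 Pa in
the package's mm–MPa–N unit system.

## Solver

Total-Lagrangian displacement formulation, assembled in compiled code
with analytic consistent tangents (material, geometric, and
follower-pressure load stiffness), sparse Cholesky with LU fallback.
Loading advances over ten equal increments of the rotation with pressures
ramped over the first half (a pure-pressure run ramps over the whole
schedule). Newton iterations use a non-monotone acceptance: the full step
is taken unless it inverts an element or grows the residual more than
fifty-fold — the stiff volumetric penalty routinely overshoots on the
first iterate and then converges quadratically, and a monotone line
search turns that into a crawl. Convergence demands a relative residual
of 1e-8, with an absolute floor of 1e-4 of the largest initial increment
unbalance (an order of magnitude tighter than common commercial force
tolerances); the floor only matters where the compliant peripapillary
card's softening band leaves Newton cycling at a mechanically negligible
residual. A failed increment is bisected from the last converged state,
and if cutting alone cannot traverse the softening band the solver
engages automatic stabilization — weak springs (1e-4 of the mean tangent
diagonal, escalating if needed) anchored at each increment's start — and
keeps it for the remainder of the schedule. Runs that never meet an
instability never pay for any of this.

## Reported quantities

Stress heat fields use the von Mises equivalent
($\sqrt{3/2\,\mathrm{dev}\sigma:\mathrm{dev}\sigma}$, reported in kPa);
strain fields use the maximum principal logarithmic (true) strain in
percent — the natural large-deformation measure, and the choice
documented here since the source does not state its strain convention.
Element values are quadrature-point averages of the tensors, with scalars
taken from the averaged tensor. Local summaries follow the 12–16
contiguous-element rule: the mean over `k` (default 14, the window
midpoint) contiguous elements nearest a named landmark, grown
deterministically from the nearest element by always adding the nearest
node-sharing neighbour. The canonical landmarks sit on the temporal side:
the disc/ON junction at the temporal canal rim, the temporal
peripapillary sclera 1.5 mm from the rim, the sheath–sclera junction at
the sheath attachment arc, the retrolaminar nerve just behind the LC, and
the mid-orbital sheath.

LC edge displacement is reported for the temporal LC edge in nasal (+x)
and posterior (+z) micrometres **relative to the rigidly adducted globe**
(the co-rotating frame in which initial and final rigid anterior sclera
coincide). That is the frame of the figure construction the analysis
mirrors and of the clinical OCT literature; it is also the only frame in
which "the LC shifts nasally" is kinematically possible while the
posterior globe swings temporally. The orbit-frame components remain
available (`frame = "orbit"`).

## The case grid as synthetic data

The generator of study conditions is the case matrix itself: stiff (95th
percentile) versus compliant (5th percentile) cards in the posterior
sclera, peripapillary sclera and sheath — cases A–D with stiff posterior
sclera, E–H compliant, each block cycling (peripapillary, sheath) through
(stiff, stiff), (stiff, compliant), (compliant, stiff), (compliant,
compliant) — plus the all-average case, pressure scenarios
(±tethering × normal/extreme translaminar gradient) and ON-stiffness
variants on the least favorable base (case B). All runs in a grid share
one mesh, so differences are purely material. What these synthetic
conditions do not emulate: anatomical variation (one average geometry),
anisotropy, viscoelasticity and dynamic saccades, orbital fat and muscle
support, globe translation — so passing the grid's property tests speaks
to the quasi-static, isotropic, average-anatomy idealization only.

## Numerical choices and limitations

* Quadrature: 3-point (triangles) and 4-point (tetrahedra) rules, exact
  for the quadratic stiffness integrand on straight-sided elements.
* Near-incompressibility is handled by the penalty alone; quadratic
  displacement elements tolerate the ~0.48 effective Poisson ratio
  without selective integration.
* Summaries depend on landmark placement by construction; landmarks are
  fixed by the geometry, not chosen per case.
* Absolute kPa/μm values from the cross-section model sit well below the
  published 3D ones (the plane ring is hoop-stiff and the mesh is three
  orders coarser); orderings across cases, the LC displacement signs, and
  the additivity of pressure and tethering effects are the reproducible
  content at this scale.
* The convergence study tracks volume-weighted mean and maximum von Mises
  over the whole model across a density ladder; the two finest levels
  agree to a few percent on the mean, while pointwise maxima at reentrant
  corners (canal rim, sheath attachment) sharpen under refinement as
  expected for corner singularities.
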