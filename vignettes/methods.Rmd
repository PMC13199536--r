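---
title: "Methods: from QCT phantoms to reproducibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from QCT phantoms to reproducibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

vertebraFE asks a practical question of CT-based vertebral biomechanics: when
different people (or the same person on different days) segment the same
vertebra from a quantitative CT scan, how much do the geometric descriptions
differ, and how much of that difference propagates into the mechanical
predictions of a subject-specific finite-element (FE) model? The package
implements the whole chain — synthetic ground-truth data, densitometric
calibration, segmentation agreement metrics, voxel-based FE with
elasto-plastic bone, mechanical outcome metrics, and precision statistics —
so the propagation can be studied end to end under controlled conditions.

This vignette explains the models and the choices behind them. It states no
empirical result that the test suite and the acceptance script do not
themselves compute.

## The synthetic study

Clinical QCT of metastatic patients cannot be redistributed, so the package
generates its own study material. A `vertebra_phantom` is an elliptic
cylinder (default semi-axes 20 and 15 mm, height 30 mm) with a cosine waist
concavity (default amplitude 0.15) standing in for the concave vertebral
body wall, an optional rigid tilt, and optional spherical lytic lesions
whose density is multiplied by a factor in `[0, 1)`. The tissue is uniform
trabecular-equivalent bone at rho_QCT = 0.18 g/cm^3 by default — a mid-range
vertebral trabecular density. Because the solid is analytic, the phantom
carries closed-form ground truth: height, mean cross-sectional area, bone
mineral content, and six anatomical landmarks.

The `scanner_model` renders the phantom into HU through an affine map
(default 1000 HU per g/cm^3, intercept -20 HU), adds Gaussian point-spread
blur (default 0.3 mm SD) and Gaussian noise (default 15 HU SD), and draws
the five-rod in-line calibration phantom — 15 mm diameter rods at 0.00 to
0.20 g/cm^3 in 0.05 steps — beneath the vertebra. The default voxel size is
0.60 mm isotropic, the protocol resolution the package emulates. Defaults
for noise and blur are plausible clinical values chosen once; the emulated
scanning protocol does not fix them.

Simulated operators perturb the true mask additively in signed-distance
space, which guarantees valid (hole-free, single-component) masks and gives
one interpretable amplitude per error source:

* a global erode/dilate offset drawn once per segmentation (systematic
  over/under-segmentation);
* a smooth correlated surface displacement (a Gaussian random field with a
  correlation length, emulating locally consistent boundary interpretation);
* an independent per-slice offset (slice-by-slice contouring);
* a Bernoulli inclusion of an osteophyte-like half-ellipsoid bump — the
  ambiguous-feature mechanism that produces worst-case Hausdorff distances
  between operators.

The signed distance is computed by an exact Euclidean distance transform
(Felzenszwalb's separable algorithm, compiled code) and corrected by half a
voxel so that boundary voxels sit at ±spacing/2; sub-voxel perturbations
then act on the boundary layer rather than being quantised away. The
`intra` and `inter` presets differ only in amplitude; they are calibration
knobs of the generator — the emulated study does not quantify per-operator
behaviour, so the presets were set once to land the Dice range reported for
manual vertebral segmentation (about 0.97–0.99 intra, 0.92–0.98 inter) and
were not revisited. All randomness flows from one master seed through a
documented splitting scheme (per vertebra, operator, repeat), so any single
artefact is regenerable in isolation.

What the generator does **not** emulate: cortical/trabecular
microarchitecture, a distinct cortical shell or endplate, surrounding soft
tissue (background density is zero), beam hardening and scatter, multiple
vertebral levels. Passing tests therefore demonstrate the correctness and
sensitivity of the *pipeline*, not clinical-level realism of any particular
variability magnitude.

## Calibration

The five prismatic ROIs (square section of half the rod diameter, i.e.
7.5 mm for protocol rods, full rod length) yield mean HU values; ordinary
least squares of known density on measured HU gives the scan-specific
calibration. The regression direction is density-on-HU because that is the
direction the equation is used in; at zero noise both directions coincide.
Calibrated densities below zero are clamped to zero: the material power
laws are undefined for negative density and lytic tissue is modelled as
near-zero density.

## Model building

Meshing is a structured voxel decomposition: the mask is resampled to cubes
of the element size (default 1 mm, honouring the maximum-element-size
protocol; a cube is kept when its centre is inside the mask), each cube is
split into the six Kuhn tetrahedra, and elements are promoted to
10-node quadratic tetrahedra through shared edge midpoints. The choice is
deliberate: it is deterministic, dependency-free, conserves volume exactly,
and all elements of a given split position are translates of one another,
which lets the solver precompute one strain-displacement matrix set per
element type. The cost is a staircase surface instead of a smooth conforming
one — a known deviation from commercial meshers, visible mainly as a few
percent of extra compliance near boundaries.

Anatomical alignment fits a plane to each landmark triple (most anterior
point plus the two posterior corners, on each endplate), takes the bisector
plane as the model transverse plane, and puts the origin at the superior
landmark centroid. Landmarking on masks picks, within an angular sector
about each target azimuth, the surface voxels at the extreme axial level
and averages them sub-voxel. In study runs all five masks of a vertebra are
aligned with the *phantom's* analytic landmarks: the emulated protocol had
a single operator place landmarks precisely to minimise rotational
variability (reported SDs a fraction of a degree), and reusing one landmark
set reproduces that design decision.

Endplate node sets anchor on the anatomical endplate planes of the frame
(superior plane at z = 0, inferior at the landmark distance), with a band
of 0.3 element sizes. Anchoring on anatomy rather than on mesh extremes
matters: an over-segmented mask carries a rind of near-zero-density
elements, and a band at the mesh extreme would feed the whole load through
that soft rind in series, collapsing the apparent stiffness by an order of
magnitude. With anatomical anchoring the rind hangs outside the load path,
as it does when a human labels the endplate. Without a frame (e.g. bar
verification models) the bands fall back to the median of per-column
extreme levels, which is robust to single-column caps and pits.

Element density is the mean of the calibrated field over a fixed 10-point
interior barycentric lattice per element (trilinear image interpolation);
for a linear field this equals the centroid value exactly. Material mapping
follows the trabecular vertebral laws: rho_QCT is treated as ash density,
`rho_app = rho_QCT / 0.6`, `E = 4730 rho_app^1.56` MPa,
`sigma_y1 = 21.7 rho_app^1.52` MPa, `E_py = 0.05 E`. The yield-stress unit
is MPa (a stress), whatever a stray unit annotation elsewhere may suggest.
Apparent densities below 0.01 g/cm^3 are floored there so fully lytic
elements keep a small positive stiffness and the system stays definite. The
default maps material from the element-mean density (rather than averaging
E over density samples); the two variants differ only through the curvature
of the power law within an element.

## The FE solver

Small-strain, geometrically linear quadratic tetrahedra with 4-point Gauss
quadrature; J2 (von Mises) plasticity with linear isotropic hardening,
integrated by radial return. The hardening modulus is chosen as
`H = E E_py / (E - E_py)` so the uniaxial elasto-plastic tangent equals
`E_py` — the 95%-reduced post-yield modulus. The algorithmically consistent
tangent is used throughout, and a backtracking line search damps Newton
steps when the plastic active set chatters. Loading is displacement
control: the cranial endplate nodes receive an axial displacement equal to
1.9% of the body height in equal increments (default 10), the caudal nodes
are fixed. Poisson's ratio is not a protocol constant; the default is 0.3,
the standard homogenised-bone value, and it is configuration-exposed.
Cranial transverse degrees of freedom are free by default ("uniaxial
compression" read as axial-only prescription); a `tied` variant bonds both
endplates and a `frictionless` variant (axial-only constraints at both ends
plus minimal rigid-body restraints) exists because the closed-form bar
solutions used for verification require it. Convergence demands a residual
norm at 1e-8 of the reaction norm; non-convergence bisects the increment.
The linear systems are solved by supernodal sparse Cholesky (CHOLMOD via
Matrix) with the symbolic factorisation reused across iterations, and the
factor itself reused while the model is still entirely elastic. Identical
results are obtained regardless of node ordering because the assembled
system, not the ordering, defines the solution up to solver tolerance.

Nodal strain tensors are evaluated from the shape-function gradients at
element nodes and averaged over adjacent elements (equal volumes on this
mesh); principal strains come from the closed-form symmetric eigensolution.

## Mechanical metrics

`F_U` is the axial reaction at the final (1.9%) increment — the protocol
reads the force at imposed deformation, not a curve maximum; under
monotonic hardening the two coincide anyway. `K` is the least-squares slope
of force against displacement over the linear range, operationalised as the
increments before any Gauss point yields; for a purely elastic run this
equals the secant exactly, and if yielding begins within the first
increment the first-increment secant is used with a warning.
`sigma_U = F_U / CSA` and `E_APP = K Hm / CSA` normalise by the mean
cross-sectional area (computed from the mask, dropping the top and bottom
10% of occupied slices as endplate bands — the protocol excludes endplates
without stating the extent, so the fraction is configurable) and by the
height between endplate centroids. Strain frequency tables use nodes in the
central 50% of the body height, binned with fixed edges cut at |strain| =
0.04, the region of interest for vertebral strain distributions. The local
probes are a 3 x 3 x 3 lattice of 2 mm-radius spheres placed at ±25% of the
body semi-extents about the body centre — the protocol fixes the count,
radius, and relative, frame-consistent placement but not the coordinates,
so the offsets are a package choice. Probes protruding from the body are
flagged, never dropped.

## Precision statistics

Per vertebra and metric: mean, SD, and CV = SD/m with the sample (n-1) SD —
the small-sample convention of the precision literature; across vertebrae
the precision error PE is the RMS of the CVs. The absolute relative
difference of a pair is scaled by the pair mean (so it is symmetric), in
percent; for n = 2 the identity CV = ARD/(100 sqrt(2)) holds and is tested.
Intra- and inter-operator means are compared per metric with a paired
two-sided t-test at 0.05, with Shapiro normality of the differences and an
F-test of variance equality reported as flags — the checks never silently
replace the test, because the emulated protocol states that checks were
performed but not what would have replaced the t-test. Zero-variance
differences are flagged degenerate instead of producing an undefined
statistic. The SD(geometric) versus CV(mechanical) regressions are ordinary
least squares with the slope t-test p-value, labelled exploratory; no
multiple-testing correction is applied by default (matching the per-metric
0.05 convention), and a Holm option is a one-liner away in user code.

## Problem sizes and test design

The verification and acceptance suites run at deliberate desk scale, chosen
once as the package's own testing conditions: bar models a few elements
across for closed-form checks; phantoms of 9 x 7 x 14 mm semi-axes/height at
1 mm voxels and 2 mm elements for pipeline-level Monte-Carlo checks (about
2,500 elements, 13,000 degrees of freedom per solve). The Monte-Carlo
ordering and planted-relation checks run the mechanical stage in its
elastic configuration with few increments: the orderings under test are
geometric in origin, and the elasto-plastic path is verified separately
against closed forms. Protocol-scale geometry (0.6 mm voxels, 1 mm
elements, full-size body) is exercised where it is cheap — calibration,
geometry, BMC — not in repeated solves. Consequences to keep in mind: CV
and PE magnitudes from the small synthetic studies are larger than
clinical values (small bodies have high surface-to-volume ratios, so the
same boundary noise moves volume fractions more), and only orderings and
planted relations, not magnitudes, are asserted.

## Numerical choices and degenerate inputs

Masks are compared after the 3 mm median smoothing by default, matching the
pipeline order (smoothing precedes everything downstream); a flag disables
it. Surface distances are measured between boundary voxel centres — the
definition is voxel-based, not mesh-based — and the Hausdorff distance is
the exact maximum, not a percentile. RVD is asymmetric by definition (the
reference volume is the denominator); in pairwise summaries the second
member of each pair is the reference, and the ordering is documented.
Degenerate inputs error loudly: empty masks, both-empty Dice, zero-mean CV,
zero-variance calibration, probes sampling no nodes, lesions leaving the
body, meshes with a missing element type.

## Known limitations

Uniform-density phantoms cannot separate density-sampling variability from
geometric variability (real bone adds the former). The staircase mesh makes
surface strains noisier than a conforming mesh would; probe averages
blunt this deliberately. The operator model is additive and isotropic in
signed-distance space — real operators err anisotropically (more along the
scan axis) and systematically at specific anatomy. The elastic
configuration used in the cheap Monte-Carlo checks understates plastic
redistribution effects on F_U variability. None of these affect the
closed-form verifications, which are exact.
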