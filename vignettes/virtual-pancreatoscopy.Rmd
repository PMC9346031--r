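---
title: "Virtual pancreatoscopy: methods and design notes"
author: "DuctScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual pancreatoscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DuctScope)
```

## The problem

The main pancreatic duct is a thin, fluid-filled (hypodense) tube embedded
in contrast-enhanced parenchyma. In abdominal CT at 1.5--2.5 mm slice
thickness it spans only about 3--5 voxels across its diameter, which makes
direct segmentation unstable: level-set and graph methods need more voxels
than that to represent a stable boundary. DuctScope implements a
segmentation strategy built for exactly this regime. The user supplies only
an ordered set of landmarks -- at minimum the duct head and tail -- and the
pipeline runs in four stages:

1. **Tubularity map.** A multiscale Hessian line filter turns the CT image
   $I$ into a vesselness map $V \in [0,1]$ that is high inside dark
   tube-like structures.
2. **Optimal-path centerline.** The centerline is the curve minimizing
   $\int_0^1 (1 - V(C(t)))\,|C'(t)|\,dt$ subject to passing through the
   landmarks $P_0, \dots, P_{N-1}$. By Bellman's principle of optimality
   the constrained problem splits into independent sections between
   consecutive landmarks, each solved exactly on the voxel graph by
   Dijkstra's algorithm.
3. **Super-resolved lumen segmentation.** A region of interest around the
   centerline is refined by an odd factor $c$ (default 5, so the ROI grows
   125-fold) with trilinear interpolation. A seed map $K$ marks the
   rasterized centerline as known lumen (label 1) and everything farther
   than $r = 10$ mm from it as known exterior (label 2). Every remaining
   voxel is assigned the label of the seed reachable with minimal
   accumulated intensity-difference cost $\sum_i |I(q_{i+1}) - I(q_i)|$
   over Moore-adjacency paths -- a seeded geodesic classification solved
   with one multi-source Dijkstra sweep per label class.
4. **Surface geometry.** The lumen mask is isosurfaced; per-vertex Gaussian
   curvature (angle deficit over mixed Voronoi area) is attached so nodules
   and cysts stand out as high-magnitude patches; a fly-through camera path
   is exported along the centerline spline with tangent view directions and
   parallel-transported up vectors.

## Coordinate conventions

All physical coordinates are LPS millimetres; voxel indices are 0-based
with the voxel-centre convention, so voxel $(i,j,k)$ sits at
`origin + direction %*% (spacing * c(i,j,k))`. NIfTI affines (RAS) and
Slicer `.fcsv` fiducials (RAS) are sign-flipped on load; `.fcsv` headers
that explicitly declare LPS are honoured. Non-axis-aligned direction
matrices are accepted with a warning; every distance in the pipeline is
computed in physical coordinates, so correctness does not depend on
axis alignment.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scalesMm` | 1, 1.5, 2, 3 | Gaussian scales of the Hessian filter (mm). Cover the expected duct radius range; responses are $\sigma^2$-normalized and maximized over scales. |
| `alpha`, `beta` | 0.5, 0.5 | plate- and blob-discrimination weights of the line filter (dimensionless, canonical values). |
| `gamma` | auto | structure-to-noise weight; "auto" resolves per scale to half the maximum Hessian Frobenius norm. |
| `polarity` | `dark_tube` | the duct is hypodense; the filter's eigenvalue sign convention (not the image) is flipped, keeping original intensities available downstream. |
| `weightFloor` | 1e-6 | lower bound on centerline edge weights; keeps shortest paths well defined where $V = 1$ and biases exact cost ties toward geometrically shorter paths. |
| `factor` | 5 | odd per-axis super-resolution factor; odd so every original voxel centre coincides with a subvoxel centre. |
| `seedRadiusMm` | 10 | exterior-seed radius $r$ (mm, physical distance honouring anisotropic spacing). |
| `roiMarginMm` | $r + 5$ | ROI dilation; must exceed $r$ or no exterior seeds exist in the ROI (a configuration error says so). |
| `connectivity` | 26 | Moore neighbourhood used by the propagation (and centerline graph). |
| `smoothSigmaMm` | 1 subvoxel | Gaussian pre-smoothing of the mask before isosurfacing, to suppress staircase curvature artifacts. |

## Numerical and design choices

**Edge weights of the centerline graph.** The continuous integrand
$(1 - V)\,|C'|$ is discretized per edge as
$\max(\text{floor},\, 1 - (V(p)+V(q))/2)\cdot\|x_p - x_q\|$ with physical,
anisotropic edge lengths. Fiducials snap to the nearest voxel centre
(optional snapping to the best-vesselness voxel within a radius exists but
is off by default). Dijkstra tie-breaking is by lexicographic voxel index,
so output is deterministic. By default the graph is restricted to the
fiducial bounding box dilated 20 mm -- a pure optimization, disable-able
with `bboxMarginMm = Inf`.

**Sections and tangents.** Sections between consecutive landmarks are
solved independently and concatenated; the curve is only piecewise smooth,
so tangents are refused at section joints unless the caller opts into the
one-sided difference. Interior tangents are central differences; endpoints
one-sided.

**Trilinear as the convex kernel.** The super-resolution kernel must be
convex (outputs within the local min/max of the 8 enclosing samples) so the
refined image introduces no overshoots near the faint duct boundary;
trilinear interpolation is the minimal such kernel on a 3D grid, and cubic
kernels are excluded precisely because they overshoot. The output grid is
$n \cdot c$ per axis (each voxel subdivides into $c^3$ subvoxels; origin
shifts by $s(1 - 1/c)/2$), which keeps the "125 times larger" arithmetic
exact for $c = 5$; beyond the outermost original centres values use
clamped (nearest) extension. The subvoxel-centre decomposition is done in
integer arithmetic so original values are reproduced bit-exactly at
original centres.

**Seed geometry.** The exterior rule $\min_y |x - y| > r$ is evaluated
against the centerline polyline with an exact point-to-segment distance in
physical coordinates (equivalent to, and sharper than, a distance transform
of the rasterized centerline; anisotropic spacing is handled for free).
Label 1 covers voxels within half a subvoxel diagonal of the polyline.

**Propagation cost and ties.** Step costs are pure intensity differences --
no spatial length factor -- so the "distance" is intensity-geodesic, unlike
the length-weighted centerline cost. Intensities are min-max normalized
over the ROI, making each step cost lie in $[0,1]$ and the labeling
invariant to positive affine rescaling. At exact cost ties label 1 wins:
centerline evidence is the stronger prior, and the rule makes output
deterministic. The classification runs as two multi-source Dijkstra sweeps
(one per seed class) and compares the two distance fields, which realizes
the per-voxel argmin exactly, including ties.

**Restricted propagation.** The pipeline restricts the propagation graph to
the undetermined region plus a one-voxel shell of exterior seeds. Any path
from an exterior seed can be shortened to start at the last exterior voxel
it visits, which lies in that shell, so exterior distances are unchanged;
a lumen-seed path through the deep exterior implies its cost already
exceeds (or equals) the exterior distance, so labels can differ only in
exact-tie corridors of constant intensity, which noisy data does not
produce. `propagateLabels()` itself defaults to the unrestricted, always
exact graph; `runPipeline()` enables the restriction for speed.

**Mask post-processing.** The largest 26-connected component is kept
(stray same-intensity pockets far from the duct are discarded -- the
rasterized centerline seeds always belong to the kept component), enclosed
cavities are filled (the duct lumen is simply connected; cavities are noise
artifacts), and the mask is majority-vote downsampled to the original grid:
an original voxel is lumen iff more than half of its $c^3$ subvoxels are
($c$ odd, so no vote ties).

**Isosurfacing.** Marching tetrahedra on the consistent Kuhn 6-tetrahedra
cube split, after zero-padding by one voxel (surfaces touching the grid
boundary still close) and Gaussian pre-smoothing. The Kuhn split is
identical across the lattice, so shared cube faces triangulate identically
and the mesh is watertight; triangles are oriented from inside to outside
at emission time. Smoothing a thin noisy mask can pinch off small interior
cavity shells in the continuous field even when the voxel mask is one
component, so only the largest shell (the outer lumen wall) is kept by
default. On noisy data the wall can still acquire a handle (genus > 0);
the discrete Gauss--Bonnet identity then gives $2\pi\chi$ rather than
$4\pi$, which the curvature machinery handles transparently.

**Curvature.** Angle deficit over Meyer's mixed Voronoi area (with the
obtuse-triangle correction). The mixed areas tile each triangle exactly, so
the total deficit of a closed mesh satisfies discrete Gauss--Bonnet
*identically* -- the test suite asserts $4\pi$ to $10^{-6}$ on genus-0
meshes -- and per-vertex values converge to the true curvature (on a
subdivided icosphere of radius $R$ they sit within a fraction of a percent
of $1/R^2$). Quadric fitting was rejected because it satisfies no such
exact identity and would leave the tests without a sharp oracle.

**Camera path.** The centerline is spline-resampled (natural cubic,
componentwise in arc length, then reparameterized to uniform arc-length
steps with endpoints preserved exactly). Up vectors are carried by
double-reflection parallel transport from an initial up orthogonal to the
first tangent; a fixed world up would flip the camera roll at vertical
tangents.

## The phantom: what it emulates and what it does not

`generatePhantom()` builds a CT-like block: darker background, a brighter
parenchyma slab inset from the faces, and a hypodense tube swept along a
spline with known radius. Rasterization is anti-aliased (3x supersampling,
box-averaged), so boundary voxels get fractional intensities -- the
partial-volume effect that motivates super-resolution -- then the image is
blurred and corrupted with seeded Gaussian noise. Ground truth (tube
indicator at voxel centres, dense centerline, head/tail fiducials) is
exact and independent of noise and blur.

The `realistic` preset fixes the study conditions: grid 48 x 48 x 36 at
(0.8, 0.8, 1.5) mm, duct radius 1.5 mm (3.75 voxels across in-plane),
parenchyma/duct contrast 70 HU, noise sigma 10 HU, blur 0.8 mm, and a
curved four-control-point path about 42 mm long. The `easy` preset is a
straight 2 mm duct on an isotropic 1 mm grid with no noise, for exact
geometric checks. In both presets the duct axis is deliberately placed
off-lattice: an axis through voxel centres with an integer radius puts an
entire ring of voxels at distance exactly $r$, a measure-zero coincidence
of the discretization that no real scan exhibits and that would make the
ground-truth mask ambiguous at the boundary.

HU values are configuration, not physics: the phantom has no beam
hardening, no reconstruction kernel, no anatomy around the duct, and its
noise is white Gaussian rather than correlated CT noise. Passing the
phantom tests therefore demonstrates the geometric and algorithmic
correctness of the pipeline under realistic size, contrast, anisotropy and
noise-amplitude conditions -- not clinical performance on patient data,
which additionally faces duct-like distractors (vessels, bowel) and
annotation uncertainty.

## Problem sizes and runtime posture

The bundled analyses are sized for a laptop-class single core: the
realistic phantom ROI refines to roughly 10 million subvoxels, on which the
two propagation sweeps, the exact polyline distance field and the surface
extraction each take seconds. Test-suite oracles run on deliberately tiny
instances (up to 6 x 6 x 6 for path costs, 5 x 5 x 3 for label
propagation) where brute-force enumeration in plain R is feasible; the
brute-force results are compared exactly, not within loose tolerances.
Stage runtimes are logged in the pipeline report but never asserted in
tests, since they are hardware-dependent.

## Known limitations

- The method is interactive by design: it needs at least head and tail
  landmarks and does not detect ducts automatically.
- Vesselness is computed at original resolution; it feeds only the
  centerline stage. Ducts thinner than the smallest filter scale at very
  low contrast may yield weak ridges and wandering centerlines.
- The intensity-geodesic cost has no boundary-length regularization, so a
  low-contrast gap in the duct wall can leak; the exterior-seed radius
  bounds how far.
- On noisy data the reconstructed wall can be genus > 0 (handles); no
  topology-correcting surgery is attempted beyond cavity filling and
  largest-shell selection.
- DICOM series, 4D volumes and registration are out of scope; convert to
  NIfTI/NRRD/MetaImage first.
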