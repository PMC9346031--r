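# DuctScope

Virtual pancreatoscopy from 3D CT: centerline extraction, super-resolved
lumen segmentation, and fly-through geometry for thin tubular ducts.

The main pancreatic duct is hypodense, thin (3–5 voxels across in typical
abdominal CT), and surrounded by contrast-enhanced parenchyma — too thin
for level-set or graph-cut segmentation to hold a stable boundary at native
resolution. DuctScope implements an interactive pipeline that needs only
the duct's head and tail landmarks:

1. **Tubularity map** `V ∈ [0,1]` — multiscale Hessian line filter
   (dark-tube polarity, spacing-aware Gaussian derivatives).
2. **Optimal-path centerline** — the curve minimizing
   `∫ (1 − V(C(t))) |C′(t)| dt` through all landmarks; by Bellman's
   principle this splits into independent sections between consecutive
   landmarks, each solved exactly with Dijkstra on the voxel graph
   (edge weight `max(floor, 1 − (V(p)+V(q))/2) · ‖x_p − x_q‖`).
3. **Super-resolved lumen segmentation** — an ROI around the centerline is
   refined by an odd factor `c = 5` (125× more voxels) with trilinear
   (convex) interpolation; a seed map labels the rasterized centerline as
   lumen and everything farther than `r = 10` mm as exterior; every other
   voxel takes the label of the seed reachable with minimal accumulated
   intensity-difference cost `Σ |I(q_{i+1}) − I(q_i)|` over Moore paths
   (multi-source Dijkstra, ties to lumen).
4. **Surface geometry** — watertight marching-tetrahedra mesh, per-vertex
   Gaussian curvature (angle deficit / mixed Voronoi area; nodules and
   cysts light up as high-magnitude patches), and a fly-through camera
   path along the centerline spline with parallel-transported up vectors.

A synthetic CT phantom generator with exact ground truth (curved hypodense
tube, partial-volume blur, seeded noise) makes the whole pipeline testable
without clinical data. Volumes are read/written as NIfTI, NRRD and
MetaImage; fiducials as 3D Slicer `.fcsv` or JSON point lists; meshes as
PLY/VTK; camera paths as JSON.

## Worked example

```r
library(DuctScope)

# a realistic phantom: curved 1.5 mm-radius duct, (0.8, 0.8, 1.5) mm
# voxels, 70 HU contrast, noise sigma 10, with exact ground truth
ph <- generatePhantom(defaultDuctSpec("realistic", seed = 1L))

res <- runPipeline(ph@image, ph@headTail,
                   truthMask = ph@ductMask,
                   truthCenterline = ph@centerline)

res$report$dice
#> [1] 0.8340807
res$report$mean_centerline_distance_mm
#> [1] 0.2872933
res$centerline
#> CenterlineCurve: 35 vertices, length 53.56 mm, cost 14.49
res$mesh
#> TriangleMesh: 71648 vertices, 143292 faces, scalars: gaussian_curvature, angle_deficit, mixed_area
```

A Dice of 0.83 against ground truth means the recovered lumen overlaps the
true 1.5 mm duct almost voxel-for-voxel at original resolution (the truth
mask itself is only ~400 voxels); the extracted centerline lies on average
0.29 mm from the true duct axis — well under the 1.88 mm voxel diagonal.
`writeMesh(res$mesh, "lumen.ply")` exports the curvature-coloured surface,
and `writeCameraPath(res$cameraPath, "fly.json")` the fly-through
keyframes.

A command-line front end wrapping the same functions ships in
`inst/cli/vp.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vp.R",package="DuctScope"))')" \
  run --image image.nii.gz --fiducials pts.fcsv --out-dir results/
```

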