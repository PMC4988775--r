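# ToothField

Interactive separation of individual teeth from 3D dental surface meshes,
for orthodontic CAD workflows where a clinician must split a scanned arch
into per-tooth parts before treatment planning.

The core is a **segmentation field**: a per-vertex scalar `u` on the mesh
`M = (V, E)`, obtained by minimizing a penalty-constrained Laplacian energy,

```
(L + P) u = P b
```

where `L = D − W` is a graph Laplacian with **concavity-aware weights**

```
w_ij = |e_ij| · beta / (|G_i + G_j| + gamma)   if vertex i or j is concave
w_ij = |e_ij|        / (|G_i + G_j| + gamma)   otherwise
```

(`|e_ij|` edge length, `G` Gaussian curvature, `beta = 0.01`,
`gamma = 1e-4`), `P` is diagonal with a large penalty `alpha = 1e8` at
constrained sites, and `b` prescribes 0 on the target tooth's cusp sites and
1 on the adjacent tooth's (Dirichlet conditions enforced softly). A vertex is
*concave* when some edge-neighbor satisfies
`dot((v_i − v_adj)/|v_i − v_adj|, n_adj − n_i) > theta` with `theta = 1e-3`.
Because concave edges get tiny weights, the harmonic field drops abruptly
across the grooves between teeth and between tooth and gingiva. Iso-contours
sampled from `u` therefore bunch inside those seams; a histogram of field
values locates the dominant unconstrained cluster and its midpoint `V_med`,
and the maximum-gradient contour in `[0, V_med]` and in `(V_med, 1]` become
the two cutting boundaries — one around the clicked tooth, one around its
neighbor. The mesh is subdivided exactly along those contours and labels are
flood-filled, so a single click separates two teeth and a full arch of `N`
teeth needs only `ceiling(N/2)` clicks.

The package provides the whole pipeline as composable S4 building blocks:
mesh I/O (OFF/OBJ/PLY/STL), discrete normals/curvature/geodesics, the
concavity-aware solver, marching-triangles contouring, boundary selection,
exact contour cuts with label propagation, a simplified cusp detector for
automatic constraint placement, deterministic synthetic dental-arch
generators with exact ground truth, and a command-line front end
(`inst/scripts/toothfield.R`).

## Worked example

```r
library(ToothField)

fx <- makeArch(nTeeth = 4, resolution = 0.4)     # synthetic arch, mm units
fx
#> ArchFixture: 4 teeth, crowding 1, noise 0; 4141 vertices, 8000 faces (2472 groove-band)

mesh   <- fx@mesh
pts    <- detectFeaturePoints(mesh, radius = 3)  # cusp points
groups <- groupFeaturePoints(mesh, pts, nGroups = 4)

## one "click" on tooth 2: solve the field, pick the two cutting boundaries
res <- segmentTooth(mesh, click = groups@representatives[2], groups = groups)
res$hist
#> FieldHistogram: 50 bins, 4141 vertices, fullest bin 26, vMed=0.51
res$selected$low
#> ContourLoop at level 0.275: 114 points, closed, length 21.75, score 0.1918
res$selected$high
#> ContourLoop at level 0.725: 120 points, closed, length 22.11, score 0.1776
res$segmented
#> SegmentedMesh: 8468 faces, 3 labels (0:7302, 1:568, 2:598)

## full arch, pairing clicks: ceiling(4/2) = 2 interactions
arch <- segmentArch(fx)
arch$nClicks
#> [1] 2
ev <- evaluateArchSegmentation(fx, arch)
round(100 * ev$agreement, 1)
#> [1] 96.4
```

The histogram's fullest bin is the gingiva/rest cluster (`vMed = 0.51`); the
selected boundaries are the closed maximum-gradient loops on either side —
the seam rings around the clicked tooth (level 0.275, ~21.8 mm around a
tooth of ~7 mm diameter) and its neighbor. After two interactions all four
teeth carry labels and 96.4% of the surface area agrees with the generator's
ground truth, with every mislabeled face inside the ambiguous groove band.

Write results with `writeSegmentedMesh(seg@mesh, faceLabels(seg), "out.ply")`
(colored PLY + JSON label map), or drive everything from the shell:

```sh
Rscript inst/scripts/toothfield.R fixture --teeth 4 --output arch.ply
Rscript inst/scripts/toothfield.R segment --input arch.ply --click 2071 --output seg.ply
```

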