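---
title: "Concavity-aware segmentation fields for tooth separation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concavity-aware segmentation fields for tooth separation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ToothField)
```

# The model

Scanned dental arches are triangle meshes on which individual teeth must be
separated along their natural seams: the interstices between neighboring
teeth and the tooth–gingiva margin. Both are *concave* creases — the minima
rule of human part perception — and that is the only geometric signal this
package relies on.

Let `M = (V, E)` be the mesh, `v_i` vertex positions (model units,
millimetres throughout), `n_i` unit vertex normals and `G_i` discrete
Gaussian curvature. A per-vertex scalar field `u` (the *segmentation
field*) is the solution of the penalty-constrained linear system

    (L + P) u = P b,

with `L = D − W` a weighted graph Laplacian, `P` the diagonal penalty
matrix holding `alpha` at constrained sites and zero elsewhere, and `b` the
prescribed site values: 0 on the *target* set (the tooth the user clicked)
and 1 on the *background* set (its neighbor). `L + P` is symmetric positive
definite on every connected component that carries at least one site, so
the system is solved by sparse Cholesky factorization; components without a
site receive the neutral value 0.5 with a warning. Under 0/1 site values the
discrete maximum principle confines `u` to `[0, 1]`; the test suite checks
this on every solve.

The weights make the field seam-seeking:

    w_ij = |e_ij| * beta / (|G_i + G_j| + gamma)    if i or j is concave,
    w_ij = |e_ij|        / (|G_i + G_j| + gamma)    otherwise,

and vertex `i` is concave when at least one edge-neighbor `adj` satisfies

    dot( (v_i − v_adj)/|v_i − v_adj| , n_adj − n_i ) > theta.

Across a valley the neighboring normals tilt toward each other, which makes
this projected difference positive; the test is symmetric in the edge, so
one evaluation per edge flags both endpoints. Concave edges with large
curvature get conductances orders of magnitude below smooth regions, so
almost the whole 0-to-1 drop of the harmonic field happens inside the
seams. Iso-contours of `u` consequently bunch there, and the contour with
the largest field-gradient magnitude is the cutting boundary.

Two formulations of the constrained problem circulate for fields of this
kind: a bi-harmonic least-squares form and the harmonic single-Laplacian
form. This package deliberately implements the harmonic form `(L+P)u = Pb`:
it is the system the Cholesky factorization targets, and the one whose
maximum principle guarantees `u` in `[0, 1]`.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | `1e8` | – | Site penalty. Large enough that site residuals are below `1e-6`; residuals decrease monotonically in `alpha` (tested at `1e4`, `1e6`, `1e8`). Fixed, not mesh-dependent. |
| `beta` | `0.01` | – | Attenuation of concave edges; the two orders of magnitude are what concentrates the field drop in seams. |
| `gamma` | `1e-4` | 1/mm² | Guard on the curvature divisor; also sets the (huge) conductance of perfectly flat edges. |
| `theta` | `1e-3` | – | Concavity threshold on the normal-difference test. Deliberately small: weak concavity should still be flagged, because the curvature division does the fine discrimination. |
| `nLevels` | 100 | – | Uniform iso-levels sampled in (0,1); dense enough that the argmax over loops approximates the continuous optimum. |
| `nBins` | 50 | – | Histogram bins on [0,1] used to locate the dominant unconstrained cluster; `vMed` is the midpoint of the fullest bin (ties to the lowest index). |
| `featureRadius` | 3 | mm | Geodesic neighborhood of the cusp detector — about half a tooth width. |
| `growRadius` | 1.5 | mm | Radius by which click-derived sites are grown into cusp patches (below). |

# Pipeline design decisions

**Patch constraints.** A penalty Dirichlet condition at a single vertex
produces a logarithmic field spike whose local gradient rivals the genuine
seam signal, so the maximum-gradient rule would select tiny rings around
the sites themselves. Click-derived target/background sets are therefore
grown into patches: all vertices within geodesic `growRadius` of the chosen
cusp group, restricted to non-concave vertices so the patch never leaves
the convex cap (`expandConstraintSites()`). This mirrors the practice of
constraining several points per tooth for complex crowns. Manual constraint
files are honored verbatim.

**Estimates on a smoothed geometry proxy.** Curvature is a second
derivative, so angle-deficit estimates on scanned data are dominated by
tessellation and scanner noise, which live at one-edge wavelength. Normals,
curvature and concavity flags are therefore computed on a proxy mesh whose
vertex positions have been Laplacian-smoothed (same connectivity); the
number of passes is chosen so the averaging kernel radius is about 0.9 mm
(capped at 30 passes), a scale well below the ~2 mm seam width. Everything
metric — edge lengths in the weights, contour geometry, cuts — uses the true
positions. With this scheme the groove-to-rest curvature contrast survives
Gaussian vertex noise up to 0.2 mean edge lengths.

**Boundary selection.** Candidates in `[0, vMed]` and `(vMed, 1]` are
ranked by the length-weighted mean gradient magnitude of their host faces
(stable under refinement, unlike a max or an unweighted mean). Two
restrictions, both fallbacks rather than hard filters: closed loops are
preferred over open rim-to-rim polylines (a closed contour bounds a
tooth-only part; open ones only occur for teeth touching the scan rim), and
a boundary may not enclose the cusp of any tooth not involved in the
interaction (checked through the field value at foreign group
representatives). The second rule matters on crowded arches, where an
unconstrained neighbor tooth floats toward the background potential and a
slightly-larger loop around *two* teeth can otherwise win. Loops shorter
than 3 median edge lengths are discarded as noise. Score ties break toward
the level nearer `vMed`.

**Cutting and label propagation.** Selected contours are realized exactly:
every crossing point becomes a mesh vertex, crossed faces are
retriangulated (a face crossed by several levels of one field is sliced
into convex level slabs, each fan-triangulated), and the loops become
chains of mesh edges. Flood fill over face adjacency never crosses a
realized chain; the component holding the target sites gets the next free
tooth id, the background component the following one unless it is already
labeled from an earlier interaction.

**Whole-arch interaction loop.** `segmentArch()` emulates an informed user:
unlabeled teeth are clicked pairwise along the arch (the click lands on a
cusp cap on the side of the intended partner, making the partner the
next-nearest group), and a leftover odd tooth is clicked against its
already-labeled neighbor — `ceiling(N/2)` interactions for `N` teeth. Every
interaction's field is solved on the *pristine* input mesh, exactly as an
interactive session would; the cuts are realized afterwards, sequentially,
by re-extracting each selected level set from the piecewise-linear field
transferred onto the accumulating refined mesh (linear interpolation on
split edges leaves level sets unchanged). Re-solving on an already-cut mesh
is deliberately avoided: subdivision slivers act as spurious insulators
under length-proportional edge weights and inject phantom high-gradient
faces.

**Geodesics and the cusp detector.** Geodesic distances are weighted
shortest paths on the edge graph — an approximation that only ranks nearby
feature groups, for which it is amply stable. The cusp detector is a
deliberately simple, deterministic proxy for published feature detectors: a
feature point is a local height maximum along the occlusal axis (default
+z, configurable) within its geodesic radius, on a convex cap, dominating
the lowest point of its neighborhood by `0.3 * radius` of relief (the
relief margin suppresses spurious maxima on noisy flat regions; exact
height ties, as produced by symmetric tessellations, disqualify nobody).
Feature points group by connectivity of the concavity-masked subgraph — the
concave grooves act as moats between cusp groups — with deterministic
merge/split rules when the expected tooth count is supplied.

# The synthetic arch generator

No public scanned-arch corpus with per-face ground truth is available at
this scale, so validation uses a parametric stand-in (`makeArch()`): a
gently bent base strip (width 16 mm, bend radius twice the arch length)
carrying a row of rotationally symmetric caps, height 4 mm and sigma 2 mm —
roughly premolar proportions. The caps are *truncated* Gaussians: a C²
smoothstep window fades them to exactly zero between 2.2 and 3 sigma, so
the gingival base is perfectly flat and forms one near-equipotential
cluster, as the smooth gum of a real arch does; the window is wide enough
that its own curvature stays far below the groove curvature. Crowding maps
to the tooth pitch as `8 * (0.7 + 0.3 * crowding)` mm: severity narrows the
interstices while the caps remain individual bumps (a mapping that fuses
the caps into a ridge would model conjoined teeth, not crowding; pitches
within 2.2 sigma are rejected). Gaussian vertex noise is quoted in mean
edge lengths and applied isotropically (a normal-displacement mode exists),
with the session RNG state restored afterwards.

Ground truth comes from the generating functions, never from the mesh: each
point's relative cap contributions `m1 >= m2` give the label (tooth of
`m1` if `m1 >= tau`, else base) and the groove band
(`m1` in `[0.05, 0.5]`, or a near-tie `m2 >= 0.5 * m1`). The boundary
threshold `tau` is placed at the ring where a seam-seeking field changes
fastest: for an axisymmetric cap with resistivity proportional to
`2|K| + gamma` (K the profile's Gaussian curvature), the radial drop
density is that resistivity divided by the circumference, so the seam ring
is `argmax (2|K(rho)| + gamma) / rho` over the concave annulus — about
1.59 sigma, `tau ≈ 0.284`. This is a property of the generating surface
and the weighting model, computed by quadrature from the profile, not a
fit to any pipeline output. Two alternative crease definitions (the
Gaussian-curvature maximum at 1.73 sigma and the radial-curvature maximum
at 2.10 sigma) bracket it; any fixed choice in that range shifts reported
agreements by a percent or two, which is the honest width of "where the
seam is" on a smooth groove.

Decimated variants (`decimateFixture()`) use midpoint edge collapse on
interior edges with a link-condition guard; ground truth is re-derived from
the parametric chart coordinates carried through the collapses, never
copied across meshes.

**What the generator does not emulate.** Anatomical crown shapes
(multi-cusp molars), scanner artifacts (holes, self-intersections,
anisotropic noise), variable gum curvature, and teeth touching the scan
rim. Passing the synthetic suite therefore demonstrates that the field
machinery finds concave seams under controlled crowding, noise and
tessellation — not clinical-grade accuracy on real scans.

# Numerical choices

* Iso-levels exactly hitting a vertex value are handled by symbolic
  perturbation (`+1e-12` on the vertex value for crossing tests only);
  a level can pass through a vertex without error or degenerate segments.
* Edge-crossing parameters are clamped to `[1e-3, 1−1e-3]` at cut time:
  a sub-micron geometric change that bounds the aspect ratio of subdivided
  faces (unbounded slivers turn solver round-off into huge spurious
  interpolant gradients).
* Gaussian curvature is the angle deficit over the barycentric (one-third)
  area; boundary vertices use the `pi` deficit. The `gamma` guard makes the
  pipeline insensitive to the area convention's scale. Open rims are
  supported throughout; the seams never touch them on the fixtures.
* The histogram is right-open except its last bin; the fullest-bin tie
  breaks to the lowest index; `vMed` is the bin midpoint (the downstream
  split only needs a value inside the dominant cluster).
* STL input is welded at `1e-8` of the bounding-box diagonal; OFF/OBJ
  1-based/0-based quirks are absorbed at I/O; all internal indices are
  1-based.
* All solves are deterministic; the only randomness anywhere is the
  seeded fixture noise.

# Problem sizes

The test suite exercises arches of 2–6 teeth at 0.4 mm resolution
(4k–12k vertices; the resolution-robustness comparison at 0.3 mm against
its quarter-face decimation), the full crowding-by-noise grid at those
sizes, and a single ~150k-vertex arch for the interactive-scale timing of
one field solve plus contour extraction. These sizes keep the complete
suite under a few minutes on one CPU while leaving every seam several
edges wide, which is the regime the method needs.

# Known limitations

* A single level set must trade the interstice position against the
  gum-seam radius on strongly crowded teeth; the cut can sit a fraction of
  a millimetre inside the deepest-concavity ring there. Multi-point
  constraints around the crown mitigate this in interactive use.
* Teeth whose seam touches the scan rim fall back to open cutting
  boundaries; the enclosed-part guarantees of closed loops do not apply.
* The cusp detector is a proxy; heavily worn or fractured crowns may need
  manual constraint files.
* Weights are graph-based (length over curvature), not finite-element
  cotangent weights; fields are only compared across tessellations of
  similar grading.
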