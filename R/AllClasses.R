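#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric Cholesky rowSums
#' @importFrom stats median rnorm hclust cutree as.dist
#' @importFrom utils head tail write.csv read.csv
NULL

# ---- condition helpers (validation / numerical / io errors get distinct classes
#      so the CLI can map them to exit codes) -----------------------------------

.vstop <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("toothFieldValidationError", "toothFieldError")))
}

.nstop <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("toothFieldNumericalError", "toothFieldError")))
}

.iostop <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("toothFieldIOError", "toothFieldError")))
}

# Undirected edge key: unique numeric per unordered vertex pair.
.edgeKey <- function(a, b, nv) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (lo - 1) * nv + hi
}

#' TriangleMesh: an indexed triangle surface
#'
#' The domain of every computation in the package: vertex positions (model
#' units, typically mm), counter-clockwise triangular faces, and the derived
#' unique undirected edge set with per-edge lengths. Construct with
#' [triangleMesh()], which validates manifoldness (every edge shared by at
#' most two faces), rejects degenerate faces and zero-length edges.
#'
#' @slot vertices numeric matrix, one row per vertex (x, y, z).
#' @slot faces integer matrix, one row per face, 1-based vertex indices.
#' @slot edges integer matrix, one row per unique undirected edge, sorted
#'   so that `edges[, 1] < edges[, 2]`.
#' @slot edgeLengths numeric vector of Euclidean edge lengths.
#' @slot edgeKeys numeric vector of canonical per-edge keys used for O(1)
#'   edge lookup via `match()`.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 edges = "matrix", edgeLengths = "numeric",
                 edgeKeys = "numeric"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must have 3 columns")
    if (nrow(f) > 0L && ncol(f) != 3L) return("faces must have 3 columns")
    if (nrow(f) > 0L) {
      if (min(f) < 1L || max(f) > nrow(v))
        return("face indices out of range")
      if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
        return("degenerate face repeats a vertex")
    }
    if (length(object@edgeLengths) && any(object@edgeLengths <= 0))
      return("edge lengths must be strictly positive")
    TRUE
  })

#' FieldParams: tuning constants of the segmentation field
#'
#' @slot alpha penalty factor enforcing the Dirichlet site values (default 1e8).
#' @slot beta attenuation applied to edge weights touching a concave vertex
#'   (default 0.01); small beta makes the field drop sharply across seams.
#' @slot gamma guard added to the curvature divisor (default 1e-4).
#' @slot theta concavity threshold on the normal-difference test (default 1e-3).
#' @exportClass FieldParams
setClass("FieldParams",
  representation(alpha = "numeric", beta = "numeric",
                 gamma = "numeric", theta = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1L || object@alpha <= 0) return("alpha must be > 0")
    if (length(object@beta) != 1L || object@beta <= 0 || object@beta > 1)
      return("beta must be in (0, 1]")
    if (length(object@gamma) != 1L || object@gamma <= 0) return("gamma must be > 0")
    if (length(object@theta) != 1L || object@theta < 0) return("theta must be >= 0")
    TRUE
  })

#' ConstraintSet: Dirichlet sites of a segmentation field
#'
#' Target sites are prescribed field value 0, background sites value 1.
#' The two sets must be disjoint; both must be non-empty before a solve.
#'
#' @slot targetSites integer vertex indices prescribed 0.
#' @slot backgroundSites integer vertex indices prescribed 1.
#' @exportClass ConstraintSet
setClass("ConstraintSet",
  representation(targetSites = "integer", backgroundSites = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@targetSites)) return("duplicated target sites")
    if (anyDuplicated(object@backgroundSites)) return("duplicated background sites")
    if (length(intersect(object@targetSites, object@backgroundSites)))
      return("target and background sites must be disjoint")
    if (length(object@targetSites) && min(object@targetSites) < 1L)
      return("target site indices must be >= 1")
    if (length(object@backgroundSites) && min(object@backgroundSites) < 1L)
      return("background site indices must be >= 1")
    TRUE
  })

#' SegmentationField: the per-vertex harmonic scalar field
#'
#' Solution of (L + P) u = P b where L is the concavity-aware Laplacian,
#' P the diagonal penalty matrix (alpha at constrained sites) and b the
#' prescribed 0/1 site values. Under 0/1 constraints the discrete maximum
#' principle confines all values to [0, 1] (validity allows 1e-6 slack).
#'
#' @slot values numeric per-vertex field values.
#' @slot params the [FieldParams] used for the solve.
#' @slot constraints the [ConstraintSet] used for the solve.
#' @exportClass SegmentationField
setClass("SegmentationField",
  representation(values = "numeric", params = "FieldParams",
                 constraints = "ConstraintSet"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("field values must be finite")
    if (length(object@values) &&
        (min(object@values) < -1e-6 || max(object@values) > 1 + 1e-6))
      return("field values violate the discrete maximum principle bound [-1e-6, 1+1e-6]")
    TRUE
  })

#' ContourLoop: one iso-contour polyline of a segmentation field
#'
#' An ordered polyline at a single iso-level. Every point lies on a mesh
#' edge (host edge id + interpolation parameter); consecutive points share
#' the host face that the connecting segment crosses.
#'
#' @slot level iso-value in (0, 1).
#' @slot points numeric matrix of ordered 3D polyline points.
#' @slot edgeIds integer host-edge index (into the mesh edge table) per point.
#' @slot edgeParams interpolation parameter in [0, 1] per point, measured
#'   from the lower-index endpoint of the canonical edge.
#' @slot faceIds integer host face per polyline segment
#'   (length `nrow(points) - 1`, or `nrow(points)` for closed loops).
#' @slot closed logical; closed loops have at least 3 points.
#' @slot length total polyline length.
#' @slot score length-weighted mean field-gradient magnitude over host faces.
#' @exportClass ContourLoop
setClass("ContourLoop",
  representation(level = "numeric", points = "matrix", edgeIds = "integer",
                 edgeParams = "numeric", faceIds = "integer",
                 closed = "logical", length = "numeric", score = "numeric"),
  validity = function(object) {
    np <- nrow(object@points)
    if (np < 2L) return("a contour needs at least 2 points")
    if (length(object@edgeIds) != np) return("one host edge per point required")
    if (any(object@edgeParams < -1e-12 | object@edgeParams > 1 + 1e-12))
      return("edge interpolation parameters must lie in [0, 1]")
    nseg <- if (object@closed) np else np - 1L
    if (length(object@faceIds) != nseg) return("one host face per segment required")
    if (object@closed && np < 3L) return("closed loops need at least 3 points")
    if (object@length <= 0) return("contour length must be positive")
    TRUE
  })

#' FieldHistogram: vertex counts over field-value bins
#'
#' Uniform bins on [0, 1] (right-open except the last). Exposes the fullest
#' bin (`binMaxIndex`, ties broken toward the lowest index) and the split
#' value `vMed` (midpoint of the fullest bin) that separates the target-tooth
#' contour interval from the adjacent-tooth interval.
#'
#' @slot binEdges numeric vector of B+1 increasing edges spanning [0, 1].
#' @slot counts integer vertex count per bin; sums to the vertex count.
#' @slot binMaxIndex 1-based index of the fullest bin.
#' @slot vMed midpoint of the fullest bin, in (0, 1).
#' @slot gaps list of numeric length-2 vectors: maximal runs of empty bins
#'   between occupied bins (the interval spacings where cutting boundaries live).
#' @exportClass FieldHistogram
setClass("FieldHistogram",
  representation(binEdges = "numeric", counts = "integer",
                 binMaxIndex = "integer", vMed = "numeric", gaps = "list"),
  validity = function(object) {
    if (length(object@counts) != length(object@binEdges) - 1L)
      return("counts/binEdges length mismatch")
    if (any(object@counts < 0L)) return("negative bin count")
    if (object@vMed <= 0 || object@vMed >= 1) return("vMed must lie in (0, 1)")
    if (object@counts[object@binMaxIndex] != max(object@counts))
      return("binMaxIndex does not point at a fullest bin")
    TRUE
  })

#' FeatureGroups: tooth-candidate groups of detected feature points
#'
#' @slot groups list of disjoint, non-empty integer vertex-index sets,
#'   one per tooth candidate.
#' @slot representatives integer vector, one vertex per group: the member
#'   nearest the group centroid.
#' @exportClass FeatureGroups
setClass("FeatureGroups",
  representation(groups = "list", representatives = "integer"),
  validity = function(object) {
    if (length(object@groups) != length(object@representatives))
      return("one representative per group required")
    if (any(vapply(object@groups, length, 1L) == 0L)) return("empty feature group")
    all_ids <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(all_ids)) return("feature groups must be pairwise disjoint")
    TRUE
  })

#' SegmentedMesh: a labeled, contour-refined mesh
#'
#' The result of cutting along selected contour loops and propagating labels:
#' the refined mesh (contour points promoted to vertices), one integer label
#' per face (0 = gingiva/rest, k >= 1 = tooth id) and the realized boundary
#' chains.
#'
#' @slot mesh the refined [TriangleMesh].
#' @slot faceLabels integer label per face of `mesh`.
#' @slot boundaries list of boundary chains; each a list with `vertexIds`
#'   (ordered refined-mesh vertex indices) and `closed`.
#' @exportClass SegmentedMesh
setClass("SegmentedMesh",
  representation(mesh = "TriangleMesh", faceLabels = "integer",
                 boundaries = "list"),
  validity = function(object) {
    if (length(object@faceLabels) != nrow(object@mesh@faces))
      return("one label per face required")
    TRUE
  })

#' ArchFixture: synthetic dental arch with ground truth
#'
#' Deterministic stand-in for scanned dental arches: a gently bent base strip
#' carrying a row of convex Gaussian caps ("teeth") separated by concave
#' grooves, with per-face ground-truth labels and a per-face groove-band mask
#' derived from the generating parametric functions.
#'
#' @slot mesh the generated [TriangleMesh].
#' @slot faceLabels integer ground-truth label per face (0 = base, k = tooth k).
#' @slot grooveBand logical per face: lies within a concave seam.
#' @slot params list of generator parameters, including the per-vertex
#'   parametric (s, t) chart coordinates under `$st`.
#' @exportClass ArchFixture
setClass("ArchFixture",
  representation(mesh = "TriangleMesh", faceLabels = "integer",
                 grooveBand = "logical", params = "list"),
  validity = function(object) {
    nf <- nrow(object@mesh@faces)
    if (length(object@faceLabels) != nf) return("one ground-truth label per face")
    if (length(object@grooveBand) != nf) return("one groove-band flag per face")
    TRUE
  })
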