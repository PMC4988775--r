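#' Construct a TriangleMesh
#'
#' Builds the indexed mesh and its derived undirected edge table, validating
#' the structural invariants: face indices in range, no degenerate faces,
#' every edge shared by at most two faces (manifold or open boundary) and
#' strictly positive edge lengths.
#'
#' @param vertices numeric matrix (or coercible) with one row per vertex
#'   and columns x, y, z.
#' @param faces integer matrix with one row per face; 1-based vertex indices,
#'   counter-clockwise when viewed from outside.
#' @return a [TriangleMesh-class] object.
#' @examples
#' m <- triangleMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' nVertices(m)
#' @export
triangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L)
      .vstop("faces must be triangles (3 columns), got %d columns", ncol(faces))
    bad <- which(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
                 faces[, 1L] == faces[, 3L])
    if (length(bad))
      .vstop("degenerate face(s) repeating a vertex: %s",
             paste(head(bad, 5L), collapse = ", "))
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      .vstop("face vertex indices must lie in [1, %d]", nrow(vertices))
  }
  nv <- nrow(vertices)
  he <- rbind(faces[, c(1L, 2L), drop = FALSE],
              faces[, c(2L, 3L), drop = FALSE],
              faces[, c(3L, 1L), drop = FALSE])
  keys <- .edgeKey(he[, 1L], he[, 2L], nv)
  tab <- table(keys)
  if (any(tab > 2L)) {
    offending <- names(tab)[tab > 2L]
    k <- as.numeric(offending)
    lo <- floor((k - 1) / nv) + 1
    hi <- k - (lo - 1) * nv
    .vstop("non-manifold edge(s) with >2 incident faces: %s",
           paste(sprintf("(%d,%d)", lo, hi)[seq_len(min(5L, length(lo)))],
                 collapse = ", "))
  }
  keep <- !duplicated(keys)
  edges <- cbind(pmin(he[keep, 1L], he[keep, 2L]),
                 pmax(he[keep, 1L], he[keep, 2L]))
  storage.mode(edges) <- "integer"
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  d <- vertices[edges[, 1L], , drop = FALSE] - vertices[edges[, 2L], , drop = FALSE]
  el <- sqrt(rowSums(d * d))
  if (length(el) && any(el <= 0))
    .vstop("zero-length edge(s): coincident vertices %s",
           paste(sprintf("(%d,%d)", edges[el <= 0, 1L], edges[el <= 0, 2L])[1:min(5, sum(el <= 0))],
                 collapse = ", "))
  new("TriangleMesh", vertices = vertices, faces = faces, edges = edges,
      edgeLengths = as.numeric(el),
      edgeKeys = .edgeKey(edges[, 1L], edges[, 2L], nv))
}

#' Mesh accessors
#'
#' @param x a [TriangleMesh-class].
#' @return `meshVertices`: the vertex coordinate matrix; `meshFaces`: the face
#'   index matrix; `meshEdges`: the unique undirected edge table;
#'   `edgeLengths`: per-edge Euclidean lengths; `nVertices`/`nFaces`: counts.
#' @name meshAccessors
#' @aliases meshVertices meshFaces meshEdges edgeLengths nVertices nFaces
NULL

#' @rdname meshAccessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname meshAccessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname meshAccessors
#' @export
setMethod("meshEdges", "TriangleMesh", function(x) x@edges)

#' @rdname meshAccessors
#' @export
setMethod("edgeLengths", "TriangleMesh", function(x) x@edgeLengths)

#' @rdname meshAccessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname meshAccessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

setMethod("show", "TriangleMesh", function(object) {
  bb <- apply(object@vertices, 2L, range)
  cat(sprintf("TriangleMesh: %d vertices, %d faces, %d edges\n",
              nrow(object@vertices), nrow(object@faces), nrow(object@edges)))
  cat(sprintf("  bounding box [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

# Per-face geometry shared by normals / curvature / gradients.
# Returns unit normals, areas and the (unnormalized) cross products.
.faceGeometry <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr * cr))
  list(cross = cr, areas = nrm2 / 2,
       normals = cr / pmax(nrm2, .Machine$double.xmin))
}

#' Area-weighted vertex normals
#'
#' The normal at each vertex is the area-weighted average of its incident
#' face normals, normalized to unit length. Orientation follows the face
#' winding (outward for meshes that are counter-clockwise viewed from
#' outside); flipping all windings negates all normals.
#'
#' @param mesh a [TriangleMesh-class].
#' @param ... unused.
#' @return numeric matrix of per-vertex unit normals.
#' @export
setMethod("vertexNormals", "TriangleMesh", function(mesh, ...) {
  fg <- .faceGeometry(mesh)
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  # area-weighted face normal = cross/2; accumulate over the 3 corners
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  contrib <- rbind(fg$cross, fg$cross, fg$cross)
  acc <- rowsum(contrib, group = idx, reorder = FALSE)
  out <- matrix(0, nv, 3L)
  out[as.integer(rownames(acc)), ] <- acc
  counted <- tabulate(idx, nbins = nv)
  if (any(counted == 0L))
    .vstop("isolated vertex with no incident face: %s",
           paste(head(which(counted == 0L), 5L), collapse = ", "))
  nn <- sqrt(rowSums(out * out))
  if (any(nn <= 0))
    .nstop("vanishing accumulated normal at vertex %d", which(nn <= 0)[1L])
  out / nn
})

# Corner angles of every face: 3 columns, angle at vertex 1, 2, 3.
.cornerAngles <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  ang <- function(a, b) {
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a * a) * rowSums(b * b))
    acos(pmin(1, pmax(-1, num / den)))
  }
  cbind(ang(p2 - p1, p3 - p1), ang(p1 - p2, p3 - p2), ang(p1 - p3, p2 - p3))
}

# Boundary vertices: endpoints of edges incident to exactly one face.
.boundaryVertices <- function(mesh) {
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  keys <- .edgeKey(he[, 1L], he[, 2L], nv)
  cnt <- table(keys)
  bkeys <- as.numeric(names(cnt)[cnt == 1L])
  out <- rep(FALSE, nv)
  if (length(bkeys)) {
    lo <- floor((bkeys - 1) / nv) + 1
    hi <- bkeys - (lo - 1) * nv
    out[c(lo, hi)] <- TRUE
  }
  out
}

#' Discrete Gaussian curvature (angle deficit over barycentric area)
#'
#' Interior vertices: (2*pi - sum of incident corner angles) / A; boundary
#' vertices (open rims): (pi - angle sum) / A, where A is one third of the
#' summed incident-face area. Units: radians per squared model unit. On a
#' closed mesh the raw angle deficits sum to 2*pi*chi (Gauss-Bonnet).
#'
#' @param mesh a [TriangleMesh-class].
#' @param raw if `TRUE`, return the raw angle deficits (not divided by area);
#'   used for Gauss-Bonnet checks.
#' @param ... unused.
#' @return numeric per-vertex curvature (or raw deficit).
#' @export
setMethod("gaussianCurvature", "TriangleMesh", function(mesh, raw = FALSE, ...) {
  fg <- .faceGeometry(mesh)
  if (any(fg$areas <= 0))
    .vstop("zero-area face(s): %s",
           paste(head(which(fg$areas <= 0), 5L), collapse = ", "))
  ang <- .cornerAngles(mesh)
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  angleSum <- rep(0, nv)
  as_ <- rowsum(c(ang[, 1L], ang[, 2L], ang[, 3L]), group = idx, reorder = FALSE)
  angleSum[as.integer(rownames(as_))] <- as_
  boundary <- .boundaryVertices(mesh)
  deficit <- ifelse(boundary, pi, 2 * pi) - angleSum
  if (raw) return(deficit)
  areaSum <- rep(0, nv)
  ar <- rowsum(rep(fg$areas / 3, 3L), group = idx, reorder = FALSE)
  areaSum[as.integer(rownames(ar))] <- ar
  if (any(areaSum <= 0))
    .vstop("vertex with zero barycentric area: %s",
           paste(head(which(areaSum <= 0), 5L), collapse = ", "))
  deficit / areaSum
})

# igraph over the mesh edge graph, weighted by edge length.
.meshGraph <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh@edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh@vertices))
    g <- igraph::add_vertices(g, nrow(mesh@vertices) - igraph::vcount(g))
  igraph::E(g)$weight <- mesh@edgeLengths
  g
}

#' Smooth a per-vertex field over the mesh graph
#'
#' Jacobi-style smoothing: each pass replaces a vertex value by the average
#' of its own value and its 1-ring mean. Used to stabilize discrete normal
#' and curvature estimates on noisy scanned meshes; a handful of passes
#' averages over a small geodesic neighborhood without displacing features
#' wider than a couple of edge lengths.
#'
#' @param mesh a [TriangleMesh-class].
#' @param values numeric vector (per vertex) or matrix (per-vertex rows).
#' @param iters number of smoothing passes.
#' @return smoothed values, same shape as the input.
#' @export
smoothVertexField <- function(mesh, values, iters = 1L) {
  if (iters < 1L) return(values)
  vec <- is.null(dim(values))
  vals <- if (vec) matrix(values, ncol = 1L) else values
  e <- mesh@edges
  nv <- nrow(mesh@vertices)
  idx <- c(e[, 1L], e[, 2L])
  deg <- tabulate(idx, nbins = nv)
  deg[deg == 0L] <- 1L
  for (it in seq_len(iters)) {
    acc <- rowsum(rbind(vals[e[, 2L], , drop = FALSE],
                        vals[e[, 1L], , drop = FALSE]),
                  group = idx, reorder = FALSE)
    nbMean <- matrix(0, nv, ncol(vals))
    nbMean[as.integer(rownames(acc)), ] <- acc
    nbMean <- nbMean / deg
    vals <- (vals + nbMean) / 2
  }
  if (vec) as.numeric(vals) else vals
}

#' Geodesic distance along the mesh edge graph
#'
#' Shortest-path (Dijkstra) distance over edges weighted by Euclidean edge
#' length — a graph approximation of surface geodesics, sufficient for
#' ranking nearby feature groups. Targets in a different connected component
#' get `+Inf`.
#'
#' @param mesh a [TriangleMesh-class].
#' @param source single source vertex index.
#' @param targets integer vector of target vertex indices.
#' @param ... unused.
#' @return numeric vector, one distance per target; 0 for the source itself.
#' @export
setMethod("geodesicDistance", "TriangleMesh", function(mesh, source, targets, ...) {
  nv <- nrow(mesh@vertices)
  source <- as.integer(source)
  targets <- as.integer(targets)
  if (length(source) != 1L || source < 1L || source > nv)
    .vstop("source must be a single valid vertex index")
  if (any(targets < 1L | targets > nv))
    .vstop("target vertex index out of range")
  g <- .meshGraph(mesh)
  d <- igraph::distances(g, v = source, to = unique(targets),
                         algorithm = "dijkstra")
  as.numeric(d[1L, match(targets, unique(targets))])
})
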