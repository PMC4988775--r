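#' Segmentation-field parameters
#'
#' @param alpha penalty factor enforcing site values (default 1e8).
#' @param beta concave-edge attenuation (default 0.01).
#' @param gamma curvature-divisor guard (default 1e-4).
#' @param theta concavity threshold (default 1e-3).
#' @return a [FieldParams-class] object.
#' @export
fieldParams <- function(alpha = 1e8, beta = 0.01, gamma = 1e-4, theta = 1e-3) {
  new("FieldParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), theta = as.numeric(theta))
}

setMethod("show", "FieldParams", function(object) {
  cat(sprintf("FieldParams: alpha=%g beta=%g gamma=%g theta=%g\n",
              object@alpha, object@beta, object@gamma, object@theta))
})

#' Constraint sets
#'
#' @param target integer vertex indices prescribed field value 0 (the tooth
#'   the user wants to separate).
#' @param background integer vertex indices prescribed field value 1 (the
#'   adjacent tooth).
#' @return a [ConstraintSet-class].
#' @export
constraintSet <- function(target = integer(), background = integer()) {
  new("ConstraintSet", targetSites = as.integer(target),
      backgroundSites = as.integer(background))
}

#' @rdname fieldAccessors
#' @export
setMethod("targetSites", "ConstraintSet", function(x) x@targetSites)

#' @rdname fieldAccessors
#' @export
setMethod("backgroundSites", "ConstraintSet", function(x) x@backgroundSites)

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet: %d target (value 0), %d background (value 1)\n",
              length(object@targetSites), length(object@backgroundSites)))
})

#' Read / write constraint sets
#'
#' CSV files carry columns `vertex_id,value` with value 0 (target) or 1
#' (background); JSON files carry `{"target": [...], "background": [...]}`.
#' Vertex ids are 1-based.
#'
#' @param path file path (`.csv` or `.json`).
#' @return a [ConstraintSet-class].
#' @export
readConstraints <- function(path) {
  if (!file.exists(path)) .iostop("no such constraint file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(constraintSet(as.integer(js$target), as.integer(js$background)))
  }
  df <- read.csv(path)
  if (!all(c("vertex_id", "value") %in% names(df)))
    .vstop("constraint CSV must have columns vertex_id,value")
  if (!all(df$value %in% c(0, 1)))
    .vstop("constraint values must be 0 (target) or 1 (background)")
  constraintSet(df$vertex_id[df$value == 0], df$vertex_id[df$value == 1])
}

#' @rdname readConstraints
#' @param constraints a [ConstraintSet-class] to write.
#' @export
writeConstraints <- function(constraints, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(target = constraints@targetSites,
                              background = constraints@backgroundSites),
                         path)
  } else {
    df <- data.frame(
      vertex_id = c(constraints@targetSites, constraints@backgroundSites),
      value = c(rep(0L, length(constraints@targetSites)),
                rep(1L, length(constraints@backgroundSites))))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Detect concave vertices
#'
#' Vertex i is concave iff some edge-neighbor `adj` satisfies
#' `dot((v_i - v_adj) / |v_i - v_adj|, n_adj - n_i) > theta`: across a valley
#' the neighboring normals tilt towards each other, making the projected
#' normal difference positive. The result does not depend on the order in
#' which neighbors are visited.
#'
#' @param mesh a [TriangleMesh-class].
#' @param normals per-vertex unit normals; computed with [vertexNormals()]
#'   when `NULL`.
#' @param theta non-negative threshold (default from [fieldParams()]).
#' @return logical per-vertex concavity flags.
#' @export
detectConcaveVertices <- function(mesh, normals = NULL,
                                  theta = fieldParams()@theta) {
  if (theta < 0) .vstop("theta must be >= 0")
  if (is.null(normals)) normals <- vertexNormals(mesh)
  if (nrow(normals) != nrow(mesh@vertices))
    .vstop("need one normal per vertex")
  nn <- sqrt(rowSums(normals * normals))
  if (any(abs(nn - 1) > 1e-6)) .vstop("normals must be unit length")
  e <- mesh@edges
  v <- mesh@vertices
  d <- v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len <= 0)) .vstop("coincident adjacent vertices on edge")
  d <- d / len
  dn <- normals[e[, 2L], , drop = FALSE] - normals[e[, 1L], , drop = FALSE]
  # the test is symmetric in the edge: swapping roles flips both the
  # direction and the normal difference, leaving the dot product unchanged,
  # so one evaluation per edge flags both endpoints
  dot <- rowSums(d * dn)
  hit <- dot > theta
  flags <- rep(FALSE, nrow(v))
  flags[unique(c(e[hit, 1L], e[hit, 2L]))] <- TRUE
  flags
}

#' Concavity-aware edge weights
#'
#' The weight of edge (i, j) is `|e_ij| / (|G_i + G_j| + gamma)`, attenuated
#' by the factor `beta` whenever either endpoint is concave. Small weights on
#' concave edges let the harmonic field drop abruptly across seams, which is
#' what concentrates iso-contours in the grooves between teeth.
#'
#' @param mesh a [TriangleMesh-class].
#' @param curvature per-vertex Gaussian curvature (see [gaussianCurvature()]).
#' @param concaveFlags logical per-vertex concavity flags
#'   (see [detectConcaveVertices()]).
#' @param params a [FieldParams-class]; defaults used when omitted.
#' @return numeric weight per mesh edge (ordered as `meshEdges(mesh)`);
#'   strictly positive and symmetric in the edge endpoints by construction.
#' @export
edgeWeights <- function(mesh, curvature, concaveFlags, params = fieldParams()) {
  nv <- nrow(mesh@vertices)
  if (length(curvature) != nv) .vstop("need one curvature value per vertex")
  if (length(concaveFlags) != nv) .vstop("need one concavity flag per vertex")
  e <- mesh@edges
  denom <- abs(curvature[e[, 1L]] + curvature[e[, 2L]]) + params@gamma
  w <- mesh@edgeLengths / denom
  concaveEdge <- concaveFlags[e[, 1L]] | concaveFlags[e[, 2L]]
  w[concaveEdge] <- w[concaveEdge] * params@beta
  w
}

# Graph Laplacian from an explicit edge list (used directly by tests on
# non-mesh graphs such as vertex paths).
.laplacianFromEdges <- function(edges, weights, n) {
  if (length(weights) != nrow(edges)) .vstop("need one weight per edge")
  if (any(weights <= 0)) .vstop("edge weights must be strictly positive")
  i <- c(edges[, 1L], edges[, 2L])
  j <- c(edges[, 2L], edges[, 1L])
  W <- Matrix::sparseMatrix(i = i, j = j, x = rep(weights, 2L),
                            dims = c(n, n))
  D <- Matrix::Diagonal(x = Matrix::rowSums(W))
  methods::as(Matrix::forceSymmetric(D - W), "CsparseMatrix")
}

#' Assemble the concavity-aware Laplacian
#'
#' `L = D - W` with `W_ij = omega_ij` on edges and `D` the diagonal of row
#' sums: `L_ii = sum_j omega_ij`, `L_ij = -omega_ij` for edges, 0 otherwise.
#' Symmetric, rows summing to zero, positive semi-definite for positive
#' weights.
#'
#' @param mesh a [TriangleMesh-class].
#' @param weights numeric per-edge weights (ordered as `meshEdges(mesh)`).
#' @return a symmetric sparse `Matrix`.
#' @export
assembleLaplacian <- function(mesh, weights) {
  if (length(weights) != nrow(mesh@edges))
    .vstop("need one weight per mesh edge (%d edges, %d weights)",
           nrow(mesh@edges), length(weights))
  if (any(!is.finite(weights))) .vstop("non-finite edge weight")
  .laplacianFromEdges(mesh@edges, weights, nrow(mesh@vertices))
}

#' Solve the constrained segmentation field
#'
#' Solves `(L + P) u = P b` where `P` is diagonal with `alpha` at constrained
#' sites and `b` holds the prescribed site values (0 at target sites, 1 at
#' background sites), via sparse Cholesky factorization. Disconnected
#' components are solved independently; a component containing no constrained
#' site gets the neutral value 0.5 and a warning.
#'
#' @param L the Laplacian from [assembleLaplacian()].
#' @param constraints a [ConstraintSet-class]; both sets must be non-empty.
#' @param params a [FieldParams-class] supplying `alpha`.
#' @param backgroundValue value prescribed at background sites (default 1).
#'   Setting it to 0 turns the solve into the zero-right-hand-side mode used
#'   by internal checks.
#' @return a [SegmentationField-class].
#' @export
solveField <- function(L, constraints, params = fieldParams(),
                       backgroundValue = 1) {
  n <- nrow(L)
  st <- constraints@targetSites
  sb <- constraints@backgroundSites
  if (!length(st) || !length(sb))
    .vstop("field requires both boundary conditions (non-empty target and background sets)")
  if (length(intersect(st, sb)))
    .vstop("target and background sites overlap")
  if (max(c(st, sb)) > n) .vstop("constrained site index exceeds system size")

  p <- numeric(n)
  p[c(st, sb)] <- params@alpha
  b <- numeric(n)
  b[sb] <- backgroundValue
  rhs <- p * b

  # connected components of the Laplacian's adjacency pattern
  trip <- Matrix::mat2triplet(L)
  offd <- trip$i < trip$j & trip$x != 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(trip$i[offd], trip$j[offd]))
  comp <- igraph::components(g)$membership

  u <- numeric(n)
  siteMask <- logical(n)
  siteMask[c(st, sb)] <- TRUE
  for (cc in seq_len(max(comp))) {
    idx <- which(comp == cc)
    if (!any(siteMask[idx])) {
      u[idx] <- 0.5
      warning(sprintf(
        "connected component %d holds no constrained site; field set to 0.5 there", cc))
      next
    }
    A <- L[idx, idx, drop = FALSE] + Matrix::Diagonal(x = p[idx])
    sol <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
      as.numeric(Matrix::solve(ch, rhs[idx]))
    }, error = function(e) .nstop("field solve failed: %s", conditionMessage(e)))
    u[idx] <- sol
  }
  new("SegmentationField", values = u, params = params, constraints = constraints)
}

#' @rdname fieldAccessors
#' @export
setMethod("fieldValues", "SegmentationField", function(x) x@values)

setMethod("show", "SegmentationField", function(object) {
  cat(sprintf("SegmentationField on %d vertices, range [%.4g, %.4g]\n",
              length(object@values), min(object@values), max(object@values)))
})

#' Field accessors
#' @param x object to access.
#' @name fieldAccessors
NULL
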