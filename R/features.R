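# concavity flags from the geometry-smoothed proxy (see .estimateGeometry)
.proxyFlags <- function(mesh, smoothIters = NULL) {
  .estimateGeometry(mesh, smoothIters = smoothIters)$concave
}

#' Detect tooth-cusp feature points
#'
#' A simplified, deterministic cusp detector used to place field constraints
#' automatically: a vertex is a feature point when it is a strict local
#' maximum of height along the occlusal axis within its geodesic
#' `radius`-neighborhood, lies on a convex cap (not concave-flagged), and
#' dominates the lowest point of that neighborhood by a relief margin of
#' `reliefFrac * radius` (which suppresses spurious maxima on noisy flat
#' regions). Fully manual constraint files can replace this detector.
#'
#' @param mesh a [TriangleMesh-class].
#' @param occlusalAxis unit 3-vector of the biting direction (default +z).
#' @param radius geodesic neighborhood radius in model units.
#' @param reliefFrac required relief as a fraction of `radius` (default 0.3).
#' @param normals optional precomputed vertex normals.
#' @param smoothIters smoothing passes applied to the normals entering the
#'   concavity test (see [smoothVertexField()]); stabilizes detection on
#'   noisy meshes.
#' @return integer vector of feature vertex indices.
#' @export
detectFeaturePoints <- function(mesh, occlusalAxis = c(0, 0, 1), radius,
                                reliefFrac = 0.3, normals = NULL,
                                smoothIters = NULL) {
  axis <- as.numeric(occlusalAxis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6) .vstop("occlusalAxis must be unit length")
  if (radius <= 0) .vstop("radius must be > 0")
  bb <- apply(mesh@vertices, 2L, range)
  diam <- sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  if (radius > diam)
    .vstop("radius %g exceeds the mesh diameter %g", radius, diam)
  h <- as.numeric(mesh@vertices %*% axis)
  concave <- if (is.null(normals)) .proxyFlags(mesh, smoothIters)
             else detectConcaveVertices(mesh, normals)

  # 1-ring local maxima as cheap candidates; exact height ties (e.g. from
  # symmetric tessellations) do not disqualify either vertex — co-maximal
  # cusp points end up in the same feature group anyway
  e <- mesh@edges
  nv <- nrow(mesh@vertices)
  beaten <- rep(FALSE, nv)
  hasLower <- rep(FALSE, nv)
  lower1 <- h[e[, 1L]] < h[e[, 2L]]
  lower2 <- h[e[, 2L]] < h[e[, 1L]]
  beaten[e[lower1, 1L]] <- TRUE
  beaten[e[lower2, 2L]] <- TRUE
  hasLower[e[lower1, 2L]] <- TRUE
  hasLower[e[lower2, 1L]] <- TRUE
  cand <- which(!beaten & hasLower & !concave)
  if (!length(cand)) return(integer(0))

  g <- .meshGraph(mesh)
  d <- igraph::distances(g, v = cand, algorithm = "dijkstra")
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    nb <- which(is.finite(d[k, ]) & d[k, ] <= radius)
    nb <- setdiff(nb, cand[k])
    if (!length(nb)) next
    keep[k] <- h[cand[k]] >= max(h[nb]) &&
      (h[cand[k]] - min(h[nb])) >= reliefFrac * radius
  }
  cand[keep]
}

#' Group feature points into tooth candidates
#'
#' Two feature points share a group iff they are connected by a mesh path
#' that never enters a concave-flagged vertex (connected components of the
#' concavity-masked subgraph): the concave grooves between teeth act as
#' moats separating cusp groups. When `nGroups` is given and differs from
#' the component count, groups are merged by single-linkage geodesic
#' proximity of their representatives, or split by a deterministic
#' farthest-pair partition, until the count matches.
#'
#' @param mesh a [TriangleMesh-class].
#' @param points integer feature vertex indices (non-empty).
#' @param nGroups target group count, or `NULL` for automatic.
#' @param concaveFlags optional precomputed per-vertex concavity flags.
#' @param smoothIters smoothing passes for the internally computed flags.
#' @return a [FeatureGroups-class].
#' @export
groupFeaturePoints <- function(mesh, points, nGroups = NULL,
                               concaveFlags = NULL, smoothIters = NULL) {
  points <- unique(as.integer(points))
  if (!length(points)) .vstop("no feature points to group")
  if (!is.null(nGroups) && nGroups > length(points))
    .vstop("nGroups (%d) exceeds number of feature points (%d)",
           nGroups, length(points))
  if (is.null(concaveFlags)) concaveFlags <- .proxyFlags(mesh, smoothIters)
  nv <- nrow(mesh@vertices)
  e <- mesh@edges
  ekeep <- !concaveFlags[e[, 1L]] & !concaveFlags[e[, 2L]]
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  g <- igraph::add_edges(g, t(e[ekeep, , drop = FALSE]))
  memb <- igraph::components(g)$membership
  # a feature point sitting on a concave vertex keeps its own singleton group
  gid <- memb[points]
  gid[concaveFlags[points]] <- max(memb) + seq_len(sum(concaveFlags[points]))
  groups <- unname(split(points, gid))

  if (!is.null(nGroups)) {
    nGroups <- as.integer(nGroups)
    while (length(groups) > nGroups) {
      reps <- vapply(groups, function(gr) .groupRepresentative(mesh, gr), 1L)
      D <- matrix(Inf, length(reps), length(reps))
      for (i in seq_along(reps))
        D[i, ] <- geodesicDistance(mesh, reps[i], reps)
      diag(D) <- Inf
      ij <- arrayInd(which.min(D), dim(D))
      a <- min(ij); b <- max(ij)
      groups[[a]] <- c(groups[[a]], groups[[b]])
      groups[[b]] <- NULL
    }
    while (length(groups) < nGroups) {
      # split the group with the largest Euclidean diameter at its farthest pair
      diam <- vapply(groups, function(gr) {
        if (length(gr) < 2L) return(0)
        P <- mesh@vertices[gr, , drop = FALSE]
        max(as.matrix(stats::dist(P)))
      }, 1)
      k <- which.max(diam)
      if (diam[k] == 0) .vstop("cannot split singleton groups to reach nGroups")
      gr <- groups[[k]]
      P <- mesh@vertices[gr, , drop = FALSE]
      D <- as.matrix(stats::dist(P))
      ij <- arrayInd(which.max(D), dim(D))
      dA <- D[ij[1L], ]; dB <- D[ij[2L], ]
      groups[[k]] <- gr[dA <= dB]
      groups[[length(groups) + 1L]] <- gr[dA > dB]
    }
  }
  reps <- vapply(groups, function(gr) .groupRepresentative(mesh, gr), 1L)
  new("FeatureGroups", groups = groups, representatives = as.integer(reps))
}

# member vertex nearest the group centroid
.groupRepresentative <- function(mesh, members) {
  P <- mesh@vertices[members, , drop = FALSE]
  ctr <- colMeans(P)
  d2 <- rowSums((P - matrix(ctr, nrow(P), 3L, byrow = TRUE))^2)
  as.integer(members[which.min(d2)])
}

setMethod("show", "FeatureGroups", function(object) {
  cat(sprintf("FeatureGroups: %d groups of sizes %s\n",
              length(object@groups),
              paste(vapply(object@groups, length, 1L), collapse = ", ")))
})

#' Write / read feature groups as JSON
#'
#' @param groups a [FeatureGroups-class].
#' @param path output JSON path.
#' @return the path (write) or a [FeatureGroups-class] (read).
#' @export
writeFeatureGroups <- function(groups, path) {
  jsonlite::write_json(list(groups = groups@groups,
                            representatives = groups@representatives),
                       path)
  invisible(path)
}

#' @rdname writeFeatureGroups
#' @export
readFeatureGroups <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  grp <- js$groups
  if (is.matrix(grp)) grp <- lapply(seq_len(nrow(grp)), function(i) grp[i, ])
  new("FeatureGroups", groups = lapply(grp, as.integer),
      representatives = as.integer(js$representatives))
}

#' Constraints from a single click
#'
#' Ranks feature groups by geodesic distance from the clicked vertex (group
#' distance = minimum over member vertices). The nearest group becomes the
#' target set (prescribed 0), the next-nearest the background set
#' (prescribed 1), so a single click segments the target tooth and its
#' adjacent tooth simultaneously.
#'
#' @param mesh a [TriangleMesh-class].
#' @param clickVertex clicked vertex index (a 3D pick snapped to the nearest
#'   vertex in the CLI).
#' @param groups a [FeatureGroups-class] with at least 2 groups.
#' @param growRadius geodesic radius (model units) by which the two chosen
#'   groups are grown into convex-cap patches via [expandConstraintSites()];
#'   0 disables growth.
#' @return a [ConstraintSet-class].
#' @export
constraintsFromClick <- function(mesh, clickVertex, groups, growRadius = 1.5) {
  clickVertex <- as.integer(clickVertex)
  if (clickVertex < 1L || clickVertex > nrow(mesh@vertices))
    .vstop("click vertex index out of range")
  if (length(groups@groups) < 2L)
    .vstop("need a neighboring tooth to constrain against (>= 2 feature groups)")
  allPts <- unlist(groups@groups, use.names = FALSE)
  d <- geodesicDistance(mesh, clickVertex, allPts)
  sizes <- vapply(groups@groups, length, 1L)
  gidx <- rep(seq_along(groups@groups), sizes)
  gdist <- vapply(seq_along(groups@groups),
                  function(k) min(d[gidx == k]), 1)
  ord <- order(gdist)
  cs <- constraintSet(target = groups@groups[[ord[1L]]],
                      background = groups@groups[[ord[2L]]])
  if (growRadius > 0) cs <- expandConstraintSites(mesh, cs, growRadius)
  cs
}

#' Grow constraint sites into cusp patches
#'
#' Replaces each constraint set by all vertices within geodesic `radius` of
#' its members, restricted to non-concave vertices (the patch never leaves
#' the convex cap). A penalty Dirichlet condition at an isolated vertex
#' produces a local field spike whose gradient rivals the groove signal;
#' patch constraints behave like the multi-point boundary constraints used
#' in practice and leave the field variation to the concave seams.
#'
#' @param mesh a [TriangleMesh-class].
#' @param constraints a [ConstraintSet-class].
#' @param radius geodesic growth radius in model units.
#' @param concaveFlags optional precomputed concavity flags.
#' @return the expanded [ConstraintSet-class].
#' @export
expandConstraintSites <- function(mesh, constraints, radius,
                                  concaveFlags = NULL, smoothIters = NULL) {
  if (radius <= 0) return(constraints)
  if (is.null(concaveFlags)) concaveFlags <- .proxyFlags(mesh, smoothIters)
  g <- .meshGraph(mesh)
  grow <- function(sites) {
    if (!length(sites)) return(integer(0))
    d <- igraph::distances(g, v = sites, algorithm = "dijkstra")
    near <- which(apply(d, 2L, min) <= radius)
    union(sites, near[!concaveFlags[near]])
  }
  tg <- grow(constraints@targetSites)
  bg <- grow(constraints@backgroundSites)
  overlap <- intersect(tg, bg)
  if (length(overlap)) {
    tg <- setdiff(tg, overlap)
    bg <- setdiff(bg, overlap)
    tg <- union(tg, intersect(constraints@targetSites, overlap))
    bg <- union(bg, setdiff(intersect(constraints@backgroundSites, overlap), tg))
  }
  constraintSet(tg, bg)
}
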