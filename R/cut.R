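#' Cut a mesh exactly along contour loops
#'
#' Every contour point is promoted to a mesh vertex and each crossed face is
#' retriangulated so the loops become chains of mesh edges: a face crossed by
#' one segment splits into a triangle plus a quad (two triangles); a face
#' crossed by several levels of the same field splits into convex level
#' slabs, each fan-triangulated. Crossing vertices are shared across faces,
#' so the output is manifold wherever the input was, and total area is
#' preserved exactly (subdivision never moves geometry).
#'
#' @param mesh a [TriangleMesh-class].
#' @param loops list of [ContourLoop-class] objects extracted from `mesh`.
#' @param field the [SegmentationField-class] the loops were extracted from;
#'   required only when one face is crossed by more than one level.
#' @return list with `mesh` (refined [TriangleMesh-class]), `boundaries`
#'   (per input loop: `vertexIds` chain in the refined mesh + `closed`),
#'   `parentFaces` (original face index per refined face) and
#'   `newVertexInfo` (host edge endpoints + interpolation parameter per
#'   added vertex, for transferring vertex attributes).
#' @export
cutMeshAlongLoops <- function(mesh, loops, field = NULL) {
  nv <- nrow(mesh@vertices)
  nf <- nrow(mesh@faces)
  if (!length(loops)) {
    return(list(mesh = mesh, boundaries = list(),
                parentFaces = seq_len(nf),
                newVertexInfo = matrix(0, 0L, 3L)))
  }
  for (l in loops) {
    if (any(l@edgeIds < 1L | l@edgeIds > nrow(mesh@edges)))
      .vstop("loop references edges outside this mesh")
    if (any(l@faceIds < 1L | l@faceIds > nf))
      .vstop("loop references faces outside this mesh")
  }
  u <- if (is.null(field)) NULL else field@values

  # ---- global crossing registry: one refined vertex per (edge, level) ----
  crKey <- character(0)
  crEdge <- integer(0); crParam <- numeric(0); crLevel <- numeric(0)
  loopNodeIdx <- vector("list", length(loops))
  for (li in seq_along(loops)) {
    l <- loops[[li]]
    keys <- paste0(l@edgeIds, "@", format(l@level, digits = 17))
    m <- match(keys, crKey)
    newk <- which(is.na(m))
    if (length(newk)) {
      crKey <- c(crKey, keys[newk])
      crEdge <- c(crEdge, l@edgeIds[newk])
      # keep crossings off the exact endpoints: bounds the aspect ratio of
      # the subdivided faces (a near-degenerate sliver turns solver noise
      # into huge spurious interpolant gradients downstream)
      crParam <- c(crParam, pmin(1 - 1e-3, pmax(1e-3, l@edgeParams[newk])))
      crLevel <- c(crLevel, rep(l@level, length(newk)))
      m[newk] <- length(crKey) - rev(seq_along(newk)) + 1L
    }
    loopNodeIdx[[li]] <- m
  }
  ncr <- length(crKey)
  elo <- mesh@edges[crEdge, 1L]
  ehi <- mesh@edges[crEdge, 2L]
  newPos <- (1 - crParam) * mesh@vertices[elo, , drop = FALSE] +
    crParam * mesh@vertices[ehi, , drop = FALSE]
  newIds <- nv + seq_len(ncr)

  # ---- per-face segment lists ----
  segFace <- integer(0); segA <- integer(0); segB <- integer(0)
  segLevel <- numeric(0)
  for (li in seq_along(loops)) {
    l <- loops[[li]]
    nodes <- loopNodeIdx[[li]]
    np <- length(nodes)
    a <- nodes[seq_len(np - 1L)]
    b <- nodes[2:np]
    fc <- l@faceIds
    if (l@closed) {
      a <- c(a, nodes[np]); b <- c(b, nodes[1L])
    } else {
      fc <- fc[seq_len(np - 1L)]
    }
    segFace <- c(segFace, l@faceIds)
    segA <- c(segA, a)
    segB <- c(segB, b)
    segLevel <- c(segLevel, rep(l@level, length(a)))
  }

  perFace <- split(seq_along(segFace), segFace)
  cutFaces <- as.integer(names(perFace))
  keepFaces <- setdiff(seq_len(nf), cutFaces)
  outFaces <- list(mesh@faces[keepFaces, , drop = FALSE])
  outParents <- list(keepFaces)

  nxt <- c(2L, 3L, 1L)
  for (fi in seq_along(cutFaces)) {
    fid <- cutFaces[[fi]]
    segs <- perFace[[fi]]
    corners <- mesh@faces[fid, ]
    if (length(segs) == 1L) {
      # single crossing: triangle + quad split, no field needed
      s <- segs[[1L]]
      cra <- segA[[s]]; crb <- segB[[s]]
      # identify which face edges host the two crossings
      hostEnds <- rbind(c(elo[cra], ehi[cra]), c(elo[crb], ehi[crb]))
      shared <- intersect(hostEnds[1L, ], hostEnds[2L, ])
      if (length(shared) != 1L)
        .vstop("contour segment endpoints do not share a face corner")
      o <- shared
      oi <- which(corners == o)
      x <- corners[nxt[oi]]
      y <- corners[nxt[nxt[oi]]]
      crOX <- if (x %in% hostEnds[1L, ]) cra else crb
      crOY <- if (crOX == cra) crb else cra
      pox <- newIds[crOX]; poy <- newIds[crOY]
      tri <- rbind(c(o, pox, poy),
                   c(pox, x, y),
                   c(pox, y, poy))
      outFaces[[length(outFaces) + 1L]] <- tri
      outParents[[length(outParents) + 1L]] <- rep(fid, 3L)
    } else {
      if (is.null(u))
        .vstop("face %d is crossed by multiple levels; the field is required to cut it", fid)
      tri <- .slabTriangulate(corners, segs, segA, segB, segLevel,
                              crEdge, crParam, newIds, elo, ehi, u,
                              mesh)
      outFaces[[length(outFaces) + 1L]] <- tri
      outParents[[length(outParents) + 1L]] <- rep(fid, nrow(tri))
    }
  }
  refFaces <- do.call(rbind, outFaces)
  refined <- triangleMesh(rbind(mesh@vertices, newPos), refFaces)

  boundaries <- lapply(seq_along(loops), function(li) {
    list(vertexIds = newIds[loopNodeIdx[[li]]], closed = loops[[li]]@closed)
  })
  list(mesh = refined, boundaries = boundaries,
       parentFaces = unlist(outParents, use.names = FALSE),
       newVertexInfo = cbind(lo = elo, hi = ehi, param = crParam))
}

# Retriangulate one face crossed by several (parallel) level chords of the
# same scalar field: walk the face boundary collecting corners and crossing
# points, then emit each level slab as a fan of a convex polygon.
.slabTriangulate <- function(corners, segs, segA, segB, segLevel,
                             crEdge, crParam, newIds, elo, ehi, u, mesh) {
  lvls <- sort(unique(segLevel[segs]))
  crs <- unique(c(segA[segs], segB[segs]))
  # perturbed corner values, consistent with extraction
  uc <- u[corners]
  for (t in lvls) uc[uc == t] <- t + 1e-12

  # boundary walk: corner, crossings on (corner, next corner) ordered along it
  ids <- integer(0); uvals <- numeric(0)
  nxt <- c(2L, 3L, 1L)
  for (ci in 1:3) {
    a <- corners[ci]; b <- corners[nxt[ci]]
    ids <- c(ids, a); uvals <- c(uvals, uc[ci])
    onEdge <- crs[(elo[crs] == min(a, b)) & (ehi[crs] == max(a, b))]
    if (length(onEdge)) {
      par <- crParam[onEdge]
      if (a > b) par <- 1 - par   # orient param from a to b
      ord <- order(par)
      ids <- c(ids, newIds[onEdge[ord]])
      uvals <- c(uvals, crLevelOf(onEdge[ord], segs, segA, segB, segLevel))
    }
  }
  bounds <- c(-Inf, lvls, Inf)
  tris <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[[k]]; hi <- bounds[[k + 1L]]
    inSlab <- (uvals > lo & uvals < hi) |
      (is.finite(lo) & uvals == lo) | (is.finite(hi) & uvals == hi)
    poly <- ids[inSlab]
    if (length(poly) < 3L) next
    for (j in 2:(length(poly) - 1L))
      tris[[length(tris) + 1L]] <- c(poly[1L], poly[j], poly[j + 1L])
  }
  do.call(rbind, tris)
}

# level of each crossing id (every crossing belongs to exactly one level)
crLevelOf <- function(crossings, segs, segA, segB, segLevel) {
  vapply(crossings, function(cr) {
    hit <- segs[segA[segs] == cr | segB[segs] == cr][1L]
    segLevel[hit]
  }, 1)
}

#' Propagate part labels over a cut mesh
#'
#' Flood-fills face labels over the face-adjacency graph of the refined mesh,
#' never crossing a realized boundary edge. The component containing the
#' target constraint sites receives the next free tooth id; the component
#' containing the background sites receives the following id unless it
#' already carries a label from an earlier interaction. All remaining faces
#' keep their existing labels (or 0).
#'
#' @param refined the refined [TriangleMesh-class] from [cutMeshAlongLoops()].
#' @param boundaries boundary chains from [cutMeshAlongLoops()].
#' @param constraints the [ConstraintSet-class] of the interaction.
#' @param existingLabels optional integer label per face from earlier
#'   interactions.
#' @return a [SegmentedMesh-class].
#' @export
propagateLabels <- function(refined, boundaries, constraints,
                            existingLabels = NULL) {
  nf <- nrow(refined@faces)
  nv <- nrow(refined@vertices)
  labels <- if (is.null(existingLabels)) rep(0L, nf) else as.integer(existingLabels)
  if (length(labels) != nf) .vstop("existingLabels length must match face count")

  bKeys <- numeric(0)
  for (b in boundaries) {
    vid <- b$vertexIds
    if (length(vid) >= 2L) {
      a <- vid[-length(vid)]; z <- vid[-1L]
      if (isTRUE(b$closed)) { a <- c(a, vid[length(vid)]); z <- c(z, vid[1L]) }
      bKeys <- c(bKeys, .edgeKey(a, z, nv))
    }
  }

  f <- refined@faces
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  keys <- .edgeKey(he[, 1L], he[, 2L], nv)
  faceOf <- rep(seq_len(nf), 3L)
  open <- !(keys %in% bKeys)
  ord <- order(keys[open])
  k <- keys[open][ord]; fo <- faceOf[open][ord]
  same <- which(k[-1L] == k[-length(k)])
  adj <- cbind(fo[same], fo[same + 1L])

  g <- igraph::make_empty_graph(nf, directed = FALSE)
  if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
  comp <- igraph::components(g)$membership

  compOfSites <- function(sites) {
    inc <- which(rowSums(matrix(f %in% sites, nf, 3L)) > 0L)
    if (!length(inc)) .vstop("constraint sites touch no face of the refined mesh")
    cc <- comp[inc]
    as.integer(names(sort(table(cc), decreasing = TRUE))[1L])
  }
  ct <- compOfSites(constraints@targetSites)
  cb <- compOfSites(constraints@backgroundSites)
  if (length(boundaries) && ct == cb)
    .vstop("cut failed to separate constraints (target and background in one component)")

  nextId <- max(labels) + 1L
  labels[comp == ct] <- nextId
  bgLabels <- labels[comp == cb]
  if (all(bgLabels %in% c(0L, nextId)) || !length(boundaries)) {
    if (ct != cb) labels[comp == cb] <- nextId + 1L
  }
  new("SegmentedMesh", mesh = refined, faceLabels = labels,
      boundaries = boundaries)
}

#' @rdname segAccessors
#' @export
setMethod("faceLabels", "SegmentedMesh", function(x) x@faceLabels)

setMethod("show", "SegmentedMesh", function(object) {
  tab <- table(object@faceLabels)
  cat(sprintf("SegmentedMesh: %d faces, %d labels (%s)\n",
              length(object@faceLabels), length(tab),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
})

#' Segmentation accessors
#' @param x object to access.
#' @name segAccessors
NULL
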