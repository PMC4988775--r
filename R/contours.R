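#' Per-face gradient of the piecewise-linear field
#'
#' The gradient of the linear interpolant of `u` over each triangle, computed
#' from the hat-function gradients; it lies in the face plane. Reproduces
#' linear fields exactly and is invariant under rigid motion.
#'
#' @param mesh a [TriangleMesh-class].
#' @param field a [SegmentationField-class] (or numeric per-vertex values).
#' @return numeric matrix, one 3-vector per face.
#' @export
faceFieldGradients <- function(mesh, field) {
  u <- if (is(field, "SegmentationField")) field@values else as.numeric(field)
  if (length(u) != nrow(mesh@vertices))
    .vstop("field must be defined on all %d vertices", nrow(mesh@vertices))
  fg <- .faceGeometry(mesh)
  if (any(fg$areas <= 0))
    .vstop("degenerate (zero-area) face: %s",
           paste(head(which(fg$areas <= 0), 5L), collapse = ", "))
  v <- mesh@vertices
  f <- mesh@faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  nhat <- fg$normals
  cross3 <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  # grad u = sum_k u_k * (nhat x e_opp_k) / (2A), e_opp_k = edge opposite k
  g <- (u[f[, 1L]] * cross3(nhat, p3 - p2) +
        u[f[, 2L]] * cross3(nhat, p1 - p3) +
        u[f[, 3L]] * cross3(nhat, p2 - p1)) / (2 * fg$areas)
  g
}

#' Extract iso-contours of the segmentation field
#'
#' Marching triangles: each face whose vertex values straddle a level
#' contributes one segment with endpoints linearly interpolated on the two
#' crossed edges; segments are chained into maximal closed loops or open
#' polylines (open chains terminate on the mesh rim). Every loop is scored by
#' the length-weighted mean gradient magnitude of its host faces; loops
#' shorter than `minLengthFactor` median edge lengths are discarded as noise.
#'
#' @param mesh a [TriangleMesh-class].
#' @param field a [SegmentationField-class] (or per-vertex numeric values).
#' @param levels iso-values to sample; default `nLevels` uniform levels in
#'   (0, 1).
#' @param nLevels number of uniform levels when `levels` is `NULL`.
#' @param minLengthFactor noise-loop cutoff in median edge lengths.
#' @return list of [ContourLoop-class] objects.
#' @export
extractIsocontours <- function(mesh, field, levels = NULL, nLevels = 100L,
                               minLengthFactor = 3) {
  u <- if (is(field, "SegmentationField")) field@values else as.numeric(field)
  if (length(u) != nrow(mesh@vertices))
    .vstop("field must be defined on all %d vertices", nrow(mesh@vertices))
  if (is.null(levels)) levels <- (seq_len(nLevels) - 0.5) / nLevels
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  U <- cbind(u[f[, 1L]], u[f[, 2L]], u[f[, 3L]])
  gmag <- sqrt(rowSums(faceFieldGradients(mesh, u)^2))
  minLen <- minLengthFactor * median(mesh@edgeLengths)
  v <- mesh@vertices
  loops <- list()
  for (t in levels) {
    eq <- U == t
    Ut <- U
    if (any(eq)) Ut[eq] <- t + 1e-12
    above <- Ut > t
    nAbove <- rowSums(above)
    crossed <- which(nAbove == 1L | nAbove == 2L)
    if (!length(crossed)) next
    ab <- above[crossed, , drop = FALSE]
    # odd corner: the lone vertex on the minority side
    odd <- integer(length(crossed))
    one <- nAbove[crossed] == 1L
    odd[one] <- max.col(ab[one, , drop = FALSE] + 0, ties.method = "first")
    odd[!one] <- max.col((!ab[!one, , drop = FALSE]) + 0, ties.method = "first")
    nxt <- c(2L, 3L, 1L)
    prv <- c(3L, 1L, 2L)
    fc <- f[crossed, , drop = FALSE]
    o <- fc[cbind(seq_along(crossed), odd)]
    x <- fc[cbind(seq_along(crossed), nxt[odd])]
    y <- fc[cbind(seq_along(crossed), prv[odd])]
    uo <- Ut[cbind(crossed, odd)]
    ux <- Ut[cbind(crossed, nxt[odd])]
    uy <- Ut[cbind(crossed, prv[odd])]
    sox <- (t - uo) / (ux - uo)   # param from o towards x
    soy <- (t - uo) / (uy - uo)
    eox <- match(.edgeKey(o, x, nv), mesh@edgeKeys)
    eoy <- match(.edgeKey(o, y, nv), mesh@edgeKeys)
    # canonical params measured from the lower-index endpoint
    pox <- ifelse(o < x, sox, 1 - sox)
    poy <- ifelse(o < y, soy, 1 - soy)
    ptx <- v[o, , drop = FALSE] + sox * (v[x, , drop = FALSE] - v[o, , drop = FALSE])
    pty <- v[o, , drop = FALSE] + soy * (v[y, , drop = FALSE] - v[o, , drop = FALSE])
    segLen <- sqrt(rowSums((ptx - pty)^2))

    # chain segments: nodes are crossed edges, links are segments
    ue <- unique(c(eox, eoy))
    n1 <- match(eox, ue)
    n2 <- match(eoy, ue)
    npt <- length(ue)
    # node -> positions/params lookup
    nodeParam <- numeric(npt)
    nodeParam[n1] <- pox
    nodeParam[n2] <- poy
    nodePos <- matrix(0, npt, 3L)
    nodePos[n1, ] <- ptx
    nodePos[n2, ] <- pty
    ns <- length(crossed)
    incSeg <- vector("list", npt)
    ends <- c(n1, n2)
    segid <- rep(seq_len(ns), 2L)
    sp <- split(segid, ends)
    incSeg[as.integer(names(sp))] <- sp
    deg <- lengths(incSeg)
    segUsed <- rep(FALSE, ns)

    walk <- function(start) {
      nodes <- integer(0)
      segs <- integer(0)
      cur <- start
      repeat {
        nodes <- c(nodes, cur)
        cand <- incSeg[[cur]]
        cand <- cand[!segUsed[cand]]
        if (!length(cand)) break
        sgl <- cand[[1L]]
        segUsed[sgl] <<- TRUE
        segs <- c(segs, sgl)
        cur <- if (n1[sgl] == cur) n2[sgl] else n1[sgl]
        if (cur == start) break
      }
      list(nodes = nodes, segs = segs,
           closed = length(segs) >= 3L &&
             (if (n1[segs[length(segs)]] == nodes[length(nodes)])
                n2[segs[length(segs)]] else n1[segs[length(segs)]]) == start)
    }

    addLoop <- function(ch) {
      if (!length(ch$segs)) return()
      totLen <- sum(segLen[ch$segs])
      if (totLen < minLen || totLen <= 0) return()
      score <- sum(segLen[ch$segs] * gmag[crossed[ch$segs]]) / totLen
      loops[[length(loops) + 1L]] <<- new("ContourLoop",
        level = t,
        points = nodePos[ch$nodes, , drop = FALSE],
        edgeIds = as.integer(ue[ch$nodes]),
        edgeParams = pmin(1, pmax(0, nodeParam[ch$nodes])),
        faceIds = as.integer(crossed[ch$segs]),
        closed = ch$closed,
        length = totLen,
        score = score)
    }

    for (start in which(deg == 1L)) {
      if (all(segUsed[incSeg[[start]]])) next
      addLoop(walk(start))
    }
    remaining <- which(!segUsed)
    while (length(remaining)) {
      addLoop(walk(n1[remaining[[1L]]]))
      remaining <- which(!segUsed)
    }
  }
  loops
}

setMethod("show", "ContourLoop", function(object) {
  cat(sprintf("ContourLoop at level %.4g: %d points, %s, length %.4g, score %.4g\n",
              object@level, nrow(object@points),
              if (object@closed) "closed" else "open",
              object@length, object@score))
})

#' Histogram of field values over vertices
#'
#' Uniform bins on [0, 1], right-open except the last. The fullest bin
#' (`binMaxIndex`, ties towards the lowest index) corresponds to the large
#' unconstrained region of the mesh; its midpoint `vMed` splits [0, 1] into
#' the target-tooth interval `[0, vMed]` and the adjacent-tooth interval
#' `(vMed, 1]`. Runs of empty bins between occupied clusters are reported as
#' `gaps` — the sparse intervals where cutting boundaries live.
#'
#' @param field a [SegmentationField-class] (or per-vertex numeric values).
#' @param nBins number of bins (>= 2), default 50.
#' @return a [FieldHistogram-class].
#' @export
fieldHistogram <- function(field, nBins = 50L) {
  u <- if (is(field, "SegmentationField")) field@values else as.numeric(field)
  nBins <- as.integer(nBins)
  if (nBins < 2L) .vstop("nBins must be >= 2")
  edges <- seq(0, 1, length.out = nBins + 1L)
  idx <- pmin(pmax(floor(pmin(pmax(u, 0), 1) * nBins) + 1L, 1L), nBins)
  counts <- tabulate(idx, nbins = nBins)
  bmax <- which.max(counts)   # ties -> lowest index
  vmed <- (edges[bmax] + edges[bmax + 1L]) / 2
  occupied <- counts > 0L
  gaps <- list()
  occIdx <- which(occupied)
  if (length(occIdx) >= 2L) {
    for (k in seq_len(length(occIdx) - 1L)) {
      a <- occIdx[k]; b <- occIdx[k + 1L]
      if (b - a > 1L)
        gaps[[length(gaps) + 1L]] <- c(edges[a + 1L], edges[b])
    }
  }
  new("FieldHistogram", binEdges = edges, counts = as.integer(counts),
      binMaxIndex = as.integer(bmax), vMed = vmed, gaps = gaps)
}

setMethod("show", "FieldHistogram", function(object) {
  cat(sprintf("FieldHistogram: %d bins, %d vertices, fullest bin %d, vMed=%.4g\n",
              length(object@counts), sum(object@counts),
              object@binMaxIndex, object@vMed))
})

#' Select the two cutting boundaries
#'
#' The low boundary is the loop with maximal gradient score among levels in
#' `[0, vMed]` (around the target tooth); the high boundary the analogue in
#' `(vMed, 1]` (around the adjacent tooth). Score ties are broken toward the
#' level nearer `vMed`. If one interval holds no loop, that boundary is
#' absent with a warning (arch-end teeth have a single neighbor); if neither
#' holds a loop, an error is raised.
#'
#' @param loops list of [ContourLoop-class] objects, scored.
#' @param hist the [FieldHistogram-class] built from the same field.
#' @param protect field values of features (e.g. cusps of teeth not involved
#'   in this interaction) that no selected boundary may enclose: low-side
#'   candidates are restricted to levels below, high-side candidates to
#'   levels above, all protected values. Ignored where it would leave an
#'   interval without candidates.
#' @return list with elements `low` and `high` ([ContourLoop-class] or `NULL`).
#' @export
selectCutBoundaries <- function(loops, hist, protect = numeric(0)) {
  if (!length(loops)) .vstop("no candidate cutting boundary")
  lv <- vapply(loops, function(l) l@level, 1)
  sc <- vapply(loops, function(l) l@score, 1)
  vmed <- hist@vMed
  pick <- function(idx) {
    if (!length(idx)) return(NULL)
    best <- idx[sc[idx] == max(sc[idx])]
    best[which.min(abs(lv[best] - vmed))]
  }
  restrict <- function(idx, keep) if (any(keep[idx])) idx[keep[idx]] else idx
  lowCand <- which(lv <= vmed)
  highCand <- which(lv > vmed)
  if (length(protect)) {
    lowCand <- restrict(lowCand, lv < min(protect))
    highCand <- restrict(highCand, lv > max(protect))
  }
  # a closed contour bounds a tooth-only part; open (rim-to-rim) contours
  # are a fallback for teeth that touch the scan boundary
  isClosed <- vapply(loops, function(l) l@closed, TRUE)
  lowCand <- restrict(lowCand, isClosed)
  highCand <- restrict(highCand, isClosed)
  lowIdx <- pick(lowCand)
  highIdx <- pick(highCand)
  if (is.null(lowIdx) && is.null(highIdx))
    .vstop("no candidate cutting boundary")
  if (is.null(lowIdx))
    warning("no contour in [0, vMed]: low boundary absent")
  if (is.null(highIdx))
    warning("no contour in (vMed, 1]: high boundary absent")
  list(low = if (is.null(lowIdx)) NULL else loops[[lowIdx]],
       high = if (is.null(highIdx)) NULL else loops[[highIdx]])
}

#' Export contour loops as JSON polylines
#'
#' @param loops list of [ContourLoop-class] objects.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeContours <- function(loops, path) {
  out <- lapply(loops, function(l) {
    list(level = l@level, closed = l@closed, length = l@length,
         score = l@score,
         points = unname(apply(l@points, 1L, function(p) as.numeric(p),
                               simplify = FALSE)))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
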