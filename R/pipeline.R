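# Differential estimates (normals, curvature, concavity flags) are computed
# on a geometry-smoothed proxy of the mesh (same connectivity, Laplacian-
# smoothed positions). Curvature is a second derivative, so tessellation
# and scanner noise — which live at one-edge wavelength — dominate the raw
# angle-deficit estimate, while the millimetre-scale seams survive the
# smoothing essentially unchanged. Everything metric (edge lengths,
# contours, cuts) stays on the true geometry.
.estimateGeometry <- function(mesh, theta = fieldParams()@theta,
                              smoothScale = 0.9, smoothIters = NULL) {
  if (is.null(smoothIters)) {
    # pick passes so the averaging kernel radius is about smoothScale model
    # units (one pass adds ~ meanEdge^2/2 of kernel variance), capped so
    # very fine tessellations stay affordable
    le <- mean(mesh@edgeLengths)
    smoothIters <- max(0L, min(30L, as.integer(round(2 * (smoothScale / le)^2))))
  }
  proxy <- if (smoothIters > 0L)
    triangleMesh(smoothVertexField(mesh, mesh@vertices, smoothIters),
                 mesh@faces)
  else mesh
  normals <- vertexNormals(proxy)
  list(normals = normals,
       curvature = gaussianCurvature(proxy),
       concave = detectConcaveVertices(proxy, normals, theta = theta))
}

# Shared per-mesh precomputation for one interaction.
.fieldOnMesh <- function(mesh, constraints, params, smoothIters = NULL) {
  est <- .estimateGeometry(mesh, theta = params@theta,
                           smoothIters = smoothIters)
  w <- edgeWeights(mesh, est$curvature, est$concave, params)
  L <- assembleLaplacian(mesh, w)
  solveField(L, constraints, params)
}

#' Segment one tooth (and its neighbor) from a single interaction
#'
#' Runs the whole per-click pipeline: concavity detection, concavity-aware
#' weights, constrained field solve, iso-contour sampling, histogram split,
#' maximum-gradient boundary selection, exact cut and label propagation.
#' The constraints come either from an explicit [ConstraintSet-class] or
#' from a clicked vertex plus feature groups.
#'
#' @param mesh a [TriangleMesh-class].
#' @param click clicked vertex index (used with `groups`).
#' @param constraints explicit [ConstraintSet-class]; overrides `click`.
#' @param groups [FeatureGroups-class] for click-based constraint assignment;
#'   detected automatically when `NULL` and `click` is given.
#' @param params a [FieldParams-class].
#' @param nLevels number of sampled iso-levels.
#' @param nBins histogram bin count.
#' @param existingLabels per-face labels from earlier interactions.
#' @param extraBoundaries boundary chains realized by earlier interactions;
#'   label propagation never crosses them either.
#' @param featureRadius geodesic radius of the cusp detector (model units).
#' @param occlusalAxis biting direction for the cusp detector.
#' @return list with `segmented` ([SegmentedMesh-class]), `field`, `loops`,
#'   `hist`, `selected`, `constraints`, `parentFaces`, `newVertexInfo`.
#' @export
segmentTooth <- function(mesh, click = NULL, constraints = NULL, groups = NULL,
                         params = fieldParams(), nLevels = 100L, nBins = 50L,
                         existingLabels = NULL, extraBoundaries = list(),
                         featureRadius = 3, occlusalAxis = c(0, 0, 1)) {
  if (is.null(constraints)) {
    if (is.null(click)) .vstop("provide either a click vertex or constraints")
    if (is.null(groups)) {
      pts <- detectFeaturePoints(mesh, occlusalAxis, featureRadius)
      groups <- groupFeaturePoints(mesh, pts)
    }
    constraints <- constraintsFromClick(mesh, click, groups)
  }
  field <- .fieldOnMesh(mesh, constraints, params)
  loops <- extractIsocontours(mesh, field, nLevels = nLevels)
  hist <- fieldHistogram(field, nBins = nBins)
  protect <- numeric(0)
  if (!is.null(groups)) {
    foreign <- setdiff(groups@representatives,
                       c(constraints@targetSites, constraints@backgroundSites))
    protect <- field@values[foreign]
  }
  sel <- selectCutBoundaries(loops, hist, protect = protect)
  chosen <- Filter(Negate(is.null), list(sel$low, sel$high))
  cut <- cutMeshAlongLoops(mesh, chosen, field = field)
  labs0 <- if (is.null(existingLabels)) NULL else existingLabels[cut$parentFaces]
  oldChains <- .spliceBoundaryChains(extraBoundaries, cut$newVertexInfo,
                                     nrow(mesh@vertices))
  seg <- propagateLabels(cut$mesh, c(cut$boundaries, oldChains), constraints,
                         existingLabels = labs0)
  seg@boundaries <- cut$boundaries
  list(segmented = seg, field = field, loops = loops, hist = hist,
       selected = sel, constraints = constraints,
       parentFaces = cut$parentFaces, newVertexInfo = cut$newVertexInfo)
}

# When a new cut inserts vertices on edges that belong to an earlier
# boundary chain, splice those vertices into the chain so it remains a
# contiguous edge path of the newly refined mesh.
.spliceBoundaryChains <- function(chains, newVertexInfo, nvOld) {
  if (!length(chains) || !nrow(newVertexInfo)) return(chains)
  newIds <- nvOld + seq_len(nrow(newVertexInfo))
  nkey <- .edgeKey(newVertexInfo[, "lo"], newVertexInfo[, "hi"], nvOld)
  lapply(chains, function(ch) {
    vid <- ch$vertexIds
    n <- length(vid)
    a <- vid[-n]; b <- vid[-1L]
    if (isTRUE(ch$closed)) { a <- c(a, vid[n]); b <- c(b, vid[1L]) }
    pieces <- lapply(seq_along(a), function(i) {
      if (a[i] > nvOld || b[i] > nvOld) return(a[i])
      hits <- which(nkey == .edgeKey(a[i], b[i], nvOld))
      if (!length(hits)) return(a[i])
      par <- newVertexInfo[hits, "param"]
      if (a[i] > b[i]) par <- 1 - par
      c(a[i], newIds[hits][order(par)])
    })
    out <- unlist(pieces, use.names = FALSE)
    if (!isTRUE(ch$closed)) out <- c(out, vid[n])
    list(vertexIds = out, closed = isTRUE(ch$closed))
  })
}

# Order feature groups along the arch: start from the most eccentric
# representative, then rank by geodesic distance from it.
.orderGroupsAlongArch <- function(mesh, groups) {
  reps <- groups@representatives
  D <- matrix(0, length(reps), length(reps))
  for (i in seq_along(reps)) D[i, ] <- geodesicDistance(mesh, reps[i], reps)
  start <- which.max(apply(D, 1L, max))
  order(D[start, ])
}

#' Fully segment an arch with the minimal number of interactions
#'
#' Emulates an informed user: unlabeled teeth are clicked pairwise along the
#' arch (the click lands on the cusp of one unlabeled tooth, on the side of
#' its unlabeled neighbor, so that one interaction labels both); a leftover
#' odd tooth is clicked against its already-labeled neighbor. An N-tooth
#' arch is therefore fully labeled after ceiling(N / 2) interactions.
#'
#' @param mesh a [TriangleMesh-class] (or an [ArchFixture-class], whose mesh
#'   is used).
#' @param nTeeth known tooth count passed to the grouping step (`NULL` for
#'   automatic).
#' @param params a [FieldParams-class].
#' @param nLevels,nBins contour / histogram resolution.
#' @param featureRadius,occlusalAxis cusp-detector settings.
#' @param stVertex optional per-vertex attribute matrix (e.g. fixture chart
#'   coordinates) carried through refinement by edge interpolation.
#' @return list with `mesh` (final refined [TriangleMesh-class]),
#'   `faceLabels`, `boundaries`, `nClicks`, `clicks`, `parentFaces`
#'   (original-mesh face per final face) and `stVertex` (carried attributes,
#'   if given).
#' @export
segmentArch <- function(mesh, nTeeth = NULL, params = fieldParams(),
                        nLevels = 100L, nBins = 50L, featureRadius = 3,
                        occlusalAxis = c(0, 0, 1), stVertex = NULL) {
  if (is(mesh, "ArchFixture")) {
    if (is.null(stVertex)) stVertex <- mesh@params$st
    if (is.null(nTeeth)) nTeeth <- mesh@params$nTeeth
    mesh <- mesh@mesh
  }
  pts <- detectFeaturePoints(mesh, occlusalAxis, featureRadius)
  if (!length(pts)) .vstop("no feature points detected; cannot segment")
  groups <- groupFeaturePoints(mesh, pts, nGroups = nTeeth)
  ord <- .orderGroupsAlongArch(mesh, groups)
  glist <- groups@groups[ord]
  n <- length(glist)
  if (n < 2L)
    .vstop("need a neighboring tooth to constrain against (>= 2 feature groups)")

  concave <- .estimateGeometry(mesh, theta = params@theta)$concave

  # an informed user clicks on the target cusp cap, on the side of the
  # intended partner tooth, so that the partner is the next-nearest group
  clickTowards <- function(fromGroup, towardGroup) {
    patch <- expandConstraintSites(
      mesh, constraintSet(glist[[fromGroup]], glist[[towardGroup]]), 1.5,
      concaveFlags = concave)
    cand <- targetSites(patch)
    d <- vapply(cand, function(v)
      min(geodesicDistance(mesh, v, glist[[towardGroup]])), 1)
    cand[which.min(d)]
  }

  archGroups <- new("FeatureGroups", groups = glist,
                    representatives = vapply(glist, function(g)
                      .groupRepresentative(mesh, g), 1L))

  # phase 1: every interaction is solved on the pristine input mesh (one
  # field per click), exactly as an interactive session would do
  interactions <- list()
  done <- rep(FALSE, n)
  k <- 1L
  while (k <= n) {
    if (done[k]) { k <- k + 1L; next }
    partner <- if (k < n && !done[k + 1L]) k + 1L
               else if (k > 1L) k - 1L else k + 1L
    click <- clickTowards(k, partner)
    cs <- constraintsFromClick(mesh, click, archGroups)
    field <- .fieldOnMesh(mesh, cs, params)
    loops <- extractIsocontours(mesh, field, nLevels = nLevels)
    hist <- fieldHistogram(field, nBins = nBins)
    foreign <- setdiff(archGroups@representatives,
                       c(cs@targetSites, cs@backgroundSites))
    sel <- selectCutBoundaries(loops, hist,
                               protect = field@values[foreign])
    interactions[[length(interactions) + 1L]] <-
      list(click = click, constraints = cs, field = field@values,
           selected = Filter(Negate(is.null), list(sel$low, sel$high)))
    done[k] <- TRUE
    done[partner] <- TRUE
    k <- k + 1L
  }

  # phase 2: realize the selected level sets as cuts, sequentially. Each
  # click's piecewise-linear field is transferred exactly onto the
  # accumulated refined mesh (linear interpolation on split edges), so its
  # level sets are unchanged and every cut call works with a single field.
  cur <- mesh
  labels <- rep(0L, nrow(mesh@faces))
  parent <- seq_len(nrow(mesh@faces))
  allBoundaries <- list()
  fields <- lapply(interactions, function(x) x$field)
  for (ix in seq_along(interactions)) {
    it <- interactions[[ix]]
    u <- fields[[ix]]
    lvls <- unique(vapply(it$selected, function(l) l@level, 1))
    reLoops <- extractIsocontours(cur, u, levels = lvls)
    keep <- vapply(it$selected, function(orig) {
      cands <- which(vapply(reLoops, function(l)
        isTRUE(all.equal(l@level, orig@level)), TRUE))
      if (!length(cands)) return(NA_integer_)
      ref <- orig@points[1L, ]
      d <- vapply(cands, function(ci) {
        min(sqrt(rowSums((reLoops[[ci]]@points -
          matrix(ref, nrow(reLoops[[ci]]@points), 3L, byrow = TRUE))^2)))
      }, 1)
      cands[which.min(d)]
    }, 1L)
    chosen <- reLoops[keep[!is.na(keep)]]
    nvOld <- nrow(cur@vertices)
    fld <- new("SegmentationField", values = u, params = params,
               constraints = it$constraints)
    cut <- cutMeshAlongLoops(cur, chosen, field = fld)
    info <- cut$newVertexInfo
    if (nrow(info)) {
      fields <- lapply(fields, function(vals)
        c(vals, (1 - info[, "param"]) * vals[info[, "lo"]] +
            info[, "param"] * vals[info[, "hi"]]))
      if (!is.null(stVertex))
        stVertex <- rbind(stVertex,
          (1 - info[, "param"]) * stVertex[info[, "lo"], , drop = FALSE] +
            info[, "param"] * stVertex[info[, "hi"], , drop = FALSE])
    }
    allBoundaries <- .spliceBoundaryChains(allBoundaries, info, nvOld)
    seg <- propagateLabels(cut$mesh, c(cut$boundaries, allBoundaries),
                           it$constraints,
                           existingLabels = labels[cut$parentFaces])
    labels <- seg@faceLabels
    parent <- parent[cut$parentFaces]
    allBoundaries <- c(allBoundaries, cut$boundaries)
    cur <- cut$mesh
  }
  list(mesh = cur, faceLabels = labels, boundaries = allBoundaries,
       nClicks = length(interactions),
       clicks = vapply(interactions, function(x) x$click, 1L),
       parentFaces = parent, stVertex = stVertex)
}

#' Evaluate an arch segmentation against fixture ground truth
#'
#' Re-derives ground-truth labels from the fixture's parametric functions at
#' the final (refined) face centroids — using the chart coordinates carried
#' through every cut — and reports the area-weighted label agreement plus
#' the fraction of mismatched area lying inside the groove band.
#'
#' @param fixture the [ArchFixture-class] that produced the mesh.
#' @param archResult result list of [segmentArch()] run on the fixture.
#' @return list with `agreement`, `mismatchInBand`, `mismatch`, `truth`.
#' @export
evaluateArchSegmentation <- function(fixture, archResult) {
  stV <- archResult$stVertex
  if (is.null(stV)) .vstop("archResult carries no chart coordinates")
  f <- archResult$mesh@faces
  fc <- (stV[f[, 1L], , drop = FALSE] + stV[f[, 2L], , drop = FALSE] +
         stV[f[, 3L], , drop = FALSE]) / 3
  truth <- archGroundTruth(fixture, fc)
  areas <- .faceGeometry(archResult$mesh)$areas
  ag <- labelAgreement(archResult$faceLabels, truth$label, weights = areas)
  mm <- ag$mismatch
  inBand <- if (any(mm)) sum(areas[mm & truth$band]) / sum(areas[mm]) else 1
  list(agreement = ag$agreement, mismatchInBand = inBand,
       mismatch = mm, truth = truth)
}

#' Label agreement up to label permutation
#'
#' Matches predicted labels to reference labels greedily by shared face
#' count (label 0 is matched like any other) and reports the fraction of
#' faces whose matched label agrees with the reference, plus the per-face
#' mismatch mask.
#'
#' @param pred integer predicted label per face.
#' @param ref integer reference label per face.
#' @param weights optional per-face weights (e.g. areas); default 1.
#' @return list with `agreement` (weighted fraction), `mapping` (named
#'   vector pred -> ref) and `mismatch` (logical per face).
#' @export
labelAgreement <- function(pred, ref, weights = NULL) {
  pred <- as.integer(pred); ref <- as.integer(ref)
  if (length(pred) != length(ref)) .vstop("label vectors differ in length")
  if (is.null(weights)) weights <- rep(1, length(pred))
  tab <- tapply(weights, list(pred = pred, ref = ref), sum, default = 0)
  mapping <- integer(0)
  usedRef <- character(0)
  repeat {
    if (!length(tab) || all(tab <= 0)) break
    ij <- arrayInd(which.max(tab), dim(tab))
    p <- rownames(tab)[ij[1L]]; r <- colnames(tab)[ij[2L]]
    mapping[p] <- as.integer(r)
    usedRef <- c(usedRef, r)
    tab[ij[1L], ] <- -1
    tab[, ij[2L]] <- -1
  }
  mapped <- mapping[as.character(pred)]
  mapped[is.na(mapped)] <- -1L
  mismatch <- mapped != ref
  list(agreement = sum(weights[!mismatch]) / sum(weights),
       mapping = mapping, mismatch = mismatch)
}

#' Transfer face labels between meshes by nearest face centroid
#'
#' @param fromMesh,toMesh [TriangleMesh-class] objects.
#' @param fromLabels integer label per face of `fromMesh`.
#' @return integer label per face of `toMesh`.
#' @export
transferLabelsNearestFace <- function(fromMesh, fromLabels, toMesh) {
  cf <- .faceCentroids(fromMesh)
  ct <- .faceCentroids(toMesh)
  out <- integer(nrow(ct))
  chunk <- 2000L
  for (s in seq(1L, nrow(ct), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ct))
    block <- ct[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(cf))) +
      outer(rep(1, nrow(block)), rowSums(cf^2)) -
      2 * block %*% t(cf)
    out[s:e] <- fromLabels[max.col(-d2, ties.method = "first")]
  }
  out
}

.faceCentroids <- function(mesh) {
  (mesh@vertices[mesh@faces[, 1L], , drop = FALSE] +
   mesh@vertices[mesh@faces[, 2L], , drop = FALSE] +
   mesh@vertices[mesh@faces[, 3L], , drop = FALSE]) / 3
}

# ---- CLI-facing entry points -------------------------------------------------

.validateRunConfig <- function(config, needConstraints = TRUE) {
  if (is.null(config$input)) .vstop("config needs an input path")
  if (needConstraints) {
    hasClick <- !is.null(config$click)
    hasFile <- !is.null(config$constraints)
    if (hasClick && hasFile)
      .vstop("click and constraint file are mutually exclusive")
    if (!hasClick && !hasFile)
      .vstop("provide exactly one of click / constraint file")
  }
  invisible(config)
}

.configParams <- function(config) {
  fieldParams(alpha = config$alpha %||% 1e8,
              beta = config$beta %||% 0.01,
              gamma = config$gamma %||% 1e-4,
              theta = config$theta %||% 1e-3)
}

.resolveClick <- function(mesh, click) {
  if (length(click) == 3L) {
    d2 <- rowSums((mesh@vertices -
                   matrix(as.numeric(click), nrow(mesh@vertices), 3L,
                          byrow = TRUE))^2)
    which.min(d2)
  } else as.integer(click)
}

#' Run the end-to-end segmentation (CLI backend)
#'
#' Reads the input mesh, derives constraints from the click (via feature
#' detection and grouping) or from a constraint file, runs the per-click
#' pipeline, and writes the colored PLY plus the JSON label map. Per-stage
#' counts are logged to stderr.
#'
#' @param config list: `input`, `output`, one of `click` (vertex id or 3D
#'   point) / `constraints` (CSV/JSON path), optional `alpha`, `beta`,
#'   `gamma`, `theta`, `levels`, `bins`, `featureRadius`, `logLevel`.
#' @return the [SegmentedMesh-class], invisibly.
#' @export
runSegment <- function(config) {
  .validateRunConfig(config)
  quiet <- identical(config$logLevel, "quiet")
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  mesh <- readMesh(config$input)
  say("stage=read vertices=%d faces=%d", nrow(mesh@vertices), nrow(mesh@faces))
  params <- .configParams(config)
  cs <- NULL; click <- NULL
  if (!is.null(config$constraints)) {
    cs <- readConstraints(config$constraints)
    say("stage=constraints target=%d background=%d",
        length(cs@targetSites), length(cs@backgroundSites))
  } else {
    click <- .resolveClick(mesh, config$click)
    say("stage=click vertex=%d", click)
  }
  res <- segmentTooth(mesh, click = click, constraints = cs, params = params,
                      nLevels = config$levels %||% 100L,
                      nBins = config$bins %||% 50L,
                      featureRadius = config$featureRadius %||% 3)
  say("stage=contours loops=%d", length(res$loops))
  say("stage=select low=%s high=%s",
      !is.null(res$selected$low), !is.null(res$selected$high))
  seg <- res$segmented
  say("stage=cut faces=%d labels=%d", nrow(seg@mesh@faces),
      length(unique(seg@faceLabels)))
  if (!is.null(config$output)) {
    writeSegmentedMesh(seg@mesh, seg@faceLabels, config$output)
    say("stage=write output=%s", config$output)
  }
  invisible(seg)
}

#' Solve and dump the segmentation field only (CLI backend)
#'
#' Writes the per-vertex field as a CSV (`vertex_id,u`) and, when the output
#' path ends in `.ply`, a vertex-colored PLY (red at 0 through blue at 1)
#' for external inspection.
#'
#' @param config list as in [runSegment()]; `output` receives the CSV (a
#'   `.ply` sibling is written when `output` has the `.ply` extension).
#' @return the [SegmentationField-class], invisibly.
#' @export
runFieldOnly <- function(config) {
  .validateRunConfig(config)
  mesh <- readMesh(config$input)
  params <- .configParams(config)
  if (!is.null(config$constraints)) {
    cs <- readConstraints(config$constraints)
  } else {
    click <- .resolveClick(mesh, config$click)
    pts <- detectFeaturePoints(mesh, config$occlusalAxis %||% c(0, 0, 1),
                               config$featureRadius %||% 3)
    groups <- groupFeaturePoints(mesh, pts)
    cs <- constraintsFromClick(mesh, click, groups)
  }
  field <- .fieldOnMesh(mesh, cs, params)
  if (!is.null(config$output)) {
    out <- config$output
    csv <- if (tolower(tools::file_ext(out)) == "csv") out
           else sub("\\.[^.]*$", ".csv", out)
    writeFieldCSV(field, csv)
    if (tolower(tools::file_ext(out)) == "ply") {
      u <- field@values
      rgbv <- cbind(round(255 * (1 - u)), 0L, round(255 * u))
      v <- mesh@vertices; f <- mesh@faces
      lines <- c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 "property uchar red", "property uchar green", "property uchar blue",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header",
                 sprintf("%.17g %.17g %.17g %d %d %d",
                         v[, 1], v[, 2], v[, 3],
                         rgbv[, 1], rgbv[, 2], rgbv[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
      writeLines(lines, out)
    }
  }
  invisible(field)
}

#' Write / read a segmentation field as CSV
#'
#' @param field a [SegmentationField-class].
#' @param path CSV path with columns `vertex_id,u`.
#' @return path (write); a [SegmentationField-class] with empty constraint
#'   slots (read).
#' @export
writeFieldCSV <- function(field, path) {
  write.csv(data.frame(vertex_id = seq_along(field@values), u = field@values),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @export
readFieldCSV <- function(path) {
  df <- read.csv(path)
  new("SegmentationField",
      values = df$u[order(df$vertex_id)],
      params = fieldParams(), constraints = constraintSet())
}
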