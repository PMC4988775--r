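# Radial profile of one Gaussian cap, z(rho) = H exp(-rho^2 / (2 sigma^2)).
# The ground-truth tooth boundary sits where a seam-seeking field changes
# most abruptly -- the operational definition of a cutting boundary in this
# framework. For an axisymmetric cap with concavity-aware resistivity
# proportional to 2|K| + gamma (K the Gaussian curvature of the profile),
# the radial drop density of a harmonic field flowing off the cap is that
# resistivity divided by the circumference, so the seam ring is
# argmax (2|K(rho)| + gamma) / rho over the concave annulus (rho > sigma),
# expressed as the relative cap contribution tau = exp(-rho*^2/(2 sigma^2)).
# This is a property of the generating surface and the weighting model, not
# of any discrete pipeline.
.capBoundaryContribution <- function(height, sigma, gamma = 1e-4) {
  rho <- seq(sigma * 1.001, 4 * sigma, length.out = 2000L)
  z1 <- -(height / sigma^2) * rho * exp(-rho^2 / (2 * sigma^2))
  z2 <- (height / sigma^2) * (rho^2 / sigma^2 - 1) * exp(-rho^2 / (2 * sigma^2))
  kRad <- z2 / (1 + z1^2)^1.5
  kCirc <- z1 / (rho * sqrt(1 + z1^2))
  K <- kRad * kCirc
  rstar <- rho[which.max((2 * abs(K) + gamma) / rho)]
  exp(-rstar^2 / (2 * sigma^2))
}

# Truncated Gaussian cap: the Gaussian bell multiplied by a C2 smoothstep
# window that fades to exactly zero over rho in [2.0, 2.6] sigma, so the
# base strip beyond the caps is exactly flat (near-equipotential gingiva,
# as on a real arch where the gum forms one connected smooth region). The
# window is wide enough that its own curvature stays well below the groove
# curvature at the cutting locus.
.capProfile <- function(rho2, sigma) {
  g <- exp(-rho2 / (2 * sigma^2))
  rho <- sqrt(rho2)
  t <- pmin(1, pmax(0, (rho - 2.2 * sigma) / (0.8 * sigma)))
  w <- 1 - (6 * t^5 - 15 * t^4 + 10 * t^3)
  g * w
}

# Per-point ground truth from the parametric chart: bump contributions,
# label (0 base / k tooth), groove-band membership.
.archTruth <- function(st, params) {
  s <- st[, 1L]; t <- st[, 2L]
  ctr <- params$centers
  tmid <- params$width / 2
  G <- vapply(ctr, function(ck) {
    .capProfile((s - ck)^2 + (t - tmid)^2, params$sigma)
  }, numeric(length(s)))
  G <- matrix(G, nrow = length(s))
  ord1 <- max.col(G, ties.method = "first")
  m1 <- G[cbind(seq_along(s), ord1)]
  m2 <- if (ncol(G) >= 2L) {
    G2 <- G
    G2[cbind(seq_along(s), ord1)] <- -Inf
    apply(G2, 1L, max)
  } else rep(0, length(s))
  label <- ifelse(m1 >= params$tau, ord1, 0L)
  band <- (m1 >= 0.05 & m1 <= 0.5) | (m1 > 0.05 & m2 >= 0.5 * m1)
  list(label = as.integer(label), band = band, m1 = m1, m2 = m2,
       zsum = rowSums(G))
}

#' Generate a synthetic dental arch fixture
#'
#' A gently bent base strip carrying `nTeeth` rotationally symmetric Gaussian
#' caps ("teeth") separated by concave grooves, triangulated at the target
#' edge length. Ground-truth per-face labels and the groove-band mask come
#' from the generating parametric functions, so they remain exact at any
#' tessellation. The `crowding` factor shrinks the tooth pitch, emulating
#' mild to severe crowding; regeneration with the same parameters is
#' bit-identical.
#'
#' @param nTeeth number of teeth (>= 2).
#' @param resolution target edge length in mm (default 0.4).
#' @param crowding crowding severity in (0, 1]: tooth pitch =
#'   8 mm * (0.7 + 0.3 * crowding), so 1 gives well-separated teeth and
#'   small values narrow the interstices while the caps remain individual
#'   bumps (as in a crowded dentition, where teeth touch but do not fuse).
#'   Pitches that would merge adjacent caps (pitch <= 2.2 sigma) are
#'   rejected.
#' @param seed integer seed used by the optional noise displacement.
#' @param noiseSigmaRel Gaussian vertex-noise standard deviation as a
#'   fraction of the mean edge length (default 0, no noise).
#' @param toothHeight cap height in mm.
#' @param sigma cap standard deviation in mm.
#' @param width strip width in mm.
#' @param margin flat margin beyond the outermost teeth in mm.
#' @return an [ArchFixture-class].
#' @export
makeArch <- function(nTeeth = 4L, resolution = 0.4, crowding = 1.0,
                     seed = 1L, noiseSigmaRel = 0,
                     toothHeight = 4, sigma = 2, width = 16, margin = 4) {
  nTeeth <- as.integer(nTeeth)
  if (nTeeth < 2L) .vstop("nTeeth must be >= 2")
  if (resolution <= 0) .vstop("resolution must be > 0")
  if (crowding <= 0 || crowding > 1) .vstop("crowding must lie in (0, 1]")
  pitch <- 8 * (0.7 + 0.3 * crowding)
  if (pitch <= 2.2 * sigma)
    .vstop("crowding %.3g merges adjacent caps beyond groove resolution (pitch %.3g <= %.3g)",
           crowding, pitch, 2.2 * sigma)
  L <- 2 * margin + nTeeth * pitch
  centers <- margin + (seq_len(nTeeth) - 0.5) * pitch
  ns <- max(3L, as.integer(round(L / resolution)))
  nt <- max(3L, as.integer(round(width / resolution)))
  sv <- seq(0, L, length.out = ns + 1L)
  tv <- seq(0, width, length.out = nt + 1L)
  st <- cbind(rep(sv, times = nt + 1L), rep(tv, each = ns + 1L))

  params <- list(nTeeth = nTeeth, resolution = resolution, crowding = crowding,
                 seed = as.integer(seed), noiseSigmaRel = noiseSigmaRel,
                 toothHeight = toothHeight, sigma = sigma, width = width,
                 margin = margin, pitch = pitch, length = L,
                 centers = centers,
                 tau = .capBoundaryContribution(toothHeight, sigma))

  truthV <- .archTruth(st, params)
  z <- toothHeight * truthV$zsum
  R <- 2 * L
  phi <- st[, 1L] / R
  r <- R - (st[, 2L] - width / 2)
  verts <- cbind(r * sin(phi), R - r * cos(phi), z)

  # grid faces, alternating diagonal by quad parity
  i <- rep(seq_len(ns), times = nt)
  j <- rep(seq_len(nt), each = ns)
  v00 <- (j - 1L) * (ns + 1L) + i
  v10 <- v00 + 1L
  v01 <- v00 + (ns + 1L)
  v11 <- v01 + 1L
  even <- (i + j) %% 2L == 0L
  fA1 <- cbind(v00, v10, v11); fA2 <- cbind(v00, v11, v01)
  fB1 <- cbind(v00, v10, v01); fB2 <- cbind(v10, v11, v01)
  faces <- rbind(fA1[even, , drop = FALSE], fA2[even, , drop = FALSE],
                 fB1[!even, , drop = FALSE], fB2[!even, , drop = FALSE])

  mesh <- triangleMesh(verts, faces)
  if (noiseSigmaRel > 0)
    mesh <- addVertexNoise(mesh, noiseSigmaRel, seed = seed)

  fcs <- (st[mesh@faces[, 1L], , drop = FALSE] +
          st[mesh@faces[, 2L], , drop = FALSE] +
          st[mesh@faces[, 3L], , drop = FALSE]) / 3
  truthF <- .archTruth(fcs, params)
  params$st <- st
  new("ArchFixture", mesh = mesh, faceLabels = truthF$label,
      grooveBand = truthF$band, params = params)
}

#' Ground truth of an arch fixture at arbitrary chart points
#'
#' Evaluates the generating parametric functions at the given (s, t) chart
#' coordinates, so labels can be re-derived for refined or decimated meshes.
#'
#' @param fixture an [ArchFixture-class] (or its `params` list).
#' @param st two-column matrix of chart coordinates.
#' @return list with `label`, `band`, and the largest/second-largest relative
#'   cap contributions `m1`, `m2`.
#' @export
archGroundTruth <- function(fixture, st) {
  params <- if (is(fixture, "ArchFixture")) fixture@params else fixture
  .archTruth(as.matrix(st), params)
}

#' @rdname segAccessors
#' @export
setMethod("faceLabels", "ArchFixture", function(x) x@faceLabels)

#' @rdname segAccessors
#' @export
setMethod("grooveBand", "ArchFixture", function(x) x@grooveBand)

#' @rdname meshAccessors
#' @export
setMethod("meshVertices", "ArchFixture", function(x) x@mesh@vertices)

setMethod("show", "ArchFixture", function(object) {
  cat(sprintf(
    "ArchFixture: %d teeth, crowding %.2g, noise %.2g; %d vertices, %d faces (%d groove-band)\n",
    object@params$nTeeth, object@params$crowding, object@params$noiseSigmaRel,
    nrow(object@mesh@vertices), nrow(object@mesh@faces),
    sum(object@grooveBand)))
})

#' Add i.i.d. Gaussian vertex noise
#'
#' Displaces every vertex by an isotropic zero-mean Gaussian offset with
#' standard deviation `sigmaRel` times the mean edge length (the usual
#' mesh-noise protocol quoted in mean-edge-length units). Connectivity is
#' unchanged; the RNG state of the session is restored afterwards.
#'
#' @param mesh a [TriangleMesh-class].
#' @param sigmaRel noise standard deviation as a fraction of mean edge length.
#' @param seed integer seed; the same seed reproduces the same displacement.
#' @param mode `"isotropic"` (default) displaces in 3D; `"normal"` displaces
#'   along vertex normals only.
#' @return a displaced [TriangleMesh-class].
#' @export
addVertexNoise <- function(mesh, sigmaRel, seed = 1L,
                           mode = c("isotropic", "normal")) {
  mode <- match.arg(mode)
  if (sigmaRel < 0) .vstop("sigmaRel must be >= 0")
  if (sigmaRel == 0) return(mesh)
  sd <- sigmaRel * mean(mesh@edgeLengths)
  nv <- nrow(mesh@vertices)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  if (mode == "isotropic") {
    disp <- matrix(rnorm(3L * nv, sd = sd), nv, 3L)
  } else {
    nrm <- vertexNormals(mesh)
    disp <- nrm * rnorm(nv, sd = sd)
  }
  triangleMesh(mesh@vertices + disp, mesh@faces)
}

#' Decimate an arch fixture by edge collapse
#'
#' Repeated shortest-edge collapses (midpoint placement, interior edges only,
#' link-condition guarded) until the face count reaches `targetFaces`.
#' Ground-truth labels and the groove band are re-derived from the parametric
#' functions at the decimated face centroids, not carried over.
#'
#' @param fixture an [ArchFixture-class].
#' @param targetFaces target face count (>= 100, below the current count).
#' @return a decimated [ArchFixture-class].
#' @export
decimateFixture <- function(fixture, targetFaces) {
  targetFaces <- as.integer(targetFaces)
  if (targetFaces < 100L) .vstop("targetFaces must be >= 100")
  mesh <- fixture@mesh
  if (targetFaces >= nrow(mesh@faces))
    .vstop("targetFaces (%d) must be below the current face count (%d)",
           targetFaces, nrow(mesh@faces))
  dec <- .edgeCollapseDecimate(mesh@vertices, mesh@faces,
                               fixture@params$st, targetFaces)
  mesh2 <- triangleMesh(dec$vertices, dec$faces)
  params <- fixture@params
  params$st <- dec$st
  params$resolution <- params$resolution *
    sqrt(nrow(mesh@faces) / nrow(mesh2@faces))
  fcs <- (dec$st[mesh2@faces[, 1L], , drop = FALSE] +
          dec$st[mesh2@faces[, 2L], , drop = FALSE] +
          dec$st[mesh2@faces[, 3L], , drop = FALSE]) / 3
  truthF <- .archTruth(fcs, params)
  new("ArchFixture", mesh = mesh2, faceLabels = truthF$label,
      grooveBand = truthF$band, params = params)
}

# Plain edge-collapse decimation on (vertices, faces) with an attribute
# matrix `st` carried by midpoint averaging. Interior edges only (the open
# rim is preserved); collapses that would break the link condition are
# skipped.
.edgeCollapseDecimate <- function(V, F, st, targetFaces) {
  V <- as.matrix(V); F <- as.matrix(F); st <- as.matrix(st)
  nfAlive <- nrow(F)
  faceAlive <- rep(TRUE, nrow(F))

  vertFaces <- function(F, faceAlive, nv) {
    idx <- c(F[faceAlive, 1L], F[faceAlive, 2L], F[faceAlive, 3L])
    fid <- rep(which(faceAlive), 3L)
    split(fid, idx)
  }

  repeat {
    if (nfAlive <= targetFaces) break
    FA <- F[faceAlive, , drop = FALSE]
    nv <- nrow(V)
    he <- rbind(FA[, c(1L, 2L)], FA[, c(2L, 3L)], FA[, c(3L, 1L)])
    keys <- .edgeKey(he[, 1L], he[, 2L], nv)
    cnt <- table(keys)
    boundaryKeys <- as.numeric(names(cnt)[cnt == 1L])
    bverts <- logical(nv)
    if (length(boundaryKeys)) {
      lo <- floor((boundaryKeys - 1) / nv) + 1
      bverts[c(lo, boundaryKeys - (lo - 1) * nv)] <- TRUE
    }
    ukeys <- as.numeric(names(cnt))
    elo <- as.integer(floor((ukeys - 1) / nv) + 1)
    ehi <- as.integer(ukeys - (elo - 1) * nv)
    interior <- !bverts[elo] & !bverts[ehi]
    if (!any(interior)) break
    elo <- elo[interior]; ehi <- ehi[interior]
    elen <- sqrt(rowSums((V[elo, , drop = FALSE] - V[ehi, , drop = FALSE])^2))
    ord <- order(elen)

    vf <- vertFaces(F, faceAlive, nv)
    neighborSets <- function(v) {
      fs <- vf[[as.character(v)]]
      if (is.null(fs)) integer(0) else setdiff(unique(as.vector(F[fs, ])), v)
    }
    dirty <- logical(nv)
    collapsedAny <- FALSE
    for (k in ord) {
      if (nfAlive <= targetFaces) break
      a <- elo[[k]]; b <- ehi[[k]]
      if (dirty[a] || dirty[b]) next
      fsA <- vf[[as.character(a)]]; fsB <- vf[[as.character(b)]]
      if (is.null(fsA) || is.null(fsB)) next
      shared <- intersect(fsA, fsB)
      shared <- shared[faceAlive[shared]]
      if (length(shared) != 2L) next     # interior edge must have 2 faces
      nbA <- neighborSets(a); nbB <- neighborSets(b)
      opp <- setdiff(unique(as.vector(F[shared, ])), c(a, b))
      if (!setequal(intersect(nbA, nbB), opp)) next   # link condition
      # collapse b into a at the midpoint
      V[a, ] <- (V[a, ] + V[b, ]) / 2
      st[a, ] <- (st[a, ] + st[b, ]) / 2
      faceAlive[shared] <- FALSE
      nfAlive <- nfAlive - length(shared)
      replFaces <- setdiff(fsB, shared)
      replFaces <- replFaces[faceAlive[replFaces]]
      F[replFaces, ][F[replFaces, , drop = FALSE] == b] <- a
      dirty[c(a, b, nbA, nbB)] <- TRUE
      collapsedAny <- TRUE
    }
    if (!collapsedAny) break
  }

  FA <- F[faceAlive, , drop = FALSE]
  used <- sort(unique(as.vector(FA)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  list(vertices = V[used, , drop = FALSE],
       faces = matrix(remap[FA], ncol = 3L),
       st = st[used, , drop = FALSE])
}

#' Export a fixture as PLY plus JSON ground truth
#'
#' @param fixture an [ArchFixture-class].
#' @param path output PLY path; ground truth goes to `<path>.truth.json`.
#' @return the path, invisibly.
#' @export
writeFixture <- function(fixture, path) {
  writeSegmentedMesh(fixture@mesh, fixture@faceLabels, path)
  jsonlite::write_json(
    list(faceLabels = fixture@faceLabels,
         grooveBand = fixture@grooveBand,
         params = fixture@params[setdiff(names(fixture@params), "st")]),
    paste0(path, ".truth.json"), auto_unbox = TRUE)
  invisible(path)
}
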