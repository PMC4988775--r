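# Mesh fixtures built in code: grids, platonic solids, spheres, tori,
# little file writers. All deterministic.

# planar (or height-field) grid on [0, lx] x [0, ly], CCW from +z
makeGridMesh <- function(nx, ny, fz = function(x, y) rep(0, length(x)),
                         lx = 1, ly = 1) {
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  st <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  V <- cbind(st, fz(st[, 1], st[, 2]))
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  triangleMesh(V, rbind(cbind(v00, v10, v11), cbind(v00, v11, v01)))
}

# regular tetrahedron with unit edge length, outward CCW faces
makeRegularTetra <- function() {
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangleMesh(V, F)
}

# icosphere: subdivided icosahedron projected to the unit sphere
makeIcosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    newF <- matrix(0L, 0L, 3L)
    mid <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid[[key]] <- nrow(V)
      nrow(V)
    }
    for (fi in seq_len(nrow(F))) {
      a <- F[fi, 1]; b <- F[fi, 2]; c <- F[fi, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    F <- newF
  }
  triangleMesh(V, F)
}

# closed torus, outward orientation
makeTorus <- function(nu = 24, nv = 12, R = 2, r = 0.7) {
  us <- (seq_len(nu) - 1) / nu * 2 * pi
  vs <- (seq_len(nv) - 1) / nv * 2 * pi
  uu <- rep(us, times = nv)
  vv <- rep(vs, each = nu)
  V <- cbind((R + r * cos(vv)) * cos(uu), (R + r * cos(vv)) * sin(uu),
             r * sin(vv))
  id <- function(i, j) ((j - 1) %% nv) * nu + ((i - 1) %% nu) + 1
  i <- rep(seq_len(nu), nv)
  j <- rep(seq_len(nv), each = nu)
  v00 <- id(i, j); v10 <- id(i + 1, j); v01 <- id(i, j + 1); v11 <- id(i + 1, j + 1)
  triangleMesh(V, rbind(cbind(v00, v10, v11), cbind(v00, v11, v01)))
}

# unit cube as a 12-facet STL soup (duplicated corners)
cubeFacets <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  do.call(rbind, lapply(quads, function(q) {
    rbind(V[q[1], ], V[q[2], ], V[q[3], ],
          V[q[1], ], V[q[3], ], V[q[4], ])
  }))
}

writeCubeSTLAscii <- function(path) {
  tri <- cubeFacets()
  lines <- c("solid cube")
  for (k in seq_len(nrow(tri) / 3)) {
    p <- tri[(3 * k - 2):(3 * k), , drop = FALSE]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               sprintf("vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
}

writeCubeSTLBinary <- function(path) {
  tri <- cubeFacets()
  ntri <- nrow(tri) / 3
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  for (k in seq_len(ntri)) {
    p <- tri[(3 * k - 2):(3 * k), , drop = FALSE]
    writeBin(as.numeric(c(0, 0, 0, t(p))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}

writeBinaryPLY <- function(path, V, F) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(t(V)), con, size = 4L, endian = "little")
  for (k in seq_len(nrow(F))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(F[k, ] - 1L), con, size = 4L, endian = "little")
  }
}

# brute-force all-pairs shortest path over an edge list (independent oracle)
floydWarshall <- function(edges, weights, n) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    D[a, b] <- min(D[a, b], weights[k])
    D[b, a] <- D[a, b]
  }
  for (m in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n))
    if (D[a, m] + D[m, b] < D[a, b]) D[a, b] <- D[a, m] + D[m, b]
  D
}

# minimal valid contour loop for selection tests
makeStubLoop <- function(level, score, closed = FALSE, length = 1) {
  pts <- rbind(c(0, 0, 0), c(length, 0, 0), c(length, length, 0))
  np <- if (closed) 3L else 2L
  new("ContourLoop", level = level, points = pts[seq_len(np), , drop = FALSE],
      edgeIds = seq_len(np), edgeParams = rep(0.5, np),
      faceIds = seq_len(if (closed) np else np - 1L),
      closed = closed, length = length, score = score)
}

faceAreasOf <- function(mesh) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

# grid on [0,1]^2 whose triangulation is symmetric under x -> 1-x:
# quads left of center use one diagonal, mirrored quads the other
makeMirrorGrid <- function(nx, ny, fz = function(x, y) rep(0, length(x))) {
  stopifnot((nx - 1) %% 2 == 0)
  xs <- seq(0, 1, length.out = nx)
  ys <- seq(0, 1, length.out = ny)
  st <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  V <- cbind(st, fz(st[, 1], st[, 2]))
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i; v10 <- v00 + 1L
  v01 <- v00 + nx; v11 <- v01 + 1L
  left <- i <= (nx - 1) / 2
  F <- rbind(cbind(v00[left], v10[left], v11[left]),
             cbind(v00[left], v11[left], v01[left]),
             cbind(v10[!left], v11[!left], v01[!left]),
             cbind(v10[!left], v01[!left], v00[!left]))
  triangleMesh(V, F)
}

# small noisy grid for property tests
randomJitteredGrid <- function(seed, nx = 7, ny = 7) {
  set.seed(seed)
  m <- makeGridMesh(nx, ny, fz = function(x, y) 0.15 * sin(3 * x) * cos(2 * y))
  m
}

# cache expensive fixtures across test files
.fixtureCache <- new.env()
cachedArch <- function(key, ...) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- makeArch(...)
  .fixtureCache[[key]]
}
arch4 <- function() cachedArch("arch4", nTeeth = 4, resolution = 0.4)
arch2 <- function() cachedArch("arch2", nTeeth = 2, resolution = 0.4)
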