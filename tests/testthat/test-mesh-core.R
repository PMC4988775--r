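test_that("tetrahedron has the simplex counts and valid structure", {
  m <- makeRegularTetra()
  expect_equal(nVertices(m), 4L)
  expect_equal(nFaces(m), 4L)
  expect_equal(nrow(meshEdges(m)), 6L)
  expect_true(all(edgeLengths(m) > 0))
  expect_equal(unname(edgeLengths(m)), rep(1, 6), tolerance = 1e-12)
})

test_that("degenerate and non-manifold meshes are rejected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  expect_error(triangleMesh(V, rbind(c(1, 1, 2))), "degenerate",
               class = "toothFieldValidationError")
  expect_error(triangleMesh(V, rbind(c(1, 2, 6))), "indices")
  # three faces sharing one edge
  expect_error(triangleMesh(V, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))),
               "non-manifold", class = "toothFieldValidationError")
})

test_that("vertex normals are area-weighted, unit, and orientation-covariant", {
  flat <- makeGridMesh(6, 6)
  nrm <- vertexNormals(flat)
  expect_equal(nrm, matrix(rep(c(0, 0, 1), each = 36), 36, 3),
               tolerance = 1e-12)

  sph <- makeIcosphere(3)
  nrm <- vertexNormals(sph)
  radial <- meshVertices(sph) / sqrt(rowSums(meshVertices(sph)^2))
  ang <- acos(pmin(1, rowSums(nrm * radial)))
  expect_lt(max(ang) * 180 / pi, 5)

  flipped <- triangleMesh(meshVertices(sph), meshFaces(sph)[, c(1, 3, 2)])
  expect_equal(vertexNormals(flipped), -nrm, tolerance = 1e-12)

  # isolated vertex has no normal
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  expect_error(vertexNormals(triangleMesh(V, rbind(c(1, 2, 3)))),
               "isolated", class = "toothFieldValidationError")
})

test_that("Gaussian curvature: flat interiors, tetra apex, Gauss-Bonnet", {
  flat <- makeGridMesh(6, 6)
  K <- gaussianCurvature(flat)
  interior <- setdiff(seq_len(36), which(ToothField:::.boundaryVertices(flat)))
  expect_equal(K[interior], rep(0, length(interior)), tolerance = 1e-12)

  # regular unit-edge tetrahedron: deficit 2*pi - 3*(pi/3) = pi at each
  # vertex, barycentric area = (3 equilateral faces / 3) = sqrt(3)/4
  tet <- makeRegularTetra()
  K <- gaussianCurvature(tet)
  expect_equal(K, rep(pi / (sqrt(3) / 4), 4), tolerance = 1e-12)

  # Gauss-Bonnet on closed surfaces: raw deficit sum = 2*pi*chi
  expect_equal(sum(gaussianCurvature(makeIcosphere(2), raw = TRUE)), 4 * pi,
               tolerance = 1e-9)
  expect_equal(sum(gaussianCurvature(makeTorus(), raw = TRUE)), 0,
               tolerance = 1e-9)
})

test_that("normals and curvature are invariant under rigid motion", {
  m <- randomJitteredGrid(1)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  m2 <- triangleMesh(meshVertices(m) %*% t(R) +
                       matrix(c(3, -2, 5), nVertices(m), 3, byrow = TRUE),
                     meshFaces(m))
  expect_equal(gaussianCurvature(m2), gaussianCurvature(m), tolerance = 1e-9)
  expect_equal(vertexNormals(m2), vertexNormals(m) %*% t(R), tolerance = 1e-9)
})

test_that("geodesic distances match brute-force shortest paths", {
  m <- randomJitteredGrid(2, 5, 5)
  D <- floydWarshall(meshEdges(m), edgeLengths(m), nVertices(m))
  for (src in c(1L, 7L, 25L)) {
    expect_equal(geodesicDistance(m, src, seq_len(nVertices(m))), D[src, ],
                 tolerance = 1e-12)
  }
  expect_identical(geodesicDistance(m, 3L, c(3L, 5L))[1], 0)
  # triangle inequality
  d1 <- geodesicDistance(m, 1L, seq_len(nVertices(m)))
  d9 <- geodesicDistance(m, 9L, seq_len(nVertices(m)))
  expect_true(all(d1 <= d1[9] + d9 + 1e-12))
})

test_that("disconnected targets get +Inf, not an error", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  m <- triangleMesh(V, rbind(c(1, 2, 3), c(4, 5, 6)))
  d <- geodesicDistance(m, 1L, c(2L, 4L))
  expect_lt(d[1], Inf)
  expect_identical(d[2], Inf)
})

test_that("field smoothing preserves constants and contracts to the mean", {
  m <- makeGridMesh(8, 8)
  expect_equal(smoothVertexField(m, rep(3.5, 64), 5), rep(3.5, 64))
  set.seed(1)
  v <- rnorm(64)
  s <- smoothVertexField(m, v, 10)
  expect_lt(diff(range(s)), diff(range(v)))
})
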