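# direct arithmetic oracle for the concavity inequality on one edge:
# dot((v_i - v_adj)/|v_i - v_adj|, n_adj - n_i) compared against theta
test_that("concave-vertex detection matches the arithmetic oracle", {
  m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  up <- c(0, 0, 1)
  tilt <- c(-0.70711, 0, 0.70711)
  tilt <- tilt / sqrt(sum(tilt^2))
  # valley: neighbor normal tilts toward vertex 1 -> dot = +0.70711 > theta
  flags <- detectConcaveVertices(m, rbind(up, tilt, up), theta = 0.001)
  expect_true(flags[1])
  # convex ridge: normals swapped -> dot = -0.70711, nothing concave
  flags <- detectConcaveVertices(m, rbind(tilt, up, up), theta = 0.001)
  expect_false(any(flags))
  # flat grid: all normals equal -> dot = 0 <= theta everywhere
  flat <- makeGridMesh(5, 5)
  expect_false(any(detectConcaveVertices(flat, vertexNormals(flat))))
})

test_that("edge weights follow the concavity-aware scheme with defaults", {
  m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  e <- meshEdges(m)
  k12 <- which(e[, 1] == 1 & e[, 2] == 2)
  zeroK <- rep(0, 3)
  # |e|=1, G_i=G_j=0, no concavity: 1 / gamma = 10000
  w <- edgeWeights(m, zeroK, rep(FALSE, 3))
  expect_equal(w[k12], 10000)
  # concave endpoint: attenuated by beta -> 100
  w <- edgeWeights(m, zeroK, c(TRUE, FALSE, FALSE))
  expect_equal(w[k12], 100)
  expect_true(all(w > 0))
  # symmetric in the endpoints: flag on the other end gives the same weight
  w2 <- edgeWeights(m, zeroK, c(FALSE, TRUE, FALSE))
  expect_equal(w2[k12], w[k12])
})

test_that("Laplacian assembly matches hand assembly and is PSD", {
  L <- ToothField:::.laplacianFromEdges(rbind(c(1L, 2L), c(2L, 3L)),
                                        c(2, 3), 3L)
  expect_equal(as.matrix(L),
               rbind(c(2, -2, 0), c(-2, 5, -3), c(0, -3, 3)),
               ignore_attr = TRUE)
  m <- randomJitteredGrid(4)
  set.seed(4)
  w <- runif(nrow(meshEdges(m)), 0.1, 5)
  L <- assembleLaplacian(m, w)
  expect_equal(max(abs(Matrix::rowSums(L))), 0, tolerance = 1e-12)
  for (k in 1:10) {
    x <- rnorm(nVertices(m))
    expect_gte(as.numeric(x %*% (L %*% x)), -1e-10)
  }
  expect_error(assembleLaplacian(m, w[-1]), class = "toothFieldValidationError")
})

test_that("the 3-vertex path solves to the harmonic closed form", {
  L <- ToothField:::.laplacianFromEdges(rbind(c(1L, 2L), c(2L, 3L)),
                                        c(1, 1), 3L)
  f <- solveField(L, constraintSet(1L, 3L))
  expect_equal(fieldValues(f), c(0, 0.5, 1), tolerance = 1e-6)
  # zero right-hand-side mode: all prescribed values 0 -> u identically 0
  f0 <- solveField(L, constraintSet(1L, 3L), backgroundValue = 0)
  expect_equal(fieldValues(f0), rep(0, 3), tolerance = 1e-9)
})

test_that("solver enforces constraint-set preconditions", {
  L <- ToothField:::.laplacianFromEdges(rbind(c(1L, 2L)), 1, 2L)
  expect_error(solveField(L, constraintSet(integer(), 2L)),
               "both boundary conditions", class = "toothFieldValidationError")
  expect_error(constraintSet(1L, 1L))
})

test_that("unconstrained components get 0.5 with a warning", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  m <- triangleMesh(V, rbind(c(1, 2, 3), c(4, 5, 6)))
  L <- assembleLaplacian(m, rep(1, nrow(meshEdges(m))))
  expect_warning(f <- solveField(L, constraintSet(1L, 2L)),
                 "no constrained site")
  expect_equal(fieldValues(f)[4:6], rep(0.5, 3))
})

test_that("mirror-symmetric problems give mirror-symmetric fields", {
  nx <- 9; ny <- 5
  m <- makeMirrorGrid(nx, ny, fz = function(x, y) 0.3 * sin(pi * x))
  # swap-symmetric constraints: left column 0, right column 1
  left <- which(abs(meshVertices(m)[, 1]) < 1e-12)
  right <- which(abs(meshVertices(m)[, 1] - 1) < 1e-12)
  w <- edgeLengths(m)   # geometric weights, symmetric under the mirror
  L <- assembleLaplacian(m, w)
  u <- fieldValues(solveField(L, constraintSet(left, right)))
  # mirror x -> 1-x maps u -> 1-u
  V <- meshVertices(m)
  mirrorIdx <- vapply(seq_len(nrow(V)), function(i) {
    which.min((V[, 1] - (1 - V[i, 1]))^2 + (V[, 2] - V[i, 2])^2)
  }, 1L)
  expect_equal(u + u[mirrorIdx], rep(1, length(u)), tolerance = 1e-8)
})

test_that("field values stay in [0,1] and constraint residual shrinks with alpha", {
  m <- randomJitteredGrid(5)
  set.seed(5)
  w <- runif(nrow(meshEdges(m)), 0.05, 8)
  L <- assembleLaplacian(m, w)
  cs <- constraintSet(c(1L, 2L), c(48L, 49L))
  res <- vapply(c(1e4, 1e6, 1e8), function(a) {
    u <- fieldValues(solveField(L, cs, fieldParams(alpha = a)))
    expect_gte(min(u), -1e-6)
    expect_lte(max(u), 1 + 1e-6)
    max(abs(c(u[targetSites(cs)], 1 - u[backgroundSites(cs)])))
  }, 1)
  expect_true(all(diff(res) < 0))
  expect_lt(res[3], 1e-4)
})
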