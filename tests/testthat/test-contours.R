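test_that("face gradients reproduce linear fields and vanish on constants", {
  m <- makeGridMesh(6, 6)
  g0 <- faceFieldGradients(m, rep(2.7, 36))
  expect_equal(g0, matrix(0, nFaces(m), 3), tolerance = 1e-12)
  gx <- faceFieldGradients(m, meshVertices(m)[, 1])
  expect_equal(gx, matrix(rep(c(1, 0, 0), each = nFaces(m)), ncol = 3),
               tolerance = 1e-12)
  # gradient magnitude is invariant under rigid motion
  th <- 0.5
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  m2 <- triangleMesh(meshVertices(m) %*% t(R), meshFaces(m))
  g2 <- faceFieldGradients(m2, meshVertices(m)[, 1])
  expect_equal(sqrt(rowSums(g2^2)), sqrt(rowSums(gx^2)), tolerance = 1e-12)
})

test_that("marching triangles matches the hand-computed single-triangle case", {
  m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  loops <- extractIsocontours(m, c(0, 0, 1), levels = 0.5,
                              minLengthFactor = 0)
  expect_length(loops, 1L)
  lp <- loops[[1]]
  expect_false(lp@closed)
  expect_equal(lp@length, 0.5, tolerance = 1e-12)
  pts <- lp@points[order(lp@points[, 1]), ]
  expect_equal(pts, rbind(c(0, 0.5, 0), c(0.5, 0.5, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("level sets of linear fields are straight, exact, and nested", {
  m <- makeGridMesh(11, 11)
  u <- meshVertices(m)[, 1]
  loops <- extractIsocontours(m, u, levels = 0.5)
  expect_length(loops, 1L)
  lp <- loops[[1]]
  expect_equal(lp@length, 1, tolerance = 1e-9)
  expect_lt(diff(range(lp@points[, 1])), 1e-9)
  # distinct levels never cross: x-coordinates are totally ordered
  loops <- extractIsocontours(m, u, levels = c(0.25, 0.55, 0.85))
  xs <- vapply(loops, function(l) mean(l@points[, 1]), 1)
  spreads <- vapply(loops, function(l) diff(range(l@points[, 1])), 1)
  expect_true(all(spreads < 1e-9))
  expect_equal(sort(xs), c(0.25, 0.55, 0.85), tolerance = 1e-9)
  # a level through a vertex value is perturbed, not an error
  expect_silent(extractIsocontours(m, u, levels = 0.5 + 1e-16))
  # out-of-range level: simply no contour
  expect_length(extractIsocontours(m, u, levels = 1.5), 0L)
})

test_that("field histograms bin, tie-break, and conserve counts", {
  vals <- c(rep(0.1, 5), rep(0.55, 8), rep(0.9, 4))
  h <- fieldHistogram(vals, nBins = 10)
  expect_equal(sum(h@counts), 17L)
  expect_equal(h@binMaxIndex, 6L)      # bin [0.5, 0.6)
  expect_equal(h@vMed, 0.55)
  expect_length(h@gaps, 2L)
  # all identical: one occupied bin, conservation
  h <- fieldHistogram(rep(0.5, 33), nBins = 10)
  expect_equal(sum(h@counts), 33L)
  expect_equal(sum(h@counts > 0), 1L)
  # uniform tie: lowest index wins
  h <- fieldHistogram(seq(0.05, 0.95, by = 0.1), nBins = 10)
  expect_equal(h@binMaxIndex, 1L)
  expect_error(fieldHistogram(vals, nBins = 1), class = "toothFieldValidationError")
})

test_that("boundary selection takes the max-gradient loop per interval", {
  loops <- list(makeStubLoop(0.30, 5), makeStubLoop(0.35, 7),
                makeStubLoop(0.80, 6))
  h <- fieldHistogram(rep(0.55, 10), nBins = 10)   # vMed = 0.55
  sel <- selectCutBoundaries(loops, h)
  expect_equal(sel$low@level, 0.35)
  expect_equal(sel$high@level, 0.80)
  # single loop per interval is returned unconditionally
  sel <- selectCutBoundaries(list(makeStubLoop(0.2, 1), makeStubLoop(0.9, 1)), h)
  expect_equal(sel$low@level, 0.2)
  expect_equal(sel$high@level, 0.9)
  # all loops low: high absent with a warning
  expect_warning(
    sel <- selectCutBoundaries(list(makeStubLoop(0.2, 1), makeStubLoop(0.3, 2)), h),
    "absent")
  expect_null(sel$high)
  expect_equal(sel$low@level, 0.3)
  expect_error(selectCutBoundaries(list(), h), "no candidate",
               class = "toothFieldValidationError")
})

test_that("selection protects foreign features and prefers closed loops", {
  h <- fieldHistogram(rep(0.55, 10), nBins = 10)
  # protected: the 0.35 loop would enclose a foreign feature at u = 0.32
  loops <- list(makeStubLoop(0.30, 5), makeStubLoop(0.35, 7),
                makeStubLoop(0.80, 6))
  sel <- selectCutBoundaries(loops, h, protect = 0.32)
  expect_equal(sel$low@level, 0.30)
  # closed beats open even at lower score
  loops <- list(makeStubLoop(0.30, 9, closed = FALSE),
                makeStubLoop(0.35, 2, closed = TRUE),
                makeStubLoop(0.80, 1, closed = TRUE))
  sel <- selectCutBoundaries(loops, h)
  expect_equal(sel$low@level, 0.35)
  # with no closed candidate the open loop is the fallback
  sel <- selectCutBoundaries(list(makeStubLoop(0.3, 1, closed = FALSE),
                                  makeStubLoop(0.9, 1, closed = TRUE)), h)
  expect_equal(sel$low@level, 0.3)
})

test_that("contour JSON export writes one polyline per loop", {
  m <- makeGridMesh(6, 6)
  loops <- extractIsocontours(m, meshVertices(m)[, 1], levels = c(0.3, 0.7))
  p <- file.path(tempdir(), "loops.json")
  writeContours(loops, p)
  js <- jsonlite::read_json(p, simplifyVector = FALSE)
  expect_length(js, 2L)
  expect_equal(js[[1]]$level, 0.3, tolerance = 1e-12)
  expect_true(all(lengths(js[[1]]$points) == 3L))
})
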