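test_that("a flat plane yields no feature points", {
  m <- makeGridMesh(12, 12, lx = 10, ly = 10)
  expect_length(detectFeaturePoints(m, radius = 3), 0L)
})

test_that("every bump cap of the arch carries a cusp point, grooves none", {
  fx <- arch4()
  pts <- detectFeaturePoints(fx@mesh, radius = 3)
  truth <- archGroundTruth(fx, fx@params$st)
  expect_true(all(truth$m1[pts] > 0.7))
  expect_false(any(truth$band[pts]))
  # at least one cusp on each of the 4 bumps
  G <- vapply(fx@params$centers, function(ck) {
    abs(fx@params$st[pts, 1] - ck)
  }, numeric(length(pts)))
  nearest <- max.col(-matrix(G, nrow = length(pts)))
  expect_setequal(unique(nearest), 1:4)
})

test_that("feature detection is invariant under vertex-index permutation", {
  fx <- arch2()
  m <- fx@mesh
  pts <- detectFeaturePoints(m, radius = 3)
  set.seed(11)
  perm <- sample(nVertices(m))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- triangleMesh(meshVertices(m)[perm, ],
                     matrix(inv[meshFaces(m)], ncol = 3))
  pts2 <- detectFeaturePoints(m2, radius = 3)
  expect_setequal(perm[pts2], pts)
})

test_that("feature points group into one candidate per tooth", {
  fx <- arch4()
  pts <- detectFeaturePoints(fx@mesh, radius = 3)
  gr <- groupFeaturePoints(fx@mesh, pts)
  expect_length(gr@groups, 4L)
  # partition: disjoint, covering, non-empty
  expect_setequal(unlist(gr@groups), pts)
  expect_true(all(lengths(gr@groups) > 0))
  # each group sits on a single bump
  truth <- archGroundTruth(fx, fx@params$st)
  for (g in gr@groups)
    expect_length(unique(truth$label[g]), 1L)
  # all points on one bump form a single group
  one <- gr@groups[[1]]
  gr1 <- groupFeaturePoints(fx@mesh, one)
  expect_length(gr1@groups, 1L)
  expect_error(groupFeaturePoints(fx@mesh, pts, nGroups = length(pts) + 1L),
               class = "toothFieldValidationError")
})

test_that("a click picks the nearest and next-nearest groups", {
  fx <- arch4()
  m <- fx@mesh
  pts <- detectFeaturePoints(m, radius = 3)
  gr <- groupFeaturePoints(m, pts, nGroups = 4)
  truth <- archGroundTruth(fx, fx@params$st)
  bump <- vapply(gr@groups, function(g) truth$label[g[1]], 1L)
  g2 <- which(bump == 2L)
  click <- gr@representatives[g2]
  cs <- constraintsFromClick(m, click, gr, growRadius = 0)
  expect_setequal(targetSites(cs), gr@groups[[g2]])
  # background is bump 1 or bump 3, whichever is geodesically nearer
  d <- vapply(seq_along(gr@groups), function(k)
    min(geodesicDistance(m, click, gr@groups[[k]])), 1)
  expected <- setdiff(order(d), g2)[1]
  expect_setequal(backgroundSites(cs), gr@groups[[expected]])
  expect_true(truth$label[backgroundSites(cs)[1]] %in% c(1L, 3L))
  expect_error(constraintsFromClick(m, click,
                                    groupFeaturePoints(m, gr@groups[[1]])),
               "neighboring tooth", class = "toothFieldValidationError")
})

test_that("site patches grow on the convex cap and stay disjoint", {
  fx <- arch2()
  m <- fx@mesh
  pts <- detectFeaturePoints(m, radius = 3)
  gr <- groupFeaturePoints(m, pts, nGroups = 2)
  cs0 <- constraintSet(gr@groups[[1]], gr@groups[[2]])
  cs <- expandConstraintSites(m, cs0, 1.5)
  expect_true(all(gr@groups[[1]] %in% targetSites(cs)))
  expect_gt(length(targetSites(cs)), length(gr@groups[[1]]))
  expect_length(intersect(targetSites(cs), backgroundSites(cs)), 0L)
  truth <- archGroundTruth(fx, fx@params$st)
  expect_false(any(truth$band[targetSites(cs)]))
})

test_that("feature groups round-trip through JSON", {
  gr <- new("FeatureGroups", groups = list(c(3L, 5L), 9L),
            representatives = c(3L, 9L))
  p <- file.path(tempdir(), "groups.json")
  writeFeatureGroups(gr, p)
  gr2 <- readFeatureGroups(p)
  expect_equal(gr2@groups, gr@groups)
  expect_equal(gr2@representatives, gr@representatives)
})
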