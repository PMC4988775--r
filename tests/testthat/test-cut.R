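test_that("cutting a planar square at x = 0.5 yields two equal halves", {
  m <- makeGridMesh(2, 2)          # unit square, two triangles
  u <- meshVertices(m)[, 1]
  loops <- extractIsocontours(m, u, levels = 0.5, minLengthFactor = 0)
  cut <- cutMeshAlongLoops(m, loops)
  expect_equal(sum(faceAreasOf(cut$mesh)), 1, tolerance = 1e-9)
  side <- tapply(faceAreasOf(cut$mesh),
                 ToothField:::.faceCentroids(cut$mesh)[, 1] > 0.5, sum)
  expect_equal(as.numeric(side), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("an empty loop list returns the mesh unchanged", {
  m <- randomJitteredGrid(6)
  cut <- cutMeshAlongLoops(m, list())
  expect_identical(cut$mesh, m)
  expect_identical(cut$parentFaces, seq_len(nFaces(m)))
})

test_that("subdivision conserves total and per-parent areas", {
  m <- randomJitteredGrid(7, 9, 9)
  u <- fieldValues(solveField(assembleLaplacian(m, edgeLengths(m)),
                              constraintSet(1L, nVertices(m))))
  fld <- new("SegmentationField", values = u, params = fieldParams(),
             constraints = constraintSet(1L, nVertices(m)))
  loops <- extractIsocontours(m, fld, levels = c(0.25, 0.5, 0.75),
                              minLengthFactor = 0)
  cut <- cutMeshAlongLoops(m, loops, field = fld)
  a0 <- faceAreasOf(m)
  a1 <- faceAreasOf(cut$mesh)
  expect_equal(sum(a1), sum(a0), tolerance = 1e-9 * sum(a0))
  child <- tapply(a1, cut$parentFaces, sum)
  expect_equal(as.numeric(child), as.numeric(a0[as.integer(names(child))]),
               tolerance = 1e-9)
  # boundary chains are contiguous edge paths of the refined mesh
  keys <- cut$mesh@edgeKeys
  for (b in cut$boundaries) {
    vid <- b$vertexIds
    a <- vid[-length(vid)]; z <- vid[-1]
    if (b$closed) { a <- c(a, vid[length(vid)]); z <- c(z, vid[1]) }
    expect_true(all(ToothField:::.edgeKey(a, z, nVertices(cut$mesh)) %in% keys))
  }
})

test_that("loops from a different mesh are rejected", {
  m <- makeGridMesh(5, 5)
  big <- makeGridMesh(9, 9)
  loops <- extractIsocontours(big, meshVertices(big)[, 1], levels = 0.5)
  expect_error(cutMeshAlongLoops(m, loops), class = "toothFieldValidationError")
})

test_that("label propagation separates parts and keeps partitions", {
  fx <- arch2()
  m <- fx@mesh
  pts <- detectFeaturePoints(m, radius = 3)
  gr <- groupFeaturePoints(m, pts, nGroups = 2)
  cs <- constraintsFromClick(m, gr@representatives[1], gr)
  res <- segmentTooth(m, constraints = cs, groups = gr)
  seg <- res$segmented
  labs <- faceLabels(seg)
  expect_setequal(unique(labs), c(0L, 1L, 2L))
  # every target-site vertex's incident faces carry the target label
  f <- meshFaces(seg@mesh)
  inc <- which(rowSums(matrix(f %in% targetSites(cs), nrow(f), 3)) > 0)
  expect_true(all(labs[inc] == 1L))
  # no boundaries: one label everywhere
  seg0 <- propagateLabels(m, list(), cs)
  expect_length(unique(faceLabels(seg0)), 1L)
})

test_that("a cut that fails to separate the constraints is reported", {
  m <- makeGridMesh(5, 5)
  cs <- constraintSet(1L, 25L)
  # a boundary that blocks nothing: single short chain in a corner
  b <- list(list(vertexIds = c(1L, 2L), closed = FALSE))
  expect_error(propagateLabels(m, b, cs), "separate",
               class = "toothFieldValidationError")
})
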