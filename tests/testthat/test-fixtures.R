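test_that("arch generation is deterministic with exact ground truth", {
  fx <- arch4()
  expect_s4_class(fx, "ArchFixture")
  expect_setequal(unique(fx@faceLabels), 0:4)
  expect_gt(sum(fx@grooveBand), 0)
  # labels and band agree with the parametric truth at face centroids
  st <- fx@params$st
  f <- meshFaces(fx@mesh)
  fc <- (st[f[, 1], ] + st[f[, 2], ] + st[f[, 3], ]) / 3
  truth <- archGroundTruth(fx, fc)
  expect_identical(truth$label, fx@faceLabels)
  expect_identical(truth$band, fx@grooveBand)
  # regeneration is bit-identical
  fx2 <- makeArch(nTeeth = 4, resolution = 0.4)
  expect_identical(meshVertices(fx2@mesh), meshVertices(fx@mesh))
  expect_identical(meshFaces(fx2@mesh), meshFaces(fx@mesh))
})

test_that("caps that would fuse are rejected", {
  expect_error(makeArch(nTeeth = 2, sigma = 3, crowding = 0.2),
               "merges", class = "toothFieldValidationError")
  expect_error(makeArch(nTeeth = 1), class = "toothFieldValidationError")
})

test_that("groove-band vertices are concave, bump caps are not", {
  fx <- arch4()
  est <- ToothField:::.estimateGeometry(fx@mesh)
  truth <- archGroundTruth(fx, fx@params$st)
  expect_true(all(est$concave[truth$band]))
  expect_lte(mean(est$concave[truth$m1 > 0.7]), 0.01)
})

test_that("vertex noise has the stated distribution and is reproducible", {
  m <- makeGridMesh(60, 60, lx = 59, ly = 59)   # unit edges, 3600 vertices
  expect_identical(addVertexNoise(m, 0, seed = 1), m)
  n1 <- addVertexNoise(m, 0.05, seed = 9)
  n2 <- addVertexNoise(m, 0.05, seed = 9)
  expect_identical(meshVertices(n1), meshVertices(n2))
  expect_identical(meshFaces(n1), meshFaces(m))
  n3 <- addVertexNoise(m, 0.05, seed = 10)
  expect_false(identical(meshVertices(n1), meshVertices(n3)))
  # RMS displacement of isotropic noise: sigma * sqrt(3) * mean edge length
  disp <- meshVertices(n1) - meshVertices(m)
  rms <- sqrt(mean(rowSums(disp^2)))
  expect_equal(rms, 0.05 * mean(edgeLengths(m)) * sqrt(3), tolerance = 0.05)
})

test_that("decimation hits the face target and re-derives ground truth", {
  fx <- arch4()
  target <- as.integer(nFaces(fx@mesh) / 2)
  dec <- decimateFixture(fx, target)
  expect_lte(nFaces(dec@mesh), target)
  expect_gte(nFaces(dec@mesh), as.integer(target * 0.98))
  expect_length(dec@faceLabels, nFaces(dec@mesh))
  expect_setequal(unique(dec@faceLabels), 0:4)
  expect_gt(sum(dec@grooveBand), 0)
  expect_error(decimateFixture(fx, 50), class = "toothFieldValidationError")
  expect_error(decimateFixture(dec, nFaces(dec@mesh) + 10L),
               class = "toothFieldValidationError")
})

test_that("fixture export writes a colored PLY plus truth JSON", {
  fx <- arch2()
  p <- file.path(tempdir(), "arch.ply")
  writeFixture(fx, p)
  m2 <- readMesh(p)
  expect_equal(nVertices(m2), nVertices(fx@mesh))
  truth <- jsonlite::read_json(paste0(p, ".truth.json"), simplifyVector = TRUE)
  expect_length(truth$faceLabels, nFaces(fx@mesh))
  expect_equal(truth$params$nTeeth, 2)
})
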