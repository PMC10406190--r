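test_that("cosine similarity is antipodally invariant with closed forms", {
  expect_equal(cosineSimilarity(c(1, 0, 0), c(2, 0, 0)), 1)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(-1, 0, 0)), 1)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosineSimilarity(c(1, 0, 0), c(1, 1, 0)), sqrt(2) / 2)
  expect_true(is.na(cosineSimilarity(c(0, 0, 0), c(1, 0, 0))))
  m <- cosineSimilarity(rbind(c(1, 0, 0), c(0, 0, 1)),
                        rbind(c(1, 1, 0), c(0, 0, -2)))
  expect_equal(m, c(sqrt(2) / 2, 1))
})

test_that("self-comparison is the exact fixed point", {
  ph <- smallPhantom()
  r <- evaluateFields(ph$tensors, ph$tensors)
  expect_equal(r$invalidCount, 0)
  for (m in r$masks) {
    expect_equal(m$cosineSimilarityMean, 1)
    expect_equal(m$anisotropyMse, 0)
    expect_equal(m$geodesicMean, 0)
  }
  ro <- evaluateFields(ph$odfs, ph$odfs)
  for (m in ro$masks) {
    expect_equal(m$cosineSimilarityMean, 1)
    expect_equal(m$anisotropyMse, 0)
    expect_equal(m$geodesicMean, 0)
  }
})

test_that("masks come from the reference and are nested", {
  ph <- smallPhantom()
  r <- evaluateFields(ph$tensors, ph$tensors)
  expect_lte(r$masks$aniso0.5$nVoxels, r$masks$aniso0.2$nVoxels)
  expect_gt(r$masks$aniso0.2$nVoxels, 0)
})

test_that("rotated tensors give zero masked cosine similarity", {
  ph <- smallPhantom(odf = FALSE)
  # rotate every tensor 90 degrees about x: z-aligned fibers become y-aligned
  R <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE)
  m <- matrix(volData(ph$tensors), ncol = 9)
  rot <- t(apply(m, 1, function(r9) as.vector(t(R %*% matrix(r9, 3, byrow = TRUE) %*% t(R)))))
  gen <- tensorField(array(rot, dim(volData(ph$tensors))), voxelSpacing(ph$tensors))
  r <- evaluateFields(gen, ph$tensors, thresholds = 0.5)
  expect_lt(r$masks$aniso0.5$cosineSimilarityMean, 1e-6)
})

test_that("isotropic generation against an FA-0.8 reference gives MSE 0.64", {
  ph <- smallPhantom(odf = FALSE)
  iso <- array(rep(as.vector(diag(3) * 0.7), each = prod(gridDim(ph$tensors))),
               dim(volData(ph$tensors)))
  gen <- tensorField(iso, voxelSpacing(ph$tensors))
  r <- evaluateFields(gen, ph$tensors, thresholds = 0.5)
  # the FA >= 0.5 mask of this phantom is exactly the FA-0.8 bundle
  expect_equal(r$masks$aniso0.5$anisotropyMse, 0.64, tolerance = 1e-6)
  expect_error(evaluateFields(gen, smallPhantom(grid = 16, odf = FALSE)$tensors),
               "same grid")
})
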