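test_that("single-bundle phantom hits FA target and axis exactly", {
  ph <- smallPhantom()
  fa <- faMap(ph$tensors)
  inb <- ph$bundleMasks[[1]]
  expect_true(all(abs(fa[inb] - 0.8) < 1e-6))
  dirs <- directionMap(ph$tensors)
  sel <- which(as.vector(inb))
  expect_true(all(abs(abs(dirs[sel, 3]) - 1) < 1e-8))
  # validity by construction
  expect_equal(fieldValidity(ph$tensors)$nInvalid, 0)
  expect_equal(odfFieldValidity(ph$odfs)$nInvalid, 0)
  # structural intensities in range and informative of the bundle
  x <- volData(ph$structural)
  expect_true(all(x >= 0 & x <= 1))
  expect_gt(mean(x[inb]), mean(x[!inb]) + 0.1)
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantomSpec(gridShape = c(16, 16, 16),
                      bundles = list(straightBundle("z", extent = 12)),
                      seed = 7L)
  a <- makePhantom(spec, odf = FALSE)
  b <- makePhantom(spec, odf = FALSE)
  expect_identical(volData(a$structural), volData(b$structural))
  expect_identical(volData(a$tensors), volData(b$tensors))
})

test_that("crossing voxels produce exactly two antipodal peak pairs", {
  spec <- phantomSpec(gridShape = c(20, 20, 20),
                      bundles = list(
                        straightBundle("z", radius = 3, extent = 14),
                        straightBundle("x", radius = 3, extent = 14)),
                      seed = 11L)
  ph <- makePhantom(spec)
  crossing <- ph$bundleMasks[[1]] & ph$bundleMasks[[2]]
  expect_gt(sum(crossing), 0)
  basis <- shBasis(4, sphereTessellation(724))
  cf <- matrix(volData(ph$odfs), ncol = 15)
  sel <- which(as.vector(crossing))
  # center-most crossing voxel
  i <- sel[ceiling(length(sel) / 2)]
  pk <- odfPeaks(cf[i, ], basis, maxPeaks = 4)
  expect_equal(nrow(pk), 2L)
  # peaks align with the two bundle axes (z and x)
  al <- abs(pk %*% diag(3))
  expect_gt(max(abs(pk[, 3])), cos(15 * pi / 180))
  expect_gt(max(abs(pk[, 1])), cos(15 * pi / 180))
  # crossing tensors are the log-Euclidean mean: oblate, lower FA
  fa <- faMap(ph$tensors)
  expect_lt(mean(fa[crossing]), 0.5)
})

test_that("infeasible FA target errors out", {
  expect_error(makePhantom(phantomSpec(
    gridShape = c(12, 12, 12),
    bundles = list(straightBundle("z", extent = 6, faTarget = 1)))),
    "positive-definite")
})

test_that("degradation preserves validity and lowers interior anisotropy", {
  ph <- smallPhantom()
  lr <- degradeToLR(ph$tensors, 1.25)
  expect_equal(gridDim(lr), as.integer(round(24 * 0.7 / 1.25)) * c(1L, 1L, 1L))
  expect_equal(fieldValidity(lr)$nInvalid, 0)
  lrOdf <- degradeToLR(ph$odfs, 1.25)
  expect_equal(odfFieldValidity(lrOdf)$nInvalid, 0)
  # partial-volume averaging cannot raise anisotropy in the interior
  hrInterior <- mean(faMap(ph$tensors)[ph$bundleMasks[[1]]])
  lrMask <- degradeToLR(structuralVolume(ph$bundleMasks[[1]] + 0, 0.7), 1.25)
  lrInterior <- mean(faMap(lr)[volData(lrMask) > 0.95])
  expect_lte(lrInterior, hrInterior + 1e-6)
  # constant field stays constant
  cst <- randomSymmetric()
  arr <- array(rep(as.vector(t(tensorExp(cst))), each = 16^3), c(16, 16, 16, 9))
  d <- degradeToLR(tensorField(arr, 0.7), 1.4)
  m <- matrix(volData(d), ncol = 9)
  expect_lt(max(abs(sweep(m, 2, as.vector(t(tensorExp(cst)))))), 1e-8)
  expect_error(degradeToLR(ph$tensors, 0.5), "coarser")
})

test_that("patch decomposition pairs HR and LR patches by world position", {
  ph <- smallPhantom()
  yLr <- fieldLog(degradeToLR(ph$tensors, 1.25))
  ps <- extractPatches(ph$structural, yLr, hrPatch = 16, lrPatch = 9, stride = 8)
  # non-overlapping tiling on an exact-multiple grid
  ps2 <- extractPatches(ph$structural, yLr, hrPatch = 12, lrPatch = 7, stride = 12)
  expect_equal(nrow(ps2$hrStarts), 2L^3)
  # every HR patch center within one LR voxel of its LR patch center
  expect_lt(max(abs(ps$hrCenters - ps$lrCenters)), 1.25)
  # identity round trip of unmodified patches
  arr <- volData(ph$structural)
  patches <- lapply(seq_len(nrow(ps$hrStarts)), function(i)
    patchArray(arr, ps$hrStarts[i, ], 16))
  back <- reassemblePatches(patches, ps$hrStarts, dim(arr))
  expect_identical(back, arr)
  expect_error(extractPatches(ph$structural, yLr, hrPatch = 64), "smaller")
})
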