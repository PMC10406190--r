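test_that("bundle agreement statistics match set algebra", {
  A <- array(FALSE, c(4, 4, 4))
  A[1:2, 1:2, 1] <- TRUE           # |A| = 4
  r <- bundleAgreement(A, A)
  expect_equal(r, list(dice = 1, ol = 1, or = 0))
  B <- array(FALSE, c(4, 4, 4))
  B[3:4, 3:4, 4] <- TRUE           # disjoint, |B| = 4
  r2 <- bundleAgreement(A, B)
  expect_equal(r2, list(dice = 0, ol = 0, or = 2))
  B2 <- array(FALSE, c(4, 4, 4))
  B2[1:2, 1, 1] <- TRUE            # overlap 2
  B2[3:4, 4, 4] <- TRUE            # plus 2 outside
  r3 <- bundleAgreement(A, B2)
  # |A| = |B| = 4, |intersection| = 2, |union| = 6
  expect_equal(r3, list(dice = 0.5, ol = 0.5, or = 1))
  expect_error(bundleAgreement(array(FALSE, c(2, 2, 2)), B2), "empty|dim")
})

test_that("density mask and streamline statistics count correctly", {
  # one straight streamline of 10 points spaced 0.5 mm -> length 4.5 mm
  pts <- cbind(seq(0, by = 0.5, length.out = 10), 1, 1)
  t <- tractogram(list(pts))
  s <- streamlineStats(t)
  expect_equal(s$lengthMean, 4.5)
  grid <- list(dims = c(10L, 4L, 4L), spacing = c(1, 1, 1))
  expect_equal(streamlineStats(t, grid)$volumeVoxels, 5L)  # nearest voxels 0:4
  # axis-aligned streamline visiting n distinct voxels
  pts2 <- cbind(0:7, 0, 0)
  expect_equal(sum(densityMask(tractogram(list(pts2)), grid)), 8)
  empty <- tractogram(list())
  expect_equal(streamlineStats(empty, grid)$volumeVoxels, 0L)
})

test_that("tracking a straight bundle recovers its geometry", {
  ph <- smallPhantom(odf = FALSE)             # straight z bundle, 24^3 at 0.7mm
  mask <- faMap(ph$tensors) >= 0.5
  t <- track(ph$tensors, mask, seed = 1)
  expect_gt(length(streamlines(t)), 50)
  lens <- vapply(streamlines(t), dmrisynth:::polylineLength, numeric(1))
  expect_true(all(lens >= 10 & lens <= 300))
  # mean direction within 5 degrees of the bundle axis
  dirs <- t(vapply(streamlines(t), function(s) {
    d <- s[nrow(s), ] - s[1, ]
    d / sqrt(sum(d^2))
  }, numeric(3)))
  expect_gt(mean(abs(dirs[, 3])), cos(5 * pi / 180))
  # lengths close to the tracking-mask extent of the bundle
  expect_gt(mean(lens), 0.6 * 24 * 0.7)
  # density mask recovers >= 90% of the bundle interior
  dm <- densityMask(t, ph$tensors)
  ag <- bundleAgreement(mask, dm)
  expect_gte(ag$ol, 0.9)
})

test_that("tracking determinism and empty/isotropic handling", {
  ph <- smallPhantom(odf = FALSE)
  mask <- faMap(ph$tensors) >= 0.5
  a <- track(ph$tensors, mask, seed = 3)
  b <- track(ph$tensors, mask, seed = 3)
  expect_identical(streamlines(a), streamlines(b))
  expect_error(track(ph$tensors, array(FALSE, gridDim(ph$tensors))), "empty")
  # isotropic field: no directions to follow, no retained streamlines
  iso <- array(rep(as.vector(diag(3) * 0.7), each = 12^3), c(12, 12, 12, 9))
  isoF <- tensorField(iso, 0.7)
  t0 <- track(isoF, array(TRUE, c(12, 12, 12)), seed = 1)
  expect_length(streamlines(t0), 0)
})

test_that("curvature handling: fine steps traverse a bend, coarse steps stop", {
  spec <- phantomSpec(gridShape = c(36, 36, 36),
                      bundles = list(arcBundle(bendRadius = 12, radius = 2.8,
                                               faTarget = 0.85)),
                      seed = 13L)
  ph <- makePhantom(spec, odf = FALSE)
  mask <- faMap(ph$tensors) >= 0.5
  arcLen <- pi / 2 * 12                       # quarter arc, r = 12mm
  # per-step turning is step/r: 2.4 deg at step 0.5, ~19 deg at step 4
  fine <- track(ph$tensors, mask, step = 0.5, maxAngle = 15, seed = 2)
  lensF <- vapply(streamlines(fine), dmrisynth:::polylineLength, numeric(1))
  expect_gt(max(lensF), 0.75 * arcLen)        # tracks traverse the bend
  coarse <- track(ph$tensors, mask, step = 4, maxAngle = 15, minLen = 0,
                  seed = 2)
  lensC <- vapply(streamlines(coarse), dmrisynth:::polylineLength, numeric(1))
  expect_lt(max(c(lensC, 0)), 0.75 * arcLen)
})

test_that("ODF tracking follows the bundle via discrete maxima", {
  ph <- smallPhantom()
  mask <- faMap(ph$tensors) >= 0.5
  t <- track(ph$odfs, mask, seed = 1)
  expect_gt(length(streamlines(t)), 20)
  dm <- densityMask(t, ph$odfs)
  expect_gte(bundleAgreement(mask, dm)$ol, 0.7)
})

test_that("TRK files round-trip streamlines", {
  set.seed(501)
  lines <- lapply(1:5, function(i) {
    n <- sample(5:20, 1)
    cbind(cumsum(runif(n)), cumsum(runif(n)), cumsum(runif(n)))
  })
  t <- tractogram(lines, provenance = list(seed = 1))
  f <- tempfile(fileext = ".trk")
  writeTrk(t, f, spacing = c(0.7, 0.7, 0.7), dims = c(24L, 24L, 24L))
  back <- readTrk(f)
  expect_length(streamlines(back), 5)
  for (i in 1:5)
    expect_equal(streamlines(back)[[i]], lines[[i]], tolerance = 1e-5)
  unlink(f)
})
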