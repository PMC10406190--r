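test_that("tensor log/exp match an independent eigen-decomposition oracle", {
  set.seed(101)
  for (i in 1:20) {
    M <- randomSpd()
    # oracle: decompose with svd (independent routine), map eigenvalues
    sv <- svd(M)
    oracle <- sv$u %*% diag(log(sv$d)) %*% t(sv$u)
    expect_lt(max(abs(tensorLog(M) - oracle)), 1e-10)
  }
})

test_that("exp is the inverse of log on SPD matrices", {
  set.seed(102)
  err <- vapply(1:1000, function(i) {
    M <- randomSpd(cond = 1e4)
    max(abs(tensorExp(tensorLog(M)) - M))
  }, numeric(1))
  expect_lt(max(err), 1e-8)
})

test_that("log/exp closed forms and rotation equivariance hold", {
  expect_equal(tensorLog(diag(3)), matrix(0, 3, 3))
  expect_equal(tensorExp(matrix(0, 3, 3)), diag(3))
  expect_equal(tensorLog(diag(rep(exp(1), 3))), diag(3), tolerance = 1e-12)
  set.seed(103)
  for (i in 1:25) {
    M <- randomSpd()
    R <- randomRotation()
    expect_lt(max(abs(tensorLog(R %*% M %*% t(R)) - R %*% tensorLog(M) %*% t(R))),
              1e-8)
  }
})

test_that("exp maps every symmetric matrix to an SPD matrix", {
  set.seed(104)
  minev <- vapply(1:10000, function(i) {
    S <- randomSymmetric(scale = 3)
    min(eigen(tensorExp(S), symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  expect_true(all(minev > 0))
})

test_that("log rejects asymmetric and non-finite input", {
  A <- matrix(rnorm(9), 3)
  A[1, 2] <- A[2, 1] + 1
  expect_error(tensorLog(A), "symmetric")
  B <- diag(3)
  B[1, 1] <- NaN
  expect_error(tensorLog(B), "finite")
})

test_that("geodesic distance has closed forms and metric properties", {
  expect_equal(tensorGeodesic(diag(3), diag(3)), 0)
  expect_equal(tensorGeodesic(diag(3), diag(rep(exp(1), 3))), sqrt(3),
               tolerance = 1e-12)
  set.seed(105)
  for (i in 1:20) {
    a <- exp(rnorm(1)); b <- exp(rnorm(1))
    expect_equal(tensorGeodesic(diag(rep(a, 3)), diag(rep(b, 3))),
                 sqrt(3) * abs(log(a) - log(b)), tolerance = 1e-10)
  }
  for (i in 1:30) {
    P1 <- randomSpd(); P2 <- randomSpd(); P3 <- randomSpd()
    d12 <- tensorGeodesic(P1, P2)
    expect_gte(d12, 0)
    expect_equal(d12, tensorGeodesic(P2, P1), tolerance = 1e-10)
    expect_lte(d12, tensorGeodesic(P1, P3) + tensorGeodesic(P3, P2) + 1e-10)
  }
  expect_error(tensorGeodesic(diag(c(1, 1, -1)), diag(3)), "SPD")
})

test_that("fractional anisotropy matches the formula and its invariances", {
  expect_equal(fractionalAnisotropy(2.5, 2.5, 2.5), 0)
  expect_equal(fractionalAnisotropy(0, 0, 0), 0)
  expect_gt(fractionalAnisotropy(1, 1e-9, 1e-9), 1 - 1e-6)
  # high-precision direct evaluation for (3, 2, 1)
  direct <- sqrt(0.5) * sqrt((1 + 1 + 4) / (9 + 4 + 1))
  expect_equal(fractionalAnisotropy(3, 2, 1), direct, tolerance = 1e-14)
  set.seed(106)
  for (i in 1:50) {
    l <- sort(rexp(3), decreasing = TRUE)
    f <- fractionalAnisotropy(l[1], l[2], l[3])
    expect_true(f >= 0 && f <= 1)
    expect_equal(f, fractionalAnisotropy(l[2], l[3], l[1]), tolerance = 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(f, fractionalAnisotropy(s * l[1], s * l[2], s * l[3]),
                 tolerance = 1e-12)
  }
})

test_that("principal direction recovers the constructed axis", {
  expect_equal(principalDirection(diag(c(3, 2, 1))), c(1, 0, 0))
  expect_null(principalDirection(diag(3)))
  set.seed(107)
  for (i in 1:25) {
    R <- randomRotation()
    M <- R %*% diag(c(3, 2, 1)) %*% t(R)
    d <- principalDirection(M)
    expect_gt(abs(sum(d * R[, 1])), 1 - 1e-8)
  }
})

test_that("isSPD agrees with a quadratic-form sampling oracle", {
  expect_true(isSPD(diag(3))$spd)
  expect_equal(isSPD(diag(3))$minEigenvalue, 1)
  r <- isSPD(diag(c(1, 1, -0.1)))
  expect_false(r$spd)
  expect_equal(r$minEigenvalue, -0.1)
  set.seed(108)
  X <- matrix(rnorm(3 * 10000), ncol = 3)
  X <- X / sqrt(rowSums(X^2))
  for (i in 1:20) {
    S <- randomSymmetric(scale = 1)
    q <- rowSums((X %*% S) * X)
    claimed <- isSPD(S)$spd
    # sampling says "definitely not SPD" when some quadratic form <= 0
    if (any(q <= 0)) expect_false(claimed)
    if (claimed) expect_true(all(q > 0))
  }
  expect_error(isSPD(matrix(NaN, 3, 3)), "finite")
})

test_that("channel packing round-trips and symmetrization averages", {
  set.seed(109)
  arr <- array(rnorm(4 * 4 * 4 * 9), c(4, 4, 4, 9))
  f <- unpackChannels(arr, symmetrize = FALSE)
  expect_identical(packChannels(f), arr)
  fs <- unpackChannels(arr, symmetrize = TRUE)
  m <- matrix(packChannels(fs), ncol = 9)
  m0 <- matrix(arr, ncol = 9)
  expect_equal(m[, 2], (m0[, 2] + m0[, 4]) / 2)
  expect_equal(m[, 2], m[, 4])
  expect_equal(m[, 3], m[, 7])
  expect_equal(m[, 6], m[, 8])
  expect_error(unpackChannels(array(0, c(4, 4, 4, 8))), "9 channels")
})

test_that("log-domain resampling is exact on constants and interpolates determinants geometrically", {
  set.seed(110)
  cst <- randomSymmetric()
  arr <- array(rep(as.vector(t(cst)), each = 4^3), c(4, 4, 4, 9))
  lf <- logTensorField(arr, 1)
  same <- resampleLogField(lf, 1)
  expect_equal(volData(same), arr, tolerance = 1e-12)
  finer <- resampleLogField(lf, 0.5)
  expect_equal(gridDim(finer), c(8L, 8L, 8L))
  expect_lt(max(abs(sweep(matrix(volData(finer), ncol = 9), 2,
                          as.vector(t(cst))))), 1e-12)
  # midpoint of a 2-voxel field: det(exp(mid)) = sqrt(det A det B)
  A <- randomSpd(); B <- randomSpd()
  arr2 <- array(0, c(2, 1, 1, 9))
  arr2[1, 1, 1, ] <- as.vector(t(tensorLog(A)))
  arr2[2, 1, 1, ] <- as.vector(t(tensorLog(B)))
  mid <- resampleLogField(logTensorField(arr2, 1), 2, c(1, 1, 1))
  M <- tensorExp(matrix(volData(mid)[1, 1, 1, ], 3, byrow = TRUE))
  expect_equal(det(M), sqrt(det(A) * det(B)), tolerance = 1e-10)
  expect_error(resampleLogField(lf, -1), "positive")
  expect_error(resampleLogField(fieldExp(lf), 1), "log")
})

test_that("field-level maps agree with voxel-level maps", {
  set.seed(111)
  arr <- array(0, c(3, 3, 3, 9))
  ms <- lapply(1:27, function(i) randomSpd())
  for (i in 1:27) arr[ , , , ][i + 27 * (0:8)] <- vapply(1:9, function(k)
    as.vector(t(ms[[i]]))[k], numeric(1))
  tf <- tensorField(arr, 1)
  lf <- fieldLog(tf)
  back <- fieldExp(lf)
  expect_equal(volData(back), volData(tf), tolerance = 1e-10)
  i <- 5
  expect_equal(matrix(matrix(volData(lf), ncol = 9)[i, ], 3, byrow = TRUE),
               tensorLog(ms[[i]]), tolerance = 1e-10)
  v <- fieldValidity(tf)
  expect_equal(v$nInvalid, 0)
  expect_equal(v$nVoxels, 27)
})
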