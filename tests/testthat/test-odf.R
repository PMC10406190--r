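test_that("spherical-harmonic basis has the right size and structure", {
  dirs <- sphereTessellation(724)
  for (L in c(0, 2, 4, 6, 8)) {
    b <- shBasis(L, dirs[1:20, ])
    expect_equal(b$K, (L + 1) * (L + 2) / 2)
  }
  b <- shBasis(4, dirs)
  expect_equal(b$K, 15L)
  # constant first function 1/sqrt(4 pi)
  expect_lt(max(abs(b$B[, 1] - 1 / sqrt(4 * pi))), 1e-12)
  # antipodal symmetry: vertex i + n/2 is the antipode of vertex i
  expect_lt(max(abs(b$B[1:362, ] - b$B[363:724, ])), 1e-10)
  b0 <- shBasis(0, dirs[1:5, ])
  expect_equal(dim(b0$B), c(5L, 1L))
  expect_error(shBasis(3, dirs), "even")
  expect_error(shBasis(4, matrix(c(2, 0, 0), 1)), "unit")
})

test_that("basis is orthonormal under dense uniform quadrature", {
  dirs <- sphereTessellation(10000)
  b <- shBasis(4, dirs)
  G <- crossprod(b$B) * 4 * pi / nrow(dirs)
  expect_lt(max(abs(G - diag(15))), 1e-2)
})

test_that("tessellation is antipodally symmetric and unit-norm", {
  s <- sphereTessellation(724)
  expect_equal(nrow(s), 724L)
  expect_lt(max(abs(sqrt(rowSums(s^2)) - 1)), 1e-12)
  expect_lt(max(abs(s[1:362, ] + s[363:724, ])), 1e-12)
  expect_error(sphereTessellation(725), "even")
})

test_that("sphere log/exp maps have closed forms and are inverse on the hemisphere", {
  K <- 15
  u <- c(1, numeric(K - 1))
  expect_equal(odfLog(u), numeric(K))
  expect_equal(odfExp(numeric(K)), u)
  for (theta in c(0.1, 0.5, 1.2, 2.5)) {
    c2 <- u * cos(theta)
    c2[2] <- sin(theta)
    v <- odfLog(c2)
    expect_equal(v, theta * c(0, 1, numeric(K - 2)), tolerance = 1e-12)
    expect_equal(odfExp(v), c2, tolerance = 1e-12)
  }
  set.seed(201)
  for (i in 1:1000) {
    c0 <- rnorm(K)
    c0 <- c0 / sqrt(sum(c0^2))
    if (c0[1] <= 0) c0 <- -c0  # hemisphere around u
    err <- max(abs(odfExp(odfLog(c0)) - c0))
    expect_lt(err, 1e-8)
    expect_equal(sqrt(sum(odfLog(c0)^2)), acos(sum(u * c0)), tolerance = 1e-10)
  }
  expect_error(odfLog(-u), "antipode")
  expect_error(odfLog(2 * u), "unit norm")
})

test_that("exp map always returns unit-norm coefficients", {
  set.seed(202)
  err <- vapply(1:10000, function(i) {
    v <- rnorm(15, sd = runif(1, 0.01, 3))
    abs(sqrt(sum(odfExp(v)^2)) - 1)
  }, numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("sphere geodesic distance has its closed forms and symmetry", {
  K <- 15
  u <- c(1, numeric(K - 1))
  set.seed(203)
  for (i in 1:50) {
    c1 <- rnorm(K); c1 <- c1 / sqrt(sum(c1^2)); if (c1[1] < 0.05) c1[1] <- abs(c1[1]) + 0.05
    c1 <- c1 / sqrt(sum(c1^2))
    c2 <- rnorm(K); c2 <- c2 / sqrt(sum(c2^2)); if (c2[1] < 0.05) c2[1] <- abs(c2[1]) + 0.05
    c2 <- c2 / sqrt(sum(c2^2))
    expect_equal(odfGeodesic(c1, c1), 0)
    expect_equal(odfGeodesic(u, c1), acos(min(1, sum(u * c1))), tolerance = 1e-10)
    expect_equal(odfGeodesic(c1, c2), odfGeodesic(c2, c1), tolerance = 1e-12)
  }
})

test_that("GFA matches the formula and its limits", {
  u <- c(1, numeric(14))
  expect_equal(gfa(u), 0)
  c0 <- c(0, 1, numeric(13))
  expect_equal(gfa(c0), 1)
  cc <- c(0.8, sqrt(1 - 0.64), numeric(13))
  expect_equal(gfa(cc), sqrt(1 - 0.8^2), tolerance = 1e-14)
  # monotone in |c1| at unit norm
  g <- vapply(seq(0, 1, 0.1), function(a)
    gfa(c(a, sqrt(1 - a^2), numeric(13))), numeric(1))
  expect_true(all(diff(g) < 0))
  # matrix form
  m <- rbind(u, c0, cc)
  expect_equal(gfa(m), c(0, 1, sqrt(1 - 0.64)), tolerance = 1e-12)
})

test_that("square-root fit recovers the uniform ODF and is a fixed point", {
  dirs <- sphereTessellation(180)
  b <- shBasis(4, dirs)
  unif <- rep(1 / (4 * pi), nrow(dirs))
  cf <- sqrtOdfFit(unif, b)
  expect_equal(cf, c(1, numeric(14)), tolerance = 1e-8)
  # round trip: reconstruct psi, square, refit
  set.seed(204)
  v <- rnorm(15, sd = 0.2); v[1] <- 0
  c1 <- odfExp(v)
  psi <- as.vector(b$B %*% c1)
  if (min(psi) >= 0) {
    c2 <- sqrtOdfFit(psi^2, b)
    expect_lt(max(abs(c2 - c1)), 1e-6)
  }
  expect_error(sqrtOdfFit(c(-1, unif[-1]), b), "non-negative")
  expect_error(sqrtOdfFit(unif[1:10], shBasis(4, dirs[1:10, ])), "rank")
})

test_that("principal direction extraction finds constructed fiber axes", {
  basis <- shBasis(4, sphereTessellation(724))
  fitB <- shBasis(4, sphereTessellation(180))
  u <- c(1, numeric(14))
  expect_null(odfPrincipalDirection(u, basis))
  # single fiber along +z via the phantom's Gaussian ODF model
  ax <- matrix(c(0, 0, 1), 1)
  s <- (1 / 0.3 + (1 / 1.6 - 1 / 0.3) *
          (fitB$directions %*% t(ax))^2)^(-1.5)
  cf <- sqrtOdfFit(as.vector(s), fitB)
  d <- odfPrincipalDirection(cf, basis)
  edgeAngle <- acos(1 - 4 / 724) # approximate vertex spacing
  expect_gt(abs(d[3]), cos(edgeAngle))
  # antipodal consistency: reflecting the ODF changes nothing (even basis)
  expect_gt(gfa(cf), 0)
  vd <- odfValidity(cf, basis)
  expect_true(vd$unitNormOk)
})

test_that("odf validity reports unit norm and amplitude sign", {
  basis <- shBasis(4, sphereTessellation(724))
  u <- c(1, numeric(14))
  v <- odfValidity(u, basis)
  expect_true(v$unitNormOk)
  expect_equal(v$minAmplitude, 1 / sqrt(4 * pi), tolerance = 1e-10)
  v2 <- odfValidity(-u, basis)
  expect_true(v2$unitNormOk)
  expect_lt(v2$minAmplitude, 0)
  set.seed(205)
  ok <- vapply(1:200, function(i)
    odfValidity(odfExp(rnorm(15)), basis)$unitNormOk, logical(1))
  expect_true(all(ok))
})

test_that("field-level ODF maps invert each other and GFA map is consistent", {
  set.seed(206)
  n <- 4
  cf <- t(vapply(1:(n^3), function(i) odfExp(rnorm(15, sd = 0.4)),
                 numeric(15)))
  f <- odfField(array(cf, c(n, n, n, 15)), 1, 4L, "sphere")
  tan <- odfFieldLog(f)
  expect_equal(tan@space, "tangent")
  back <- odfFieldExp(tan)
  expect_equal(volData(back), volData(f), tolerance = 1e-10)
  expect_equal(as.vector(gfaMap(f)), as.vector(gfaMap(tan)), tolerance = 1e-10)
  expect_equal(odfFieldValidity(f)$nInvalid, 0)
})
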