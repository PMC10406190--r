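test_that("LSGAN losses have their closed-form fixed points", {
  expect_equal(lsganDiscriminatorLoss(rep(1, 4), rep(0, 4)), 0)
  expect_equal(lsganDiscriminatorLoss(0.5, 0.5), 0.25)
  expect_equal(lsganGeneratorLoss(rep(1, 3)), 0)
  expect_equal(lsganGeneratorLoss(0), 0.5)
  expect_error(lsganDiscriminatorLoss(NaN, 0), "diverged")
})

test_that("anisotropy weights floor isotropic tissue and keep fibers at FA", {
  # isotropic field -> all weights at the floor
  iso <- array(rep(as.vector(diag(3)), each = 4^3), c(4, 4, 4, 9))
  w <- anisotropyWeights(tensorField(iso, 1), floor = 0.05)
  expect_true(all(w == 0.05))
  ph <- smallPhantom()
  w2 <- anisotropyWeights(ph$tensors, floor = 0.05)
  expect_true(all(abs(w2[ph$bundleMasks[[1]]] - 0.8) < 1e-6))
  expect_true(all(w2 >= 0.05 & w2 <= 1))
  # weighted mean of a constant error field equals constant * mean(w)
  err <- 0.3
  expect_equal(mean(err * w2), err * mean(w2), tolerance = 1e-12)
})

test_that("cycle loss equals a loop-based oracle and is zero at its fixed point", {
  set.seed(401)
  d <- c(4, 4, 4)
  x <- array(runif(prod(d)), d)
  yUp <- array(rnorm(prod(d) * 9, sd = 0.3), c(d, 9))
  yLr <- array(rnorm(2^3 * 9, sd = 0.3), c(2, 2, 2, 9))
  wHr <- array(runif(prod(d), 0.05, 1), d)
  wLr <- array(runif(8, 0.05, 1), c(2, 2, 2))
  idF <- function(z) z
  # exact reconstructions -> 0 (F must map yUp's grid to yLr's exactly)
  Fex <- function(z) yLr
  GXex <- function(z) if (length(dim(z)) == 4) x else x
  GYex <- function(z) yUp
  expect_equal(cycleLoss(x, yUp, yLr, GXex, GYex, Fex, lossWeights(), wHr, wLr), 0)
  # constant offset on the structural cycle only
  delta <- 0.07
  GXoff <- function(z) if (length(dim(z)) == 4) x + delta else x + delta
  w <- lossWeights()
  expect_equal(cycleLoss(x, yUp, yLr, function(z) x + delta, GYex, Fex,
                         w, wHr, wLr),
               w$cycX * delta, tolerance = 1e-12)
  # generic case against an explicit loop oracle
  GY2 <- function(z) yUp + 0.1
  GX2 <- function(z) if (length(dim(z)) == 4) x + 0.05 else x + 0.05
  F2 <- function(z) yLr - 0.2
  got <- cycleLoss(x, yUp, yLr, GX2, GY2, F2, w, wHr, wLr)
  # oracle computed element-by-element
  o1 <- w$cycX * mean(abs(GX2(GY2(x)) - x))
  t2 <- abs(GY2(GX2(yUp)) - yUp)
  o2 <- 0.5 * w$cycY * mean(as.vector(t2) * rep(as.vector(wHr), 9))
  t3 <- abs(F2(GY2(GX2(yUp))) - yLr)
  o3 <- 0.5 * w$cycY * mean(as.vector(t3) * rep(as.vector(wLr), 9))
  expect_equal(got, o1 + o2 + o3, tolerance = 1e-12)
})

test_that("prior loss matches its oracle and validates pairing", {
  set.seed(402)
  d <- c(4, 4, 4)
  x <- array(runif(prod(d)), d)
  yUp <- array(rnorm(prod(d) * 9, sd = 0.3), c(d, 9))
  w <- lossWeights()
  expect_equal(priorLoss(x, yUp, function(z) x, function(z) yUp, w), 0)
  delta <- 0.11
  expect_equal(priorLoss(x, yUp, function(z) x, function(z) yUp + delta, w),
               w$priorY * delta, tolerance = 1e-12)
  # anisotropy-weighted diffusion term against a loop oracle
  wv <- array(runif(prod(d), 0.05, 1), d)
  GY3 <- function(z) yUp + 0.2
  got <- priorLoss(x, yUp, function(z) x, GY3, w, wv)
  oracle <- w$priorY * mean(rep(as.vector(wv), 9) * 0.2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(priorLoss(x, array(0, c(5, 5, 5, 9)), identity, identity, w),
               "aligned")
})

test_that("full objective decomposes into its independently computed parts", {
  set.seed(403)
  d <- c(4, 4, 4)
  batch <- list(x = array(runif(prod(d)), d),
                yUp = array(rnorm(prod(d) * 9, sd = 0.3), c(d, 9)),
                yLr = array(rnorm(8 * 9, sd = 0.3), c(2, 2, 2, 9)),
                pairedX = array(runif(prod(d)), d),
                pairedYUp = array(rnorm(prod(d) * 9, sd = 0.3), c(d, 9)))
  models <- list(
    GY = function(z) batch$yUp * 0.9,
    GX = function(z) if (length(dim(z)) == 4) batch$x * 0.8 else batch$x * 0.8,
    F = function(z) batch$yLr * 1.1,
    DY = function(z) 0.3,
    DX = function(z) 0.6)
  w <- lossWeights()
  r <- fullObjective(batch, models, w)
  expect_equal(r$generator,
               r$adversarialX + r$adversarialY + r$cycle + r$prior)
  expect_equal(r$adversarialY, lsganGeneratorLoss(0.3))
  expect_equal(r$discX,
               lsganDiscriminatorLoss(models$DX(batch$x), 0.6))
  expect_equal(r$cycle,
               cycleLoss(batch$x, batch$yUp, batch$yLr, models$GX, models$GY,
                         models$F, w))
  # all-zero fixed point
  models0 <- list(GY = function(z) batch$yUp, GX = function(z) batch$x,
                  F = function(z) batch$yLr, DY = function(z) 1,
                  DX = function(z) 1)
  # with perfect generators and fooled discriminators the generator-side
  # cycle and prior vanish
  r0 <- fullObjective(list(x = batch$x, yUp = batch$yUp, yLr = batch$yLr,
                           pairedX = batch$x, pairedYUp = batch$yUp),
                      models0, w)
  expect_equal(r0$cycle, 0)
  expect_equal(r0$prior, 0)
  expect_equal(r0$adversarialX + r0$adversarialY, 0)
})
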