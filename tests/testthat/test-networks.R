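test_that("generator respects shape and output-range contracts", {
  set.seed(301)
  G <- buildGenerator(generatorSpec(1, 1, "sigmoid", depth = 1, baseWidth = 2))
  x <- array(runif(16^3), c(16, 16, 16))
  y <- netApply(G, x)
  expect_equal(dim(y), c(16L, 16L, 16L))
  expect_true(all(y >= 0 & y <= 1))
  Gd <- buildGenerator(generatorSpec(1, 9, "hardtanh", depth = 1, baseWidth = 2,
                                     activationBound = 3))
  yd <- netApply(Gd, x)
  expect_equal(dim(yd)[4], 9L)
  expect_true(all(abs(yd) <= 3))
  expect_gt(nParams(Gd), 0)
})

test_that("manifold decoding yields valid fields for arbitrary weights", {
  set.seed(302)
  x <- array(runif(12^3), c(12, 12, 12))
  for (rep in 1:3) {
    Gd <- buildGenerator(generatorSpec(1, 9, "hardtanh", depth = 1, baseWidth = 2))
    tf <- decodeDiffusion(netApply(Gd, x), "dt", spacing = 0.7)
    expect_s4_class(tf, "TensorField")
    expect_equal(fieldValidity(tf)$nInvalid, 0)
    Go <- buildGenerator(generatorSpec(1, 15, "tanh", depth = 1, baseWidth = 2))
    of <- decodeDiffusion(netApply(Go, x), "odf", spacing = 0.7)
    expect_s4_class(of, "OdfField")
    expect_equal(odfFieldValidity(of)$nInvalid, 0)
  }
})

test_that("discriminator returns one scalar score per volume", {
  set.seed(303)
  D <- buildDiscriminator(discriminatorSpec(9, c(4, 8)))
  y <- netApply(D, array(rnorm(9 * 9^3), c(9, 9, 9, 9)))
  expect_length(y, 1)
  expect_true(is.finite(y))
})

test_that("downsampler reduces 32^3 to 18^3 and is trilinear when zeroed", {
  set.seed(304)
  F <- buildDownsampler(downsamplerSpec(9, 0.7, 1.25, c(18, 18, 18), hidden = 3))
  x <- array(rnorm(9 * 32^3), c(32, 32, 32, 9))
  y <- netApply(F, x)
  expect_equal(dim(y), c(18L, 18L, 18L, 9L))
  # learned correction is zero-initialized: constant fields map to constants
  cst <- array(rep(1:9, each = 32^3), c(32, 32, 32, 9))
  yc <- netApply(F, cst)
  expect_lt(max(abs(sweep(matrix(yc, ncol = 9), 2, 1:9))), 1e-5)
})

test_that("backpropagation matches finite differences for all architectures", {
  set.seed(305)
  # exact check in double precision (the training default is single)
  withr::local_options(dmrisynth.convSingle = FALSE)
  ns <- asNamespace("dmrisynth")
  checkGrads <- function(net, dims, cin, lossGrad) {
    x <- matrix(rnorm(prod(dims) * cin), ncol = cin)
    fw <- ns$netForward(net, x, dims, keep = TRUE)
    ns$zeroGrad(net)
    dy <- lossGrad(fw$y)
    dx <- ns$netBackward(net, fw$cache, dy, needDx = TRUE)
    loss <- function() {
      y <- ns$netForward(net, x, dims)$y
      if (length(y) == 1) 0.5 * (y - 1)^2 else 0.5 * sum(y^2)
    }
    for (nm in names(net$par)) {
      i <- sample(length(net$par[[nm]]$W), 1)
      old <- net$par[[nm]]$W[i]
      h <- 1e-6
      net$par[[nm]]$W[i] <- old + h; lp <- loss()
      net$par[[nm]]$W[i] <- old - h; lm <- loss()
      net$par[[nm]]$W[i] <- old
      fd <- (lp - lm) / (2 * h)
      an <- net$grad[[nm]]$W[i]
      expect_lt(abs(fd - an), 1e-5 * max(1, abs(fd)))
    }
    # input gradient at one voxel
    i <- min(50, length(x))
    old <- x[i]
    h <- 1e-6
    x[i] <- old + h
    fw2 <- ns$netForward(net, x, dims)
    lp <- if (length(fw2$y) == 1) 0.5 * (fw2$y - 1)^2 else 0.5 * sum(fw2$y^2)
    x[i] <- old - h
    fw3 <- ns$netForward(net, x, dims)
    lm <- if (length(fw3$y) == 1) 0.5 * (fw3$y - 1)^2 else 0.5 * sum(fw3$y^2)
    x[i] <- old
    expect_lt(abs((lp - lm) / (2 * h) - dx[i]), 1e-5 * max(1, abs(dx[i])))
  }
  G <- buildGenerator(generatorSpec(2, 3, "tanh", depth = 1, baseWidth = 2))
  checkGrads(G, c(8, 8, 8), 2, function(y) y)
  D <- buildDiscriminator(discriminatorSpec(3, c(2, 4)))
  checkGrads(D, c(7, 7, 7), 3, function(y) y - 1)
  F <- buildDownsampler(downsamplerSpec(3, 0.7, 1.25, c(5, 5, 5), hidden = 2))
  F$par$r3$W[] <- rnorm(length(F$par$r3$W), sd = 0.05)
  checkGrads(F, c(8, 8, 8), 3, function(y) y)
})
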