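test_that("subject splits are reproducible, disjoint and correctly sized", {
  cfg <- runConfig(seed = 5, nPriorPaired = 2)
  s1 <- splitSubjects(1:20, cfg)
  s2 <- splitSubjects(1:20, cfg)
  expect_identical(s1, s2)
  expect_length(c(s1$trainX, s1$trainY, s1$paired), 14)
  expect_length(s1$validation, 4)
  expect_length(s1$test, 2)
  all <- c(s1$trainX, s1$trainY, s1$paired, s1$validation, s1$test)
  expect_equal(sort(all), 1:20)
  expect_length(intersect(s1$trainX, s1$trainY), 0)
  # full-scale split proportions
  s3 <- splitSubjects(1:1065, runConfig(seed = 1, nPriorPaired = 50))
  expect_length(c(s3$trainX, s3$trainY, s3$paired), 746)
  expect_length(s3$validation, 213)
  expect_length(s3$test, 106)
  expect_length(s3$paired, 50)
  expect_length(s3$trainX, 348)
  expect_length(s3$trainY, 348)
  expect_error(splitSubjects(1:4, cfg), "at least 5")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- deskRunConfig("dt", seed = 9, hrPatch = 12L, lrPatch = 7L,
                       patchesPerEpoch = 24L, epochs = 1L)
  data <- phantomDataset(10, cfg, gridShape = c(16, 16, 16), seed = 50L)
  a <- trainModel(cfg, data)
  b <- trainModel(cfg, data)
  expect_identical(a$log, b$log)
  expect_identical(a$nets$GY$par$final$W, b$nets$GY$par$final$W)
})

test_that("supervised baseline trains and manifold mode stays valid every epoch", {
  cfg <- deskRunConfig("dt", seed = 3, hrPatch = 12L, lrPatch = 7L,
                       patchesPerEpoch = 48L, epochs = 2L, mode = "ma_unet")
  data <- phantomDataset(10, cfg, gridShape = c(16, 16, 16), seed = 60L)
  ck <- trainModel(cfg, data)
  expect_equal(nrow(ck$log), 2)
  expect_true(all(is.finite(ck$log$valLoss)))
  # supervised l1 decreases over epochs on this easy task
  expect_lt(ck$log$gLoss[2], ck$log$gLoss[1])
  out <- inferVolume(data[[1]]$phantom$structural, ck)
  expect_equal(fieldValidity(out)$nInvalid, 0)
})

test_that("no-manifold baseline admits weight states with invalid tensors", {
  cfg <- deskRunConfig("dt", seed = 4, hrPatch = 12L, lrPatch = 7L,
                       mode = "unet")
  ck <- initializeModels(cfg)
  # construct the weight state: zero all layers, set the final bias to a
  # matrix with a negative eigenvalue
  for (nm in names(ck$nets$GY$par)) {
    ck$nets$GY$par[[nm]]$W[] <- 0
    ck$nets$GY$par[[nm]]$b[] <- 0
  }
  ck$nets$GY$par$final$b <- as.vector(t(diag(c(1, 1, -1))))
  ck$init <- ck$nets
  ph <- smallPhantom(grid = 16, odf = FALSE)
  out <- inferVolume(ph$structural, ck)
  expect_s4_class(out, "TensorField")
  v <- fieldValidity(out)
  expect_gte(v$nInvalid, 1)
})

test_that("inference blends patches consistently and is deterministic", {
  cfg <- deskRunConfig("dt", seed = 6, hrPatch = 12L, lrPatch = 7L)
  ck <- initializeModels(cfg)
  ck$init <- ck$nets
  ph <- smallPhantom(grid = 16, odf = FALSE)
  a <- inferVolume(ph$structural, ck)
  b <- inferVolume(ph$structural, ck)
  expect_identical(volData(a), volData(b))
  # constant input: overlap amount does not change the constant output
  cst <- structuralVolume(array(0.5, c(16, 16, 16)), 0.7)
  o1 <- inferVolume(cst, ck, overlap = 0)
  o2 <- inferVolume(cst, ck, overlap = 0.5)
  expect_equal(volData(o1), volData(o2), tolerance = 1e-6)
  expect_error(inferVolume(structuralVolume(array(0.5, c(8, 8, 8)), 0.7), ck),
               "smaller")
})

test_that("random-weight ODF generation is valid after inference blending", {
  cfg <- deskRunConfig("odf", seed = 8, hrPatch = 12L, lrPatch = 7L)
  ck <- initializeModels(cfg)
  ck$init <- ck$nets
  ph <- smallPhantom(grid = 16, odf = FALSE)
  out <- inferVolume(ph$structural, ck)
  expect_s4_class(out, "OdfField")
  expect_equal(out@space, "sphere")
  expect_equal(odfFieldValidity(out)$nInvalid, 0)
})

test_that("ODF-modality adversarial training runs and stays on the sphere", {
  cfg <- deskRunConfig("odf", seed = 2, hrPatch = 12L, lrPatch = 7L,
                       patchesPerEpoch = 24L, epochs = 1L)
  data <- phantomDataset(10, cfg, gridShape = c(16, 16, 16), seed = 70L)
  ck <- trainModel(cfg, data)
  expect_true(all(is.finite(ck$log$gLoss)))
  out <- inferVolume(data[[1]]$phantom$structural, ck)
  expect_equal(odfFieldValidity(out)$nInvalid, 0)
})
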