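test_that("the default architecture has 5 two-conv decoder blocks", {
  model <- buildEnDeNet(segModelConfig(inChannels = 2L), seed = 1)
  expect_length(model@params$dec, 5L)
  for (blk in model@params$dec)
    expect_identical(sort(names(blk)), c("conv1", "conv2"))
  ## first decoder block emits 256 channels, last 16
  expect_equal(dim(model@params$dec[[1]]$conv1$w)[4], 256L)
  expect_equal(dim(model@params$dec[[5]]$conv2$w)[4], 16L)
  ## decoder convolutions are all 3x3
  for (blk in model@params$dec) {
    expect_equal(dim(blk$conv1$w)[1:2], c(3L, 3L))
    expect_equal(dim(blk$conv2$w)[1:2], c(3L, 3L))
  }
  expect_error(segModelConfig(decoderChannels = c(16L, 32L, 64L, 128L, 256L)),
               "decreasing")
})

test_that("forward maps a 2-channel input to an in-range probability map", {
  model <- buildEnDeNet(segModelConfig(
    inChannels = 2L, encoderChannels = c(4L, 6L, 8L, 10L, 12L),
    decoderChannels = c(12L, 10L, 8L, 6L, 4L)), seed = 2)
  x <- array(runif(128 * 128 * 2), c(128, 128, 2, 1))
  p <- predictSegmentation(model, x)
  expect_equal(dim(p), c(128L, 128L, 1L))
  expect_true(all(p > 0 & p < 1))
  ## indivisible spatial size errors at forward time
  bad <- array(runif(100 * 100 * 2), c(100, 100, 2, 1))
  expect_error(predictSegmentation(model, bad), "divisible")
})

test_that("a small model learns on separable phantoms deterministically", {
  train <- phantomSet(64, imageSize = 32L, seed = 31L)
  cfg <- segModelConfig(encoder = "tiny5", encoderDepth = 3L,
                        encoderChannels = c(4L, 8L, 16L),
                        decoderChannels = c(16L, 8L, 4L))
  model <- buildEnDeNet(cfg, seed = 3)
  tc <- segTrainConfig(maxEpochs = 5L, batchSize = 16L, lr = 0.003)
  r <- trainSegmentation(model, train, valData = train[1:8], trainCfg = tc,
                         seed = 4L)
  expect_lt(tail(r$history$train_loss, 1), r$history$train_loss[1])
  expect_equal(nrow(r$history), 5L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in%
                    names(r$history)))

  ## determinism: identical histories and identical predictions
  r2 <- trainSegmentation(buildEnDeNet(cfg, seed = 3), train,
                          valData = train[1:8], trainCfg = tc, seed = 4L)
  expect_identical(r$history, r2$history)
  p1 <- predictSegmentation(r$model, train[1:2])
  p2 <- predictSegmentation(r2$model, train[1:2])
  expect_identical(p1, p2)
  expect_error(trainSegmentation(model, list()), "empty")
})

test_that("plateau scheduler fires after the configured patience", {
  s <- plateauScheduler(0.001, factor = 0.1, patience = 5L)
  s <- plateauStep(s, 0.5)                 # establishes the minimum
  for (k in 1:4) {
    s <- plateauStep(s, 0.5)               # unchanged loss
    expect_equal(s$lr, 0.001)
  }
  s <- plateauStep(s, 0.5)                 # fifth flat epoch
  expect_equal(s$lr, 1e-4)
  ## an improvement resets the wait counter
  s2 <- plateauScheduler(0.01, patience = 3L)
  s2 <- plateauStep(s2, 1.0)
  s2 <- plateauStep(s2, 1.0); s2 <- plateauStep(s2, 1.0)
  s2 <- plateauStep(s2, 0.5)
  expect_equal(s2$wait, 0L)
  expect_equal(s2$lr, 0.01)
  ## repeated plateaus exhaust the scheduler below minLR
  s3 <- plateauScheduler(1e-5, patience = 1L, minLR = 1e-6)
  s3 <- plateauStep(s3, 1); s3 <- plateauStep(s3, 1); s3 <- plateauStep(s3, 1)
  expect_true(s3$exhausted)
})

test_that("binarization thresholds at 0.5 with ties to foreground", {
  expect_equal(binarize(matrix(0.7, 3, 3)), matrix(1, 3, 3))
  expect_equal(binarize(matrix(0.5, 1, 1)), matrix(1, 1, 1))
  expect_equal(binarize(matrix(0.499, 1, 1)), matrix(0, 1, 1))
  set.seed(12)
  m <- matrix(runif(100), 10, 10)
  expect_identical(binarize(m), (m >= 0.5) * 1)
})

test_that("fragment clearing drops components below the area threshold", {
  m <- matrix(0, 64, 64)
  m[2:3, 2:3] <- 1                         # area 4 fragment
  m[10:49, 10:47] <- 1                     # area 1520 component
  out <- clearFragments(m, minArea = 1024L)
  expect_equal(sum(out), 40 * 38)
  expect_equal(out[2, 2], 0)
  expect_equal(clearFragments(matrix(0, 8, 8)), matrix(0, 8, 8))

  ## a component of exactly minArea pixels is retained (strict "less than")
  m2 <- matrix(0, 40, 40)
  m2[1:32, 1:32] <- 1                      # exactly 1024 pixels
  expect_equal(sum(clearFragments(m2, 1024L)), 1024)
  m3 <- matrix(0, 40, 40)
  m3[1:31, 1:33] <- 1                      # 1023 pixels
  expect_equal(sum(clearFragments(m3, 1024L)), 0)

  ## diagonal pixels form one 8-connected component
  d <- matrix(0, 6, 6); d[cbind(1:4, 1:4)] <- 1
  expect_equal(sum(clearFragments(d, 4L)), 4)
  expect_equal(sum(clearFragments(d, 5L)), 0)
})

test_that("fragment clearing matches a brute-force flood fill", {
  set.seed(13)
  for (i in 1:30) {
    m <- randomMask(15, 15, 0.45)
    for (minArea in c(2L, 5L, 10L))
      expect_identical(clearFragments(m, minArea),
                       naiveClearFragments(m, minArea))
  }
})

test_that("binarize then clear is idempotent", {
  set.seed(14)
  for (i in 1:10) {
    p <- matrix(runif(400), 20, 20)
    once <- clearFragments(binarize(p), minArea = 5L)
    twice <- clearFragments(binarize(once), minArea = 5L)
    expect_identical(once, twice)
  }
})

test_that("mask union behaves as a pixel-wise OR ensemble", {
  m <- randomMask(8, 8)
  expect_identical(unionEnsemble(list(m, matrix(0, 8, 8))), m * 1)
  expect_identical(unionEnsemble(list(m, m)), m * 1)
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(sum(unionEnsemble(list(a, b))), 2)
  expect_error(unionEnsemble(list(a, matrix(0, 5, 5))), "mismatch")
})

test_that("segmentation models serialize to a directory and back", {
  cfg <- segModelConfig(encoder = "tiny5", encoderDepth = 3L,
                        encoderChannels = c(4L, 6L, 8L),
                        decoderChannels = c(8L, 6L, 4L))
  model <- buildEnDeNet(cfg, seed = 5)
  dir <- tempfile()
  saveSegModel(model, dir)
  back <- loadSegModel(dir)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(predictSegmentation(back, x),
                   predictSegmentation(model, x))
})
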