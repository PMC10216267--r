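test_that("SubNet forward shapes follow the pooling arithmetic", {
  ## preset A (3 pooled 3x3 groups) on 32x32x1 -> 4x4x32
  mod <- buildSubNet(subnetPreset("A"), inChannels = 1, seed = 1)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  y <- GraMNet:::.subnetFw(mod, x, train = FALSE)$y
  expect_equal(dim(y), c(4L, 4L, 32L, 1L))
  ## ReLU: all post-activation values non-negative
  expect_true(all(y >= 0))

  ## zero-weight module maps to the zero feature map
  z <- mod
  for (g in seq_along(z@params)) {
    z@params[[g]]$w[] <- 0; z@params[[g]]$b[] <- 0
    z@params[[g]]$beta[] <- 0
  }
  expect_equal(max(abs(GraMNet:::.subnetFw(z, x, train = FALSE)$y)), 0)

  ## pooling below 2 pixels errors
  small <- array(runif(4 * 4), c(4, 4, 1, 1))
  expect_error(GraMNet:::.subnetFw(mod, small, train = FALSE), "pooling")
  ## adaptSpecToInput turns off infeasible pooling flags
  sp <- adaptSpecToInput(subnetPreset("A"), c(4L, 4L))
  expect_identical(sp@useMaxpool, c(TRUE, TRUE, FALSE))
})

test_that("softmax head emits normalized probabilities", {
  mod <- buildSubNet(subnetPreset("A"), 1, seed = 2)
  net <- gramnetFromSubnet(mod, inputSize = c(32L, 32L), seed = 2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  p <- forwardWithHead(net, x)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  ## zero head weights -> uniform probabilities 1/M
  net0 <- net
  net0@head@w[] <- 0; net0@head@b[] <- 0
  expect_equal(as.numeric(forwardWithHead(net0, x)), rep(0.5, 6))

  ## two-class softmax matches the scalar formula
  logits <- c(a = 1.3, b = -0.4)
  sm <- GraMNet:::.softmaxCols(matrix(logits, 2, 1))
  expect_equal(sm[1, 1], exp(1.3) / (exp(1.3) + exp(-0.4)))
})

test_that("series combination composes and counts layers L_A + L_B + 1", {
  A <- buildSubNet(subnetPreset("A"), 1, seed = 3)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 3)
  specB <- adaptSpecToInput(subnetPreset("B"), c(4L, 4L))
  B <- buildSubNet(specB, 32, seed = 4)
  comb <- combineSeries(net, B, inputSize = c(32L, 32L), seed = 5)

  expect_equal(GraMNet:::.treeConvLayers(comb@tree), 6)  # L_A + L_B
  ## + 1 fully connected head layer
  expect_equal(comb@head@nClasses, 2L)

  ## base is frozen, new SubNet trainable
  leaves <- GraMNet:::.treeLeaves(comb@tree)
  expect_true(leaves[[1]]@frozen)
  expect_false(leaves[[2]]@frozen)

  ## channel interface is validated
  badB <- buildSubNet(specB, 16, seed = 4)
  expect_error(combineSeries(net, badB, inputSize = c(32L, 32L)),
               "channel mismatch")

  ## forward of the combined net equals A's features fed through B + head
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  featA <- GraMNet:::.subnetFw(leaves[[1]], x, train = FALSE)$y
  featB <- GraMNet:::.subnetFw(leaves[[2]], featA, train = FALSE)$y
  z <- GraMNet:::.gapFw(featB)
  manual <- t(GraMNet:::.softmaxCols(comb@head@w %*% z + comb@head@b))
  expect_equal(unname(forwardWithHead(comb, x)), manual, tolerance = 1e-12)
})

test_that("parallel combination aligns, concatenates and freezes", {
  A <- buildSubNet(subnetPreset("B"), 1, seed = 6)   # depth 256, 3 pools
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 6)
  specC <- SubNetSpec(list(c(1, 1, 8), c(1, 1, 32)), useMaxpool = TRUE)
  C <- buildSubNet(specC, 1, seed = 7)               # depth 32, 2 pools
  comb <- combineParallel(net, C, inputSize = c(32L, 32L), seed = 8)

  ## concatenated depth 256 + 32 = 288
  sh <- GraMNet:::.treeOutShape(comb@tree, c(32L, 32L), 1L)
  expect_equal(sh[3], 288)
  ## spatial alignment to the smaller (deeper-pooled) map
  expect_equal(sh[1:2], c(4, 4))

  ## both branches read the identical raw input
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw <- GraMNet:::.treeFw(comb@tree, x, train = FALSE, grad = TRUE)
  expect_identical(fw$cache$first$cache$sub[[1]]$x,
                   fw$cache$second$cache$sub[[1]]$x)

  ## concatenation carries branch outputs (second branch aligned by mean)
  ya <- GraMNet:::.subnetFw(GraMNet:::.treeLeaves(comb@tree)[[1]], x,
                            train = FALSE)$y
  expect_equal(fw$y[, , 1:256, , drop = FALSE], ya)

  ## channel precondition
  bad <- buildSubNet(specC, 3, seed = 7)
  expect_error(combineParallel(net, bad, inputSize = c(32L, 32L)),
               "raw input")
})

test_that("series composition matches a naive layer-by-layer oracle", {
  set.seed(10)
  for (rep in 1:6) {
    specA <- SubNetSpec(list(c(3, 3, 3)), useBatchnorm = FALSE,
                        useMaxpool = TRUE)
    specB <- SubNetSpec(list(c(1, 3, 2), c(3, 1, 4)), useBatchnorm = FALSE,
                        useMaxpool = c(FALSE, TRUE))
    A <- buildSubNet(specA, 1, seed = rep)
    B <- buildSubNet(specB, 3, seed = rep + 50)
    x3 <- array(runif(8 * 8), c(8, 8, 1))
    got <- GraMNet:::.subnetFw(B, GraMNet:::.subnetFw(
      A, array(x3, c(8, 8, 1, 1)), train = FALSE)$y, train = FALSE)$y
    want <- naiveSubnetForward(B, naiveSubnetForward(A, x3))
    expect_equal(got[, , , 1], want, tolerance = 1e-10)
  }
})

test_that("parameter counting matches closed-form arithmetic", {
  ## single 3x3 conv, 1 -> 8 channels, bias, no BN: 3*3*1*8 + 8 = 80
  sp <- SubNetSpec(list(c(3, 3, 8)), useBatchnorm = FALSE)
  expect_equal(countParameters(buildSubNet(sp, 1, seed = 1)), 80)
  expect_equal(specParameterCount(sp, 1), 80)
  expect_equal(countParameters(list()), 0L)

  ## batch norm adds scale and shift
  spbn <- SubNetSpec(list(c(3, 3, 8)), useBatchnorm = TRUE)
  expect_equal(countParameters(buildSubNet(spbn, 1, seed = 1)), 96)

  ## SubNet B conv stack on 32 input channels, weights + biases:
  ## 3*3*32*64+64 + 3*3*64*128+128 + 3*3*128*256+256 = 387,520
  nB <- specParameterCount(subnetPreset("B"), 32, useBatchnorm = FALSE)
  expect_equal(nB, 387520)
  expect_lt(abs(nB - 390000) / 390000, 0.01)
})

test_that("MAdd counting follows the conv cost model", {
  ## 1x1 conv, 1 -> 1 channel, on 4x4 input: 16 MAdds
  sp <- SubNetSpec(list(c(1, 1, 1)), useBatchnorm = FALSE, useMaxpool = FALSE)
  m <- buildSubNet(sp, 1, seed = 1)
  expect_equal(countMAdd(m, c(4, 4)), 16)
  ## doubling both spatial dims quadruples conv MAdds
  expect_equal(countMAdd(m, c(8, 8)), 4 * countMAdd(m, c(4, 4)))
  ## pooled stacks accumulate at shrinking resolutions
  spA <- subnetPreset("A")
  mA <- buildSubNet(spA, 1, seed = 1)
  want <- 32 * 32 * 9 * 1 * 8 + 16 * 16 * 9 * 8 * 16 + 8 * 8 * 9 * 16 * 32
  expect_equal(countMAdd(mA, c(32, 32)), want)
  ## graph-level count includes the head
  net <- gramnetFromSubnet(mA, inputSize = c(32L, 32L))
  expect_equal(countMAdd(net, c(32, 32)), want + 32 * 2)
})

test_that("GraMNet graphs serialize to a directory and back", {
  A <- buildSubNet(subnetPreset("A"), 1, seed = 11)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 11)
  specE <- adaptSpecToInput(subnetPreset("E"), c(32L, 32L))
  E <- buildSubNet(specE, 1, seed = 12)
  net <- combineParallel(net, E, inputSize = c(32L, 32L), seed = 13)
  dir <- tempfile()
  saveGramnet(net, dir)
  back <- loadGramnet(dir)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_equal(forwardWithHead(back, x), forwardWithHead(net, x))
  expect_identical(vapply(GraMNet:::.treeLeaves(back@tree),
                          function(m) m@frozen, logical(1)),
                   c(TRUE, FALSE))
})
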