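test_that("staged training requires exactly one unfrozen SubNet", {
  samples <- phantomSet(8, imageSize = 32L, seed = 21L)
  spec <- SubNetSpec(list(c(3, 3, 4)), useMaxpool = TRUE)
  A <- buildSubNet(spec, 1, seed = 1)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L))
  frozenNet <- freezeParameters(net)
  expect_error(trainStage(frozenNet, samples), "exactly one unfrozen")

  B <- buildSubNet(SubNetSpec(list(c(3, 3, 4)), useMaxpool = FALSE), 1,
                   seed = 2)
  twoLive <- net
  twoLive@tree <- list(op = "parallel", first = net@tree,
                       second = GraMNet:::.leafNode(B))
  expect_error(trainStage(twoLive, samples), "exactly one unfrozen")
})

test_that("training touches only the unfrozen SubNet and the head", {
  samples <- phantomSet(24, imageSize = 32L, seed = 22L)
  A <- buildSubNet(adaptSpecToInput(subnetPreset("A"), c(32L, 32L)), 1,
                   seed = 3)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 3)
  r1 <- trainStage(net, samples, cfg = stageTrainConfig(epochs = 2L,
                                                        batchSize = 8L))
  specB <- adaptSpecToInput(subnetPreset("B"), c(4L, 4L))
  B <- buildSubNet(specB, 32, seed = 4)
  net2 <- combineSeries(r1$net, B, inputSize = c(32L, 32L), seed = 4)

  before <- frozenLeafParams(net2)
  hashBefore <- paramHash(before)
  r2 <- trainStage(net2, samples, cfg = stageTrainConfig(epochs = 2L,
                                                         batchSize = 8L))
  after <- frozenLeafParams(r2$net)
  expect_identical(before, after)               # bit-identical tensors
  expect_identical(hashBefore, paramHash(after))
  ## the trainable SubNet did move
  liveBefore <- GraMNet:::.treeLeaves(net2@tree)[[2]]@params
  liveAfter <- GraMNet:::.treeLeaves(r2$net@tree)[[2]]@params
  expect_false(identical(liveBefore, liveAfter))
})

test_that("learning rate drops by 0.1 at half of the epochs", {
  samples <- phantomSet(16, imageSize = 32L, seed = 23L)
  A <- buildSubNet(adaptSpecToInput(subnetPreset("A"), c(32L, 32L)), 1,
                   seed = 5)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 5)
  cfg <- stageTrainConfig(epochs = 6L, batchSize = 8L, initialLR = 0.001)
  r <- trainStage(net, samples, cfg = cfg)
  h <- r$history
  expect_equal(unique(h$lr[h$epoch < 3]), 0.001)
  expect_equal(unique(h$lr[h$epoch >= 3]), 0.0001)   # ceiling(6/2) = 3
  ## scheduling helper states the same contract
  expect_equal(halfEpochLR(2, 6, 0.001), 0.001)
  expect_equal(halfEpochLR(3, 6, 0.001), 0.0001)
  expect_equal(halfEpochLR(5, 9, 0.001), 0.0001)
})

test_that("validation patience stops after exactly the configured checks", {
  m <- patienceMonitor(50L)
  m <- patienceStep(m, 1.0)          # establishes the minimum
  for (k in 1:49) {
    m <- patienceStep(m, 1.1)
    expect_false(m$stop)
  }
  m <- patienceStep(m, 1.1)          # the 50th check past the minimum
  expect_true(m$stop)
  ## an improvement resets the counter
  m2 <- patienceMonitor(3L)
  m2 <- patienceStep(m2, 1.0)
  m2 <- patienceStep(m2, 1.2); m2 <- patienceStep(m2, 1.2)
  m2 <- patienceStep(m2, 0.9)
  expect_equal(m2$bad, 0L)
  expect_false(m2$stop)
})

test_that("stage presets encode the two training protocols", {
  d <- stageTrainPreset("default", epochs = 8L)
  expect_equal(d$initialLR, 0.001)
  expect_equal(d$validationEvery, 50L)
  expect_equal(d$validationPatience, 50L)
  expect_equal(d$l2, 1e-4)
  expect_equal(d$lrDropAt, 4L)
  s4 <- stageTrainPreset("section4")
  expect_equal(s4$initialLR, 1e-4)
  expect_equal(s4$batchSize, 16L)
  expect_equal(s4$maxIterations, 500L)
  expect_equal(s4$lrDropAtIteration, 20L)
})

test_that("the five-stage build follows the growth plan", {
  samples <- phantomSet(40, imageSize = 32L, seed = 24L)
  labels <- labelsOf(samples)
  tr <- samples[1:32]; va <- samples[33:40]
  r <- buildAndTrainGramnet(tr, va,
                            cfg = stageTrainConfig(epochs = 1L,
                                                   batchSize = 8L),
                            inputSize = c(32L, 32L), seed = 25L)
  expect_identical(r$stageNames,
                   c("A", "A+B", "A+B||C", "A+B||C+D", "(A+B||C+D)||E"))
  expect_identical(vapply(r$stages, function(s) s$name, character(1)),
                   r$stageNames)
  ## trainable share shrinks: after stage 1, strictly fewer trainable
  ## than total parameters
  for (k in 2:5) {
    st <- r$stages[[k]]
    expect_lt(st$trainableParameters, st$totalParameters)
  }
  ## stage 5 trains SubNet E + head only
  leaves <- GraMNet:::.treeLeaves(r$net@tree)
  frozen <- vapply(leaves, function(m) m@frozen, logical(1))
  expect_equal(sum(!frozen), 1L)
  expect_equal(r$stages[[5]]$trainableParameters,
               countParameters(leaves[[which(!frozen)]]) +
                 countParameters(r$net@head))
  ## every stage's trainable load stays below the largest single SubNet
  ## plus head (the computational-saving contract)
  maxSingle <- max(vapply(leaves, countParameters, numeric(1)))
  headSize <- countParameters(r$net@head)
  for (st in r$stages)
    expect_lte(st$trainableParameters, maxSingle + headSize)
})

test_that("class prediction breaks ties low and tracks scores", {
  A <- buildSubNet(adaptSpecToInput(subnetPreset("A"), c(32L, 32L)), 1,
                   seed = 6)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 6)
  net@head@w[] <- 0; net@head@b[] <- 0
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  expect_warning(p <- predictClass(net, x), "untrained")
  ## uniform probabilities -> first class by the tie rule
  expect_true(all(p$labels == "benign"))
  expect_true(all(p$scores >= 0 & p$scores <= 1))

  net@trained <- TRUE
  set.seed(1)
  net@head@w[] <- rnorm(length(net@head@w))
  p2 <- predictClass(net, x)
  expect_identical(p2$labels == "malignant", p2$scores > 0.5)
})

test_that("stage training histories are reproducible under a fixed seed", {
  samples <- phantomSet(16, imageSize = 32L, seed = 26L)
  A <- buildSubNet(adaptSpecToInput(subnetPreset("A"), c(32L, 32L)), 1,
                   seed = 7)
  net <- gramnetFromSubnet(A, inputSize = c(32L, 32L), seed = 7)
  cfg <- stageTrainConfig(epochs = 2L, batchSize = 8L)
  r1 <- trainStage(net, samples, cfg = cfg, seed = 9L)
  r2 <- trainStage(net, samples, cfg = cfg, seed = 9L)
  expect_identical(r1$history, r2$history)
  expect_identical(GraMNet:::.treeLeaves(r1$net@tree)[[1]]@params,
                   GraMNet:::.treeLeaves(r2$net@tree)[[1]]@params)
})
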