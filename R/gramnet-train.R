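#' Training protocol configuration for one GraMNet stage
#'
#' Adam over the single unfrozen SubNet and the classification head,
#' with the learning rate dropped by a factor of 0.1 once half of the
#' scheduled epochs are completed, validation every `validationEvery`
#' iterations, a validation patience of `validationPatience` checks
#' (training stops when the validation loss has exceeded its running
#' minimum for that many consecutive checks), and L2 regularization of
#' 1e-4 applied to the trainable parameters only.
#'
#' @param epochs scheduled epochs.
#' @param batchSize minibatch size.
#' @param initialLR starting learning rate (default 0.001).
#' @param lrDropFactor multiplicative drop (default 0.1).
#' @param lrDropAt epoch at which the drop applies; default
#'   `ceiling(epochs / 2)`.
#' @param validationEvery iterations between validation checks.
#' @param validationPatience consecutive above-minimum checks before
#'   early stop.
#' @param l2 L2 regularization strength.
#' @param maxIterations optional hard iteration cap (overrides epochs
#'   when smaller).
#' @param lrDropAtIteration optional iteration-based drop point; when
#'   set, the rate drops after this many iterations instead of at
#'   half-epochs.
#' @return a list of class "StageTrainConfig".
#' @export
stageTrainConfig <- function(epochs = 10L, batchSize = 16L,
                             initialLR = 0.001, lrDropFactor = 0.1,
                             lrDropAt = NULL, validationEvery = 50L,
                             validationPatience = 50L, l2 = 1e-4,
                             maxIterations = NULL,
                             lrDropAtIteration = NULL) {
  stopifnot(epochs >= 1, batchSize >= 1, initialLR > 0,
            lrDropFactor > 0, lrDropFactor < 1, validationEvery >= 1,
            validationPatience >= 1, l2 >= 0)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), initialLR = initialLR,
                 lrDropFactor = lrDropFactor,
                 lrDropAt = if (is.null(lrDropAt)) ceiling(epochs / 2)
                            else as.integer(lrDropAt),
                 validationEvery = as.integer(validationEvery),
                 validationPatience = as.integer(validationPatience),
                 l2 = l2, maxIterations = maxIterations,
                 lrDropAtIteration = lrDropAtIteration),
            class = "StageTrainConfig")
}

#' Named stage-training presets
#'
#' `"default"` is the staged protocol above; `"section4"` is the
#' alternative schedule of batch 16, learning rate 1e-4, 500 iterations
#' with a 0.1 drop after 20 iterations.
#'
#' @param name "default" or "section4".
#' @param epochs scheduled epochs (both presets).
#' @return a [stageTrainConfig()].
#' @export
stageTrainPreset <- function(name = c("default", "section4"), epochs = 10L) {
  name <- match.arg(name)
  if (name == "default") return(stageTrainConfig(epochs = epochs))
  stageTrainConfig(epochs = epochs, batchSize = 16L, initialLR = 1e-4,
                   maxIterations = 500L, lrDropAtIteration = 20L)
}

#' Validation-patience early-stopping monitor
#'
#' `patienceMonitor` creates the counter state; `patienceStep` feeds one
#' validation loss. A check whose loss exceeds the running minimum
#' increments the counter; a new minimum resets it; `state$stop` becomes
#' TRUE after `patience` consecutive above-minimum checks.
#'
#' @param patience consecutive above-minimum checks tolerated.
#' @return a state list with `best`, `bad`, `stop`.
#' @export
patienceMonitor <- function(patience = 50L)
  list(patience = as.integer(patience), best = Inf, bad = 0L, stop = FALSE)

#' @rdname patienceMonitor
#' @param state the monitor state.
#' @param valLoss validation loss at this check.
#' @export
patienceStep <- function(state, valLoss) {
  if (valLoss < state$best) {
    state$best <- valLoss
    state$bad <- 0L
  } else if (valLoss > state$best) {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) state$stop <- TRUE
  }
  state
}

## Stack classification samples: x tensor + one-hot M x N truth.
.stackClassif <- function(samples, classes) {
  d <- dim(samples[[1]]@image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- matrix(0, length(classes), n)
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]@image
    m <- match(samples[[i]]@label, classes)
    if (is.na(m)) stop("label not in classes: ", samples[[i]]@label)
    y[m, i] <- 1
  }
  list(x = x, y = y)
}

## Collect (possibly BN-updated) params of unfrozen leaves from a forward
## structure, keyed by preorder leaf index.
.collectLeafParams <- function(node, fw, leafIndex = 1L, out = list()) {
  if (node$op == "leaf") {
    if (!node$module@frozen) out[[as.character(leafIndex)]] <- fw$params
    return(out)
  }
  nFirst <- length(.treeLeaves(node$first))
  out <- .collectLeafParams(node$first, fw$cache$first, leafIndex, out)
  .collectLeafParams(node$second, fw$cache$second, leafIndex + nFirst, out)
}

.unfrozenCount <- function(net)
  sum(vapply(.treeLeaves(net@tree), function(m) !m@frozen, logical(1)))

#' Train one GraMNet stage (the single unfrozen SubNet plus the head)
#'
#' Minimizes the minibatch cross-entropy risk with Adam. Only the
#' parameters of the one unfrozen SubNet and of the classification head
#' change; every frozen parameter (batch-norm statistics included) is
#' bit-identical before and after. Validation runs every
#' `validationEvery` iterations; training stops early when the
#' validation loss has exceeded its running minimum for
#' `validationPatience` consecutive checks.
#'
#' @param net a [GraMNetGraph-class] with exactly one unfrozen SubNet.
#' @param trainData,valData a [DatasetManifest-class] or list of
#'   [PhantomSample-class].
#' @param cfg a [stageTrainConfig()].
#' @param seed RNG seed (shuffling).
#' @param verbose print progress.
#' @return list with `net` (trained), `history` (per-iteration
#'   data.frame: iteration, epoch, train_loss, lr), and `valHistory`
#'   (iteration, val_loss).
#' @export
trainStage <- function(net, trainData, valData = NULL,
                       cfg = stageTrainConfig(), seed = 1L,
                       verbose = FALSE) {
  nTrainable <- .unfrozenCount(net)
  if (nTrainable != 1L)
    stop("staged training requires exactly one unfrozen SubNet (found ",
         nTrainable, ")")
  trainSamples <- .loadSplit(trainData, "train")
  if (length(trainSamples) == 0L) stop("empty training data")
  valSamples <- if (!is.null(valData)) .loadSplit(valData, "val") else list()
  tr <- .stackClassif(trainSamples, net@classes)
  va <- if (length(valSamples)) .stackClassif(valSamples, net@classes)
  n <- dim(tr$x)[4]
  M <- length(net@classes)

  leaves <- .treeLeaves(net@tree)
  trainIdx <- which(vapply(leaves, function(m) !m@frozen, logical(1)))
  key <- as.character(trainIdx)
  adamLeaf <- .adamInit(leaves[[trainIdx]]@params)
  adamHead <- .adamInit(list(w = net@head@w, b = net@head@b))

  history <- valHistory <- data.frame()
  monitor <- patienceMonitor(cfg$validationPatience)
  iter <- 0L; stop.now <- FALSE
  set.seed(.deriveSeed(seed, 31L))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (!is.null(cfg$lrDropAtIteration)) NA else
      if (epoch >= cfg$lrDropAt) cfg$initialLR * cfg$lrDropFactor
      else cfg$initialLR
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    for (b in batches) {
      iter <- iter + 1L
      if (!is.null(cfg$lrDropAtIteration))
        lr <- if (iter > cfg$lrDropAtIteration)
          cfg$initialLR * cfg$lrDropFactor else cfg$initialLR
      xb <- tr$x[, , , b, drop = FALSE]
      yb <- tr$y[, b, drop = FALSE]
      fw <- .treeFw(net@tree, xb, train = TRUE, grad = TRUE)
      ## BN running statistics of the trainable SubNet
      upd <- .collectLeafParams(net@tree, fw)
      net@tree <- .treeSetParams(net@tree, upd)
      z <- .gapFw(fw$y)
      logits <- net@head@w %*% z + net@head@b
      probs <- .softmaxCols(logits)
      loss <- -sum(yb * log(.clampProb(probs))) / M
      dlogits <- (probs - yb) / M
      dW <- tcrossprod(dlogits, z); db <- rowSums(dlogits)
      dz <- crossprod(net@head@w, dlogits)
      dfeat <- .gapBw(dz, dim(fw$y)[1], dim(fw$y)[2])
      acc <- new.env()
      .treeBw(net@tree, fw, dfeat, acc)
      grads <- get(key, envir = acc)

      upLeaf <- .adamUpdate(leaves[[trainIdx]]@params, grads, adamLeaf,
                            iter, lr, l2 = cfg$l2)
      adamLeaf <- upLeaf$s
      leaves <- .treeLeaves(net@tree)       # refresh (BN stats changed)
      newParams <- upLeaf$p
      ## keep running BN statistics from the forward pass (not optimized)
      for (gi in seq_along(newParams)) {
        cur <- leaves[[trainIdx]]@params[[gi]]
        if (!is.null(cur$rmean)) {
          newParams[[gi]]$rmean <- cur$rmean
          newParams[[gi]]$rvar <- cur$rvar
        }
      }
      net@tree <- .treeSetParams(net@tree,
                                 stats::setNames(list(newParams), key))
      leaves <- .treeLeaves(net@tree)
      upHead <- .adamUpdate(list(w = net@head@w, b = net@head@b),
                            list(w = dW, b = db), adamHead, iter, lr,
                            l2 = cfg$l2)
      adamHead <- upHead$s
      net@head@w <- upHead$p$w; net@head@b <- upHead$p$b

      history <- rbind(history, data.frame(
        iteration = iter, epoch = epoch, train_loss = loss, lr = lr))

      if (length(valSamples) && iter %% cfg$validationEvery == 0L) {
        probsV <- forwardWithHead(net, va$x)
        valLoss <- crossEntropyRisk(probsV, t(va$y))
        valHistory <- rbind(valHistory,
                            data.frame(iteration = iter, val_loss = valLoss))
        monitor <- patienceStep(monitor, valLoss)
        if (monitor$stop) stop.now <- TRUE
        if (verbose)
          message(sprintf("iter %d: val %.4f (bad %d)", iter, valLoss,
                          monitor$bad))
      }
      if (!is.null(cfg$maxIterations) && iter >= cfg$maxIterations)
        stop.now <- TRUE
      if (stop.now) break
    }
    if (stop.now) break
  }
  net@trained <- TRUE
  list(net = net, history = history, valHistory = valHistory)
}

#' Build and train a GraMNet through its five stages
#'
#' Executes the staged growth A, A+B, A+B||C, A+B||C+D, (A+B||C+D)||E:
#' B and D attach in series (consuming the frozen network's final
#' feature maps), C and E in parallel (reading the raw input). After
#' each stage the whole network is frozen before the next SubNet is
#' added, so each stage trains only the newest SubNet and a fresh head.
#' Pooling flags of each preset are adapted to the spatial size the
#' SubNet actually sees.
#'
#' @param trainData,valData manifests or lists of
#'   [PhantomSample-class].
#' @param presets SubNet preset names for the five stages.
#' @param cfg a [stageTrainConfig()].
#' @param classes class labels (head order).
#' @param inputSize integer c(H, W) of the images.
#' @param inChannels raw input channel count.
#' @param seed RNG seed.
#' @param verbose print stage progress.
#' @return list with `net` (final trained graph), `stages` (per-stage
#'   list: name, valAccuracy, trainableParameters, totalParameters,
#'   history), and `stageNames`.
#' @export
buildAndTrainGramnet <- function(trainData, valData = NULL,
                                 presets = c("A", "B", "C", "D", "E"),
                                 cfg = stageTrainConfig(),
                                 classes = c("benign", "malignant"),
                                 inputSize = c(32L, 32L), inChannels = 1L,
                                 seed = 1L, verbose = FALSE) {
  stopifnot(length(presets) == 5L)
  inputSize <- as.integer(inputSize)
  arrangement <- c("series", "series", "parallel", "series", "parallel")
  stageNames <- c("A", "A+B", "A+B||C", "A+B||C+D", "(A+B||C+D)||E")
  valSamples <- if (!is.null(valData)) .loadSplit(valData, "val") else NULL

  net <- NULL
  stages <- vector("list", 5L)
  for (k in 1:5) {
    if (k == 1L) {
      spec <- adaptSpecToInput(subnetPreset(presets[k]), inputSize)
      mod <- buildSubNet(spec, inChannels, seed = .deriveSeed(seed, k))
      net <- gramnetFromSubnet(mod, classes, inputSize,
                               seed = .deriveSeed(seed, k))
    } else if (arrangement[k] == "series") {
      sh <- .treeOutShape(net@tree, inputSize, inChannels)
      spec <- adaptSpecToInput(subnetPreset(presets[k]), sh[1:2])
      mod <- buildSubNet(spec, sh[3], seed = .deriveSeed(seed, k))
      net <- combineSeries(net, mod, inputSize, seed = .deriveSeed(seed, k))
    } else {
      spec <- adaptSpecToInput(subnetPreset(presets[k]), inputSize)
      mod <- buildSubNet(spec, inChannels, seed = .deriveSeed(seed, k))
      net <- combineParallel(net, mod, inputSize, seed = .deriveSeed(seed, k))
    }
    if (verbose) message("training stage ", stageNames[k])
    r <- trainStage(net, trainData, valData, cfg,
                    seed = .deriveSeed(seed, 100L + k), verbose = verbose)
    net <- r$net
    valAcc <- NA_real_
    if (!is.null(valSamples) && length(valSamples)) {
      pv <- predictClass(net, .stackClassif(valSamples, classes)$x)
      valAcc <- mean(pv$labels ==
                       vapply(valSamples, function(s) s@label, character(1)))
    }
    stages[[k]] <- list(name = stageNames[k], valAccuracy = valAcc,
                        trainableParameters = countTrainableParameters(net),
                        totalParameters = countParameters(net),
                        history = r$history, valHistory = r$valHistory)
  }
  list(net = net, stages = stages, stageNames = stageNames)
}

#' Predict class labels and positive-class scores
#'
#' Labels are the argmax of the softmax probabilities (ties break toward
#' the lower class index); scores are the probability of
#' `positiveClass`.
#'
#' @param net a [GraMNetGraph-class].
#' @param images (H, W, C, N) tensor, single image or list of
#'   [PhantomSample-class].
#' @param positiveClass class whose probability is reported as the score.
#' @return list with `labels` (character), `scores` (numeric) and
#'   `probs` (N x M matrix).
#' @export
predictClass <- function(net, images, positiveClass = "malignant") {
  if (!net@trained)
    warning("predicting with an untrained GraMNet")
  if (is.list(images) && !is.array(images))
    images <- .stackClassif(images, net@classes)$x
  probs <- forwardWithHead(net, images)
  labels <- net@classes[apply(probs, 1L, which.max)]
  scores <- if (positiveClass %in% net@classes) probs[, positiveClass]
            else probs[, ncol(probs)]
  list(labels = labels, scores = as.numeric(scores), probs = probs)
}
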