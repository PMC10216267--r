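#' Configuration of the En-DeNet encoder-decoder segmentation model
#'
#' The encoder is a pluggable 5-stage (by default) convolutional pyramid;
#' each stage is two 3x3 conv + batch-norm + ReLU layers followed by 2x2
#' max pooling, and the pre-pool feature map feeds the matching decoder
#' block through a skip connection. The decoder mirrors it with 5 blocks
#' of two 3x3 convolutions at channel counts (256, 128, 64, 32, 16),
#' nearest-neighbor upsampling and skip concatenation; a final 1x1
#' convolution with sigmoid gives the per-pixel foreground probability.
#'
#' @param encoder "tiny5" (8, 16, 32, 64, 64 channels) or
#'   "effnet-b3-style" (24, 32, 48, 96, 136; same interface, wider
#'   channel progression, no pretrained weights).
#' @param encoderDepth number of stages; each halves the resolution.
#' @param decoderChannels strictly decreasing, one per decoder block.
#' @param inChannels 1 or 2 image channels.
#' @param encoderChannels optional explicit per-stage channel counts
#'   (overrides the named preset).
#' @return a [SegModelConfig-class].
#' @export
segModelConfig <- function(encoder = "tiny5", encoderDepth = 5L,
                           decoderChannels = c(256L, 128L, 64L, 32L, 16L),
                           inChannels = 1L, encoderChannels = NULL) {
  if (is.null(encoderChannels))
    encoderChannels <- switch(encoder,
      "tiny5" = c(8L, 16L, 32L, 64L, 64L),
      "effnet-b3-style" = c(24L, 32L, 48L, 96L, 136L),
      stop("unknown encoder preset: ", encoder))[seq_len(encoderDepth)]
  obj <- new("SegModelConfig", encoder = encoder,
             encoderDepth = as.integer(encoderDepth),
             encoderChannels = as.integer(encoderChannels),
             decoderChannels = as.integer(decoderChannels),
             inChannels = as.integer(inChannels))
  validObject(obj)
  obj
}

#' A reduced configuration for desk-scale experiments
#'
#' Same topology as the default, with narrow channel counts so the whole
#' train-and-evaluate cycle runs in minutes on one CPU core.
#'
#' @param inChannels 1 or 2.
#' @return a [SegModelConfig-class].
#' @export
tinySegConfig <- function(inChannels = 1L)
  segModelConfig(encoder = "tiny5", encoderDepth = 5L,
                 encoderChannels = c(4L, 8L, 16L, 32L, 64L),
                 decoderChannels = c(64L, 32L, 16L, 8L, 4L),
                 inChannels = inChannels)

.convBnInit <- function(kh, kw, cin, cout)
  list(w = .heConv(kh, kw, cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rmean = numeric(cout), rvar = rep(1, cout))

#' Build (initialize) an En-DeNet segmentation model
#'
#' @param cfg a [SegModelConfig-class] from [segModelConfig()].
#' @param seed initialization seed (deterministic build).
#' @return a [SegModel-class] mapping (H, W, inChannels) inputs to
#'   (H, W) probability maps in (0, 1); H and W must be divisible by
#'   2^encoderDepth (checked at forward time).
#' @export
buildEnDeNet <- function(cfg = segModelConfig(), seed = 1L) {
  validObject(cfg)
  set.seed(.deriveSeed(seed, 17L))
  depth <- cfg@encoderDepth
  ec <- cfg@encoderChannels; dc <- cfg@decoderChannels
  enc <- vector("list", depth)
  cin <- cfg@inChannels
  for (i in seq_len(depth)) {
    enc[[i]] <- list(conv1 = .convBnInit(3, 3, cin, ec[i]),
                     conv2 = .convBnInit(3, 3, ec[i], ec[i]))
    cin <- ec[i]
  }
  dec <- vector("list", depth)
  prev <- ec[depth]                       # bottleneck channels
  for (j in seq_len(depth)) {
    skip <- ec[depth + 1L - j]
    dec[[j]] <- list(conv1 = .convBnInit(3, 3, prev + skip, dc[j]),
                     conv2 = .convBnInit(3, 3, dc[j], dc[j]))
    prev <- dc[j]
  }
  final <- list(w = .heConv(1, 1, dc[depth], 1), b = numeric(1))
  new("SegModel", config = cfg,
      params = list(enc = enc, dec = dec, final = final))
}

## conv + BN + ReLU block forward/backward over a params list.
.cbrFw <- function(p, x, train, grad) {
  y <- .convFw(x, p$w, p$b)
  bn <- .bnFw(y, p, train)
  r <- .reluFw(bn$y)
  list(y = r$y,
       cache = if (grad) list(x = x, bn = bn$cache, mask = r$mask) else NULL,
       params = if (train) bn$params else p)
}

.cbrBw <- function(p, cache, dy) {
  dy <- dy * cache$mask
  bb <- .bnBw(p, cache$bn, dy)
  cb <- .convBw(cache$x, p$w, bb$dx)
  list(dx = cb$dx,
       grads = list(w = cb$dw, b = cb$db, gamma = bb$dgamma, beta = bb$dbeta,
                    rmean = p$rmean * 0, rvar = p$rvar * 0))
}

## Full forward. Returns probs, logits and (optionally) caches.
.segFw <- function(model, x, train = FALSE, grad = FALSE) {
  cfg <- model@config
  d <- dim(x)
  if (d[1] %% 2^cfg@encoderDepth != 0 || d[2] %% 2^cfg@encoderDepth != 0)
    stop("input spatial size must be divisible by 2^", cfg@encoderDepth)
  if (d[3] != cfg@inChannels)
    stop("input has ", d[3], " channels; model expects ", cfg@inChannels)
  p <- model@params
  depth <- cfg@encoderDepth
  skips <- vector("list", depth)
  encCache <- vector("list", depth)
  for (i in seq_len(depth)) {
    c1 <- .cbrFw(p$enc[[i]]$conv1, x, train, grad)
    p$enc[[i]]$conv1 <- c1$params
    c2 <- .cbrFw(p$enc[[i]]$conv2, c1$y, train, grad)
    p$enc[[i]]$conv2 <- c2$params
    skips[[i]] <- c2$y
    mp <- .poolFw(c2$y)
    x <- mp$y
    encCache[[i]] <- if (grad)
      list(c1 = c1$cache, c2 = c2$cache, idx = mp$idx, predim = dim(c2$y))
  }
  decCache <- vector("list", depth)
  for (j in seq_len(depth)) {
    up <- .upsample2Fw(x)
    skip <- skips[[depth + 1L - j]]
    du <- dim(up); ds <- dim(skip)
    z <- array(0, c(du[1], du[2], du[3] + ds[3], du[4]))
    z[, , seq_len(du[3]), ] <- up
    z[, , du[3] + seq_len(ds[3]), ] <- skip
    c1 <- .cbrFw(p$dec[[j]]$conv1, z, train, grad)
    p$dec[[j]]$conv1 <- c1$params
    c2 <- .cbrFw(p$dec[[j]]$conv2, c1$y, train, grad)
    p$dec[[j]]$conv2 <- c2$params
    x <- c2$y
    decCache[[j]] <- if (grad)
      list(c1 = c1$cache, c2 = c2$cache, upch = du[3], skch = ds[3])
  }
  logits <- .convFw(x, p$final$w, p$final$b)
  probs <- .sigmoid(logits)
  list(probs = probs, logits = logits, params = p,
       cache = if (grad) list(enc = encCache, dec = decCache, preFinal = x))
}

## Backward from dLoss/dlogits; returns grads mirroring model@params.
.segBw <- function(model, cache, dlogits) {
  p <- model@params
  depth <- model@config@encoderDepth
  fb <- .convBw(cache$preFinal, p$final$w, dlogits)
  grads <- list(enc = vector("list", depth), dec = vector("list", depth),
                final = list(w = fb$dw, b = fb$db))
  dy <- fb$dx
  dskips <- vector("list", depth)
  for (j in rev(seq_len(depth))) {
    cc <- cache$dec[[j]]
    b2 <- .cbrBw(p$dec[[j]]$conv2, cc$c2, dy)
    b1 <- .cbrBw(p$dec[[j]]$conv1, cc$c1, b2$dx)
    grads$dec[[j]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    dz <- b1$dx
    dup <- dz[, , seq_len(cc$upch), , drop = FALSE]
    dskips[[depth + 1L - j]] <- dz[, , cc$upch + seq_len(cc$skch), , drop = FALSE]
    dy <- .upsample2Bw(dup)
  }
  for (i in rev(seq_len(depth))) {
    cc <- cache$enc[[i]]
    d <- cc$predim
    dpre <- .cpp_maxpool_bw(dy, cc$idx, d[1], d[2], d[3], d[4]) +
      dskips[[i]]
    b2 <- .cbrBw(p$enc[[i]]$conv2, cc$c2, dpre)
    b1 <- .cbrBw(p$enc[[i]]$conv1, cc$c1, b2$dx)
    grads$enc[[i]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    dy <- b1$dx
  }
  grads
}

#' Training protocol configuration for En-DeNet
#'
#' Adam with learning rate 0.001 and weight decay 1e-8; a plateau
#' scheduler multiplies the rate by 0.1 when the validation loss has not
#' improved for 5 consecutive epochs; training runs for at most 200
#' epochs (earlier if the rate falls below `minLR`) in batches of 16.
#'
#' @param lr,weightDecay Adam settings.
#' @param plateauFactor,plateauPatience plateau scheduler settings.
#' @param maxEpochs,batchSize loop settings.
#' @param minLR stop when the scheduled rate falls below this.
#' @return a list of class "SegTrainConfig".
#' @export
segTrainConfig <- function(lr = 0.001, weightDecay = 1e-8,
                           plateauFactor = 0.1, plateauPatience = 5L,
                           maxEpochs = 200L, batchSize = 16L, minLR = 1e-6) {
  stopifnot(lr > 0, weightDecay >= 0, plateauFactor > 0, plateauFactor < 1,
            plateauPatience >= 1, maxEpochs >= 1, batchSize >= 1)
  structure(list(lr = lr, weightDecay = weightDecay,
                 plateauFactor = plateauFactor,
                 plateauPatience = as.integer(plateauPatience),
                 maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), minLR = minLR),
            class = "SegTrainConfig")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' `plateauScheduler` creates the state; `plateauStep` feeds one
#' validation loss and returns the updated state. When the loss has not
#' improved on its running minimum for `patience` consecutive steps the
#' rate is multiplied by `factor` and the counter resets.
#'
#' @param initialLR starting learning rate.
#' @param factor multiplicative drop (default 0.1).
#' @param patience consecutive non-improving checks before a drop.
#' @param minLR floor; `state$exhausted` is TRUE once lr < minLR.
#' @return a scheduler state list with elements `lr`, `best`, `wait`,
#'   `exhausted`.
#' @export
plateauScheduler <- function(initialLR, factor = 0.1, patience = 5L,
                             minLR = 1e-6) {
  list(lr = initialLR, factor = factor, patience = as.integer(patience),
       minLR = minLR, best = Inf, wait = 0L, exhausted = FALSE)
}

#' @rdname plateauScheduler
#' @param state a scheduler state.
#' @param valLoss the validation loss observed at this check.
#' @export
plateauStep <- function(state, valLoss) {
  if (valLoss < state$best - 1e-12) {
    state$best <- valLoss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  if (state$lr < state$minLR) state$exhausted <- TRUE
  state
}

#' Learning rate under the drop-at-half-the-epochs schedule
#'
#' The staged classification protocol decreases the rate by a factor of
#' 0.1 once half of the scheduled epochs are completed: from epoch
#' `ceiling(epochs / 2)` on, the rate is `factor * initialLR`.
#'
#' @param epoch current epoch (1-based).
#' @param epochs total scheduled epochs.
#' @param initialLR starting rate.
#' @param factor drop factor (default 0.1).
#' @return the rate for `epoch`.
#' @export
halfEpochLR <- function(epoch, epochs, initialLR, factor = 0.1)
  if (epoch >= ceiling(epochs / 2)) initialLR * factor else initialLR

## Stack a list of PhantomSample into (x, y) tensors; target selects the
## mask being segmented.
.stackSamples <- function(samples, target = c("liver", "tumor")) {
  target <- match.arg(target)
  d <- dim(samples[[1]]@image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]@image
    y[, , 1L, i] <- if (target == "liver") samples[[i]]@liverMask
                    else samples[[i]]@tumorMask
  }
  list(x = x, y = y)
}

.loadSplit <- function(data, split) {
  if (is(data, "DatasetManifest")) {
    idx <- which(data@records$split == split)
    lapply(idx, function(i) readPhantomRecord(data, i))
  } else data
}

#' Train the En-DeNet segmentation model
#'
#' Minimizes the combined BCE + alpha * (1 - Dice) loss with Adam,
#' plateau learning-rate scheduling and per-epoch validation. Training
#' stops at `maxEpochs` or when the scheduler exhausts (rate below
#' `minLR`). Deterministic for a fixed seed.
#'
#' @param model a [SegModel-class] from [buildEnDeNet()].
#' @param trainData,valData a [DatasetManifest-class] (records with the
#'   matching split tag are read from disk) or a list of
#'   [PhantomSample-class].
#' @param lossCfg a [lossConfig()].
#' @param trainCfg a [segTrainConfig()].
#' @param target segment the "liver" (default) or "tumor" mask.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (data.frame of
#'   epoch, train_loss, val_loss, lr).
#' @export
trainSegmentation <- function(model, trainData, valData = NULL,
                              lossCfg = lossConfig(),
                              trainCfg = segTrainConfig(),
                              target = "liver", seed = 1L, verbose = FALSE) {
  trainSamples <- .loadSplit(trainData, "train")
  if (length(trainSamples) == 0L) stop("empty training manifest")
  valSamples <- if (!is.null(valData)) .loadSplit(valData, "val") else list()
  tr <- .stackSamples(trainSamples, target)
  va <- if (length(valSamples)) .stackSamples(valSamples, target)
  n <- dim(tr$x)[4]
  state <- .adamInit(model@params)
  sched <- plateauScheduler(trainCfg$lr, trainCfg$plateauFactor,
                            trainCfg$plateauPatience, trainCfg$minLR)
  history <- data.frame()
  set.seed(.deriveSeed(seed, 23L))
  t <- 0L
  for (epoch in seq_len(trainCfg$maxEpochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / trainCfg$batchSize))
    epochLoss <- 0
    for (b in batches) {
      xb <- tr$x[, , , b, drop = FALSE]
      yb <- tr$y[, , , b, drop = FALSE]
      fw <- .segFw(model, xb, train = TRUE, grad = TRUE)
      model@params <- fw$params
      lg <- .combinedLossGrad(fw$probs, yb, lossCfg)
      epochLoss <- epochLoss + lg$loss * length(b)
      grads <- .segBw(model, fw$cache, lg$dlogits)
      t <- t + 1L
      up <- .adamUpdate(model@params, grads, state, t, sched$lr,
                        l2 = trainCfg$weightDecay)
      model@params <- up$p; state <- up$s
    }
    trainLoss <- epochLoss / n
    valLoss <- NA_real_
    if (length(valSamples)) {
      fv <- .segFw(model, va$x, train = FALSE, grad = FALSE)
      valLoss <- combinedLoss(fv$probs, va$y, lossCfg)
      sched <- plateauStep(sched, valLoss)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = trainLoss, val_loss = valLoss,
      lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %g", epoch,
                      trainLoss, valLoss, sched$lr))
    if (sched$exhausted) break
  }
  list(model = model, history = history)
}

#' Predict probability maps for a batch of images
#'
#' @param model a trained [SegModel-class].
#' @param images (H, W, C, N) tensor, single image, or list of
#'   [PhantomSample-class].
#' @return (H, W, N) array of per-pixel foreground probabilities.
#' @export
predictSegmentation <- function(model, images) {
  if (is.list(images) && !is.array(images))
    images <- .stackSamples(images)$x
  x <- .asTensor(images, model@config@inChannels)
  fw <- .segFw(model, x, train = FALSE, grad = FALSE)
  array(fw$probs, dim(fw$probs)[c(1, 2, 4)])
}

#' Binarize a probability map at a threshold
#'
#' Pixels with value >= threshold (ties map to foreground) become 1.
#'
#' @param probMap numeric matrix/array with values in [0, 1].
#' @param threshold default 0.5.
#' @return binary array of the same shape.
#' @export
binarize <- function(probMap, threshold = 0.5) {
  (probMap >= threshold) * 1
}

#' Remove small connected components ("fragments") from a binary mask
#'
#' Components are 8-connected; a component is removed when its area is
#' strictly less than `minArea` pixels (a component of exactly `minArea`
#' pixels is retained). The default of 1024 px is defined at the native
#' 512x512 scale; when working on images resized by 0.25 the area scales
#' by the square of the factor (1024 / 16 = 64).
#'
#' @param mask binary matrix.
#' @param minArea minimum component area to keep (default 1024).
#' @return the cleaned binary matrix.
#' @export
clearFragments <- function(mask, minArea = 1024L) {
  stopifnot(all(mask %in% c(0, 1)))
  lab <- .cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  if (max(lab) == 0L) return(mask * 0)
  areas <- tabulate(lab)
  keep <- which(areas >= minArea)
  matrix(as.numeric(lab %in% keep), nrow(mask), ncol(mask))
}

#' Pixel-wise union of several predicted masks (mask ensemble)
#'
#' @param masks list of binary matrices of identical shape.
#' @return binary matrix, the logical OR of all masks.
#' @export
unionEnsemble <- function(masks) mergeMasks(masks)

#' Save / load an En-DeNet model directory
#'
#' The configuration is written as YAML, the parameters as an RDS blob.
#'
#' @param model a [SegModel-class].
#' @param dir output directory (created if needed).
#' @return `saveSegModel` returns `dir` invisibly; `loadSegModel` the
#'   model.
#' @export
saveSegModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model@config
  yaml::write_yaml(list(encoder = cfg@encoder,
                        encoderDepth = cfg@encoderDepth,
                        encoderChannels = as.list(cfg@encoderChannels),
                        decoderChannels = as.list(cfg@decoderChannels),
                        inChannels = cfg@inChannels),
                   file.path(dir, "seg-config.yaml"))
  saveRDS(model@params, file.path(dir, "seg-params.rds"))
  invisible(dir)
}

#' @rdname saveSegModel
#' @export
loadSegModel <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "seg-config.yaml"))
  cfg <- segModelConfig(encoder = meta$encoder,
                        encoderDepth = meta$encoderDepth,
                        decoderChannels = unlist(meta$decoderChannels),
                        inChannels = meta$inChannels,
                        encoderChannels = unlist(meta$encoderChannels))
  new("SegModel", config = cfg,
      params = readRDS(file.path(dir, "seg-params.rds")))
}

setMethod("show", "SegModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SegModel (En-DeNet): encoder '%s' depth %d (%s), decoder (%s), %d-channel input\n",
    cfg@encoder, cfg@encoderDepth,
    paste(cfg@encoderChannels, collapse = ", "),
    paste(cfg@decoderChannels, collapse = ", "), cfg@inChannels))
  cat("  parameters:", format(countParameters(object), big.mark = ","), "\n")
})

#' @describeIn countParameters an En-DeNet segmentation model.
#' @export
setMethod("countParameters", "SegModel", function(object, ...) {
  cnt <- function(p) length(p$w) + length(p$b) +
    if (!is.null(p$gamma)) length(p$gamma) + length(p$beta) else 0L
  s <- 0
  for (st in object@params$enc) s <- s + cnt(st$conv1) + cnt(st$conv2)
  for (st in object@params$dec) s <- s + cnt(st$conv1) + cnt(st$conv2)
  s + cnt(object@params$final)
})
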