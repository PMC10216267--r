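## Central S4 data objects. Tensors throughout the package are plain R
## arrays with dim (H, W, C, N); single images are H x W matrices or
## H x W x C arrays; masks are 0/1 matrices.

#' Configuration for the synthetic CT-like phantom generator
#'
#' A phantom is a 2-D grayscale slice containing an elliptical "liver"
#' region on a darker background, with zero or more disk-shaped "tumors"
#' whose intensity is offset from the surrounding parenchyma: a negative
#' contrast gives hypodense (darker) tumors, a positive one hyperdense
#' (brighter) tumors. All geometry is sampled deterministically from the
#' config seed and the sample index.
#'
#' @slot imageSize integer, pixels per side (square images).
#' @slot liverAxes numeric length 2, range of ellipse semi-axes as a
#'   fraction of the image side.
#' @slot nTumors integer length 2, inclusive range of tumor counts.
#' @slot tumorRadius numeric length 2, tumor radius range in pixels.
#' @slot tumorContrast numeric length 2, signed intensity offset range;
#'   negative = hypodense, positive = hyperdense.
#' @slot noiseSD numeric, standard deviation of additive Gaussian noise
#'   (images are clipped back to [0, 1]).
#' @slot channels integer, 1 or 2; the second channel is a smoothed,
#'   contrast-stretched copy standing in for a perfusion map.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig", representation(
  imageSize = "integer", liverAxes = "numeric", nTumors = "integer",
  tumorRadius = "numeric", tumorContrast = "numeric", noiseSD = "numeric",
  channels = "integer", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
  if (length(object@liverAxes) != 2L || any(object@liverAxes <= 0) ||
      any(object@liverAxes >= 0.5))
    msg <- c(msg, "liverAxes must be two fractions in (0, 0.5)")
  if (length(object@nTumors) != 2L || any(object@nTumors < 0L) ||
      object@nTumors[1] > object@nTumors[2])
    msg <- c(msg, "nTumors must be a non-negative increasing range")
  if (max(object@tumorRadius) >= min(object@liverAxes) * object@imageSize)
    msg <- c(msg, "tumor radii must be smaller than the smallest liver semi-axis")
  if (min(abs(object@tumorContrast)) <= 2 * object@noiseSD)
    msg <- c(msg, "|tumorContrast| must exceed 2 * noiseSD (separability)")
  if (diff(sign(object@tumorContrast)) != 0)
    msg <- c(msg, "tumorContrast range must not straddle zero")
  if (!object@channels %in% c(1L, 2L)) msg <- c(msg, "channels must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' A single synthetic phantom sample
#'
#' @slot image H x W matrix or H x W x 2 array of intensities in [0, 1].
#' @slot liverMask,tumorMask H x W binary (0/1) matrices; the tumor mask
#'   is always nested inside the liver mask.
#' @slot label "benign" or "malignant"; by convention malignant iff the
#'   tumor mask is nonempty.
#' @export
setClass("PhantomSample", representation(
  image = "array", liverMask = "matrix", tumorMask = "matrix",
  label = "character"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (!all(dim(object@liverMask) == d[1:2]) ||
      !all(dim(object@tumorMask) == d[1:2]))
    msg <- c(msg, "mask dimensions must match the image")
  if (min(object@image) < 0 || max(object@image) > 1)
    msg <- c(msg, "intensities must lie in [0, 1]")
  if (!all(object@liverMask %in% c(0, 1)) || !all(object@tumorMask %in% c(0, 1)))
    msg <- c(msg, "masks must be binary")
  if (any(object@tumorMask > object@liverMask))
    msg <- c(msg, "tumorMask must be nested inside liverMask")
  if (!object@label %in% c("benign", "malignant"))
    msg <- c(msg, "label must be 'benign' or 'malignant'")
  if (length(msg)) msg else TRUE
})

#' Tabular index of a dataset on disk
#'
#' Wraps a data.frame with columns id, image_path, liver_mask_path,
#' tumor_mask_path, label, split; every pipeline stage consumes records
#' through a manifest rather than raw directory listings.
#'
#' @slot records the records data.frame.
#' @slot provenance free-text note on where the records came from.
#' @export
setClass("DatasetManifest", representation(
  records = "data.frame", provenance = "character"))

.manifestCols <- c("id", "image_path", "liver_mask_path",
                   "tumor_mask_path", "label", "split")

setValidity("DatasetManifest", function(object) {
  msg <- character()
  if (!all(.manifestCols %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:",
                        paste(.manifestCols, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$id)) msg <- c(msg, "record ids must be unique")
    if (!all(object@records$split %in% c("train", "val", "test", "unassigned")))
      msg <- c(msg, "split tags must be train/val/test/unassigned")
  }
  if (length(msg)) msg else TRUE
})

#' Architecture of a SubNet: an ordered stack of conv layer groups
#'
#' Each layer group is convolution -> (batch norm) -> ReLU -> (2x2 max
#' pool). Kernels may be asymmetric (e.g. 1x3 / 3x1).
#'
#' @slot layerGroups list of numeric length-3 vectors
#'   (kernel_h, kernel_w, n_filters).
#' @slot useBatchnorm logical flag (one per stack).
#' @slot useMaxpool logical vector, one flag per layer group.
#' @export
setClass("SubNetSpec", representation(
  layerGroups = "list", useBatchnorm = "logical", useMaxpool = "logical"))

setValidity("SubNetSpec", function(object) {
  msg <- character()
  if (length(object@layerGroups) < 1L) msg <- c(msg, "need at least one layer group")
  for (g in object@layerGroups)
    if (length(g) != 3L || any(g < 1))
      msg <- c(msg, "each layer group is (kernel_h, kernel_w, n_filters), all >= 1")
  if (length(object@useMaxpool) != length(object@layerGroups))
    msg <- c(msg, "useMaxpool needs one flag per layer group")
  if (length(msg)) unique(msg) else TRUE
})

#' A built SubNet: spec plus parameters plus frozen flag
#'
#' @slot spec the [SubNetSpec-class].
#' @slot inChannels integer, input channel count the module was built for.
#' @slot params list of per-group parameter lists (conv weights `w`
#'   (kh, kw, cin, cout), biases `b`, and when batch norm is on `gamma`,
#'   `beta`, `rmean`, `rvar`).
#' @slot frozen logical; frozen modules are evaluated in inference mode
#'   and their parameters (batch-norm statistics included) never change.
#' @export
setClass("SubNetModule", representation(
  spec = "SubNetSpec", inChannels = "integer", params = "list",
  frozen = "logical"))

#' Fully connected classification head over globally pooled features
#'
#' @slot w M x F weight matrix, @slot b length-M bias, @slot nClasses M.
#' @export
setClass("ClassificationHead", representation(
  w = "matrix", b = "numeric", nClasses = "integer"))

setValidity("ClassificationHead", function(object) {
  if (nrow(object@w) != object@nClasses || length(object@b) != object@nClasses)
    "head output dimension must equal nClasses" else TRUE
})

#' A GraMNet: a composition tree of SubNets plus one classification head
#'
#' The tree is a nested list. A leaf is `list(op = "leaf", module =
#' <SubNetModule>)`; internal nodes are `list(op = "series", first, second)`
#' (second consumes first's feature maps) or `list(op = "parallel", first,
#' second)` (both consume the tree input; final feature maps are spatially
#' aligned by adaptive average pooling to the smaller map and concatenated
#' along depth). The head global-average-pools the final feature map and
#' applies one fully connected layer followed by softmax.
#'
#' @slot tree the composition tree.
#' @slot head a [ClassificationHead-class].
#' @slot classes character vector of class names (head order).
#' @slot inChannels integer, raw input channel count.
#' @export
setClass("GraMNetGraph", representation(
  tree = "list", head = "ClassificationHead", classes = "character",
  inChannels = "integer", trained = "logical"),
  prototype(trained = FALSE))

setValidity("GraMNetGraph", function(object) {
  if (length(object@classes) != object@head@nClasses)
    return("classes must match the head dimension")
  ok <- TRUE
  walk <- function(node) {
    if (!is.list(node) || is.null(node$op)) ok <<- FALSE
    else if (node$op == "leaf") {
      if (!is(node$module, "SubNetModule")) ok <<- FALSE
    } else if (node$op %in% c("series", "parallel")) {
      walk(node$first); walk(node$second)
    } else ok <<- FALSE
  }
  walk(object@tree)
  if (!ok) "malformed composition tree" else TRUE
})

#' Configuration of the encoder-decoder segmentation network
#'
#' @slot encoder "tiny5" (plain conv encoder) or "effnet-b3-style"
#'   (wider channel progression; no pretrained weights).
#' @slot encoderDepth integer number of encoder stages (each halves the
#'   spatial resolution).
#' @slot encoderChannels integer vector of per-stage channel counts.
#' @slot decoderChannels integer vector, one per decoder block,
#'   strictly decreasing; default (256, 128, 64, 32, 16).
#' @slot inChannels 1 or 2 input channels.
#' @export
setClass("SegModelConfig", representation(
  encoder = "character", encoderDepth = "integer",
  encoderChannels = "integer", decoderChannels = "integer",
  inChannels = "integer"))

setValidity("SegModelConfig", function(object) {
  msg <- character()
  if (length(object@decoderChannels) != object@encoderDepth)
    msg <- c(msg, "decoderChannels length must equal encoderDepth")
  if (any(diff(object@decoderChannels) >= 0))
    msg <- c(msg, "decoderChannels must be strictly decreasing")
  if (length(object@encoderChannels) != object@encoderDepth)
    msg <- c(msg, "encoderChannels length must equal encoderDepth")
  if (!object@inChannels %in% c(1L, 2L)) msg <- c(msg, "inChannels must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' The En-DeNet segmentation model (U-Net style encoder-decoder)
#'
#' @slot config a [SegModelConfig-class].
#' @slot params nested parameter list (encoder stages, decoder blocks,
#'   final 1x1 convolution); sigmoid output.
#' @export
setClass("SegModel", representation(config = "SegModelConfig", params = "list"))

#' Pixel- or image-level confusion counts
#' @slot tp,tn,fp,fn non-negative counts.
#' @export
setClass("ConfusionCounts", representation(
  tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0) || any(v != round(v))) "counts must be non-negative integers" else TRUE
})

#' Bundle of evaluation metrics
#'
#' Jaccard similarity (jsi), Dice (dc), accuracy, precision, recall,
#' specificity, F1 and AUC; a metric whose denominator is degenerate
#' (0/0) is reported as NA rather than 0 or 1 so that means over
#' records are not biased.
#' @slot jsi,dc,acc,pre,rec,spe,f1,auc numeric scalars in [0,1] or NA.
#' @export
setClass("MetricRecord", representation(
  jsi = "numeric", dc = "numeric", acc = "numeric", pre = "numeric",
  rec = "numeric", spe = "numeric", f1 = "numeric", auc = "numeric"))
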