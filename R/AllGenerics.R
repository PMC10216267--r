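#' Count learnable parameters
#'
#' Sums every learnable scalar: convolution weights and biases,
#' batch-norm scale/shift (running statistics are not learnable), and
#' fully connected head weights and biases.
#'
#' @param object a [SubNetModule-class], [GraMNetGraph-class],
#'   [SegModel-class], [ClassificationHead-class], or a list of these.
#' @param ... unused.
#' @return integer scalar.
#' @examples
#' sp <- SubNetSpec(list(c(3, 3, 8)), useBatchnorm = FALSE)
#' countParameters(buildSubNet(sp, inChannels = 1, seed = 1))  # 3*3*1*8 + 8
#' @export
setGeneric("countParameters", function(object, ...) standardGeneric("countParameters"))

#' Count multiply-add operations of a forward pass
#'
#' Convolutions contribute H_out * W_out * kh * kw * C_in * C_out and the
#' fully connected head contributes in * out; activation, pooling and
#' normalization layers are not counted (the usual MAdd convention).
#'
#' @param object a built module, graph or model.
#' @param inputShape integer c(H, W) spatial size of the input.
#' @param ... unused.
#' @return numeric scalar (counts can exceed .Machine$integer.max).
#' @export
setGeneric("countMAdd", function(object, inputShape, ...) standardGeneric("countMAdd"))

#' Freeze all parameters of a module or graph
#'
#' Frozen modules run in inference mode (batch-norm uses its stored
#' statistics) and are never touched by any subsequent training step.
#'
#' @param object a [SubNetModule-class] or [GraMNetGraph-class].
#' @return the object with every SubNet marked frozen.
#' @export
setGeneric("freezeParameters", function(object) standardGeneric("freezeParameters"))

#' @describeIn countParameters a list of modules (an empty list counts 0).
#' @export
setMethod("countParameters", "list", function(object, ...)
  if (length(object) == 0L) 0L else sum(vapply(object, countParameters, numeric(1))))
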