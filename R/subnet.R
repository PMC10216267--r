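#' Create a SubNet architecture spec
#'
#' @param layerGroups list of length-3 numeric vectors
#'   `c(kernel_h, kernel_w, n_filters)`, one per conv layer group.
#' @param useBatchnorm add a batch-norm layer after each convolution
#'   (default TRUE).
#' @param useMaxpool logical, recycled to one flag per group: apply 2x2
#'   max pooling at the end of the group (default TRUE).
#' @return a [SubNetSpec-class].
#' @examples
#' SubNetSpec(list(c(3, 3, 8), c(3, 3, 16), c(3, 3, 32)))
#' @export
SubNetSpec <- function(layerGroups, useBatchnorm = TRUE, useMaxpool = TRUE) {
  new("SubNetSpec",
      layerGroups = lapply(layerGroups, function(g) as.numeric(g)),
      useBatchnorm = isTRUE(useBatchnorm),
      useMaxpool = rep_len(as.logical(useMaxpool), length(layerGroups)))
}

#' Named SubNet presets "A" to "E"
#'
#' The five small SubNets used by the staged GraMNet build: A and C are
#' three 3x3 (resp. 1x1) groups with 8/16/32 filters, B and D three 3x3
#' groups with 64/128/256 filters, and E uses asymmetric 1x3 / 3x1 / 1x3
#' kernels with 64/128/256 filters.
#'
#' @param name one of "A", "B", "C", "D", "E".
#' @param useBatchnorm,useMaxpool passed to [SubNetSpec()].
#' @return a [SubNetSpec-class].
#' @export
subnetPreset <- function(name, useBatchnorm = TRUE, useMaxpool = TRUE) {
  groups <- switch(toupper(name),
    A = list(c(3, 3, 8), c(3, 3, 16), c(3, 3, 32)),
    B = list(c(3, 3, 64), c(3, 3, 128), c(3, 3, 256)),
    C = list(c(1, 1, 8), c(1, 1, 16), c(1, 1, 32)),
    D = list(c(3, 3, 64), c(3, 3, 128), c(3, 3, 256)),
    E = list(c(1, 3, 64), c(3, 1, 128), c(1, 3, 256)),
    stop("unknown SubNet preset: ", name))
  SubNetSpec(groups, useBatchnorm = useBatchnorm, useMaxpool = useMaxpool)
}

#' Build (initialize) a SubNet from its spec
#'
#' Each layer group is convolution (same padding) -> optional batch norm
#' -> ReLU -> optional 2x2 max pool. Weights use He initialization from
#' the given seed, so building is deterministic.
#'
#' @param spec a [SubNetSpec-class].
#' @param inChannels input channel count.
#' @param seed integer RNG seed for initialization.
#' @return a [SubNetModule-class] (unfrozen).
#' @export
buildSubNet <- function(spec, inChannels, seed = 1L) {
  validObject(spec)
  set.seed(.deriveSeed(seed))
  cin <- as.integer(inChannels)
  params <- vector("list", length(spec@layerGroups))
  for (i in seq_along(spec@layerGroups)) {
    g <- spec@layerGroups[[i]]
    p <- list(w = .heConv(g[1], g[2], cin, g[3]), b = numeric(g[3]))
    if (spec@useBatchnorm)
      p <- c(p, list(gamma = rep(1, g[3]), beta = numeric(g[3]),
                     rmean = numeric(g[3]), rvar = rep(1, g[3])))
    params[[i]] <- p
    cin <- as.integer(g[3])
  }
  new("SubNetModule", spec = spec, inChannels = as.integer(inChannels),
      params = params, frozen = FALSE)
}

## Forward through a SubNet. Returns list(y, caches); caches is NULL-free
## only when needed for backward (grad = TRUE).
.subnetFw <- function(mod, x, train = TRUE, grad = FALSE) {
  spec <- mod@spec
  train <- train && !mod@frozen
  caches <- if (grad) vector("list", length(mod@params)) else NULL
  params <- mod@params
  for (i in seq_along(params)) {
    p <- params[[i]]
    cc <- list(x = if (grad) x else NULL)
    y <- .convFw(x, p$w, p$b)
    if (spec@useBatchnorm) {
      bn <- .bnFw(y, p, train)
      y <- bn$y
      if (train) params[[i]][c("rmean", "rvar")] <- bn$params[c("rmean", "rvar")]
      cc$bn <- if (grad) bn$cache else NULL
    }
    r <- .reluFw(y)
    y <- r$y
    cc$mask <- if (grad) r$mask else NULL
    if (spec@useMaxpool[i]) {
      cc$predim <- dim(y)
      mp <- .poolFw(y)
      y <- mp$y
      cc$idx <- if (grad) mp$idx else NULL
    }
    if (grad) caches[[i]] <- cc
    x <- y
  }
  list(y = x, caches = caches, params = params)
}

## Backward through a SubNet; returns parameter grads and dx.
.subnetBw <- function(mod, caches, dy) {
  spec <- mod@spec
  grads <- vector("list", length(mod@params))
  for (i in rev(seq_along(mod@params))) {
    p <- mod@params[[i]]; cc <- caches[[i]]
    if (spec@useMaxpool[i]) {
      d <- cc$predim
      dy <- .cpp_maxpool_bw(dy, cc$idx, d[1], d[2], d[3], d[4])
    }
    dy <- dy * cc$mask
    g <- list()
    if (spec@useBatchnorm) {
      bb <- .bnBw(p, cc$bn, dy)
      dy <- bb$dx
      g$gamma <- bb$dgamma; g$beta <- bb$dbeta
      g$rmean <- p$rmean * 0; g$rvar <- p$rvar * 0
    }
    cb <- .convBw(cc$x, p$w, dy)
    grads[[i]] <- c(list(w = cb$dw, b = cb$db), g)
    dy <- cb$dx
  }
  list(grads = grads, dx = dy)
}

## Output spatial size and channel count of a SubNet given input H, W.
.subnetOutShape <- function(spec, hw) {
  p <- sum(spec@useMaxpool)
  g <- spec@layerGroups[[length(spec@layerGroups)]]
  c(hw %/% 2^p, g[3])[c(1, 2, 3)]
}

#' Adapt a spec's pooling flags to a given input size
#'
#' Pooling halves the spatial size; flags beyond the point where a 2x2
#' window no longer fits are switched off. Used by the staged builder
#' when a SubNet is attached to an already-downsampled feature map.
#'
#' @param spec a [SubNetSpec-class].
#' @param inputSize integer c(H, W) of the feature map the SubNet will see.
#' @return the spec with feasible pooling flags.
#' @export
adaptSpecToInput <- function(spec, inputSize) {
  hw <- as.integer(inputSize)
  flags <- spec@useMaxpool
  for (i in seq_along(flags)) {
    if (flags[i]) {
      if (any(hw < 2L)) flags[i] <- FALSE else hw <- hw %/% 2L
    }
  }
  spec@useMaxpool <- flags
  spec
}

#' @describeIn countParameters a built SubNet (conv weights/biases plus
#'   batch-norm scale/shift when present).
#' @export
setMethod("countParameters", "SubNetModule", function(object, ...) {
  sum(vapply(object@params, function(p)
    length(p$w) + length(p$b) +
      if (!is.null(p$gamma)) length(p$gamma) + length(p$beta) else 0L,
    numeric(1)))
})

#' @describeIn countParameters a classification head.
#' @export
setMethod("countParameters", "ClassificationHead", function(object, ...)
  length(object@w) + length(object@b))

#' Learnable-parameter count of a conv stack given by a spec
#'
#' Closed-form count for a [SubNetSpec-class] without building it:
#' kernel_h * kernel_w * c_in * n_filters weights + n_filters biases per
#' group (+ 2 * n_filters batch-norm scalars when `useBatchnorm`).
#'
#' @param spec a [SubNetSpec-class].
#' @param inChannels input channel count.
#' @param useBatchnorm override the spec's batch-norm flag (e.g. FALSE to
#'   count weights and biases only).
#' @return numeric scalar.
#' @examples
#' # SubNet B conv stack fed 32 channels, weights + biases only:
#' specParameterCount(subnetPreset("B"), 32, useBatchnorm = FALSE)
#' @export
specParameterCount <- function(spec, inChannels,
                               useBatchnorm = spec@useBatchnorm) {
  cin <- inChannels; total <- 0
  for (g in spec@layerGroups) {
    total <- total + g[1] * g[2] * cin * g[3] + g[3] +
      if (useBatchnorm) 2 * g[3] else 0
    cin <- g[3]
  }
  total
}

#' @describeIn countMAdd a built SubNet at the given input spatial size.
#' @export
setMethod("countMAdd", "SubNetModule", function(object, inputShape, ...) {
  hw <- as.numeric(inputShape); cin <- object@inChannels; total <- 0
  spec <- object@spec
  for (i in seq_along(spec@layerGroups)) {
    g <- spec@layerGroups[[i]]
    if (any(hw < 1)) break
    total <- total + hw[1] * hw[2] * g[1] * g[2] * cin * g[3]
    cin <- g[3]
    if (spec@useMaxpool[i]) hw <- hw %/% 2
  }
  total
})

#' @describeIn countMAdd a classification head (one FC layer).
#' @export
setMethod("countMAdd", "ClassificationHead", function(object, inputShape, ...)
  as.numeric(length(object@w)))

#' @describeIn freezeParameters a SubNet module.
#' @export
setMethod("freezeParameters", "SubNetModule", function(object) {
  object@frozen <- TRUE
  object
})

setMethod("show", "SubNetSpec", function(object) {
  cat("SubNetSpec:", length(object@layerGroups), "layer group(s)\n")
  for (i in seq_along(object@layerGroups)) {
    g <- object@layerGroups[[i]]
    cat(sprintf("  [%d] %dx%dx%d%s%s\n", i, g[1], g[2], g[3],
                if (object@useBatchnorm) " +BN" else "",
                if (object@useMaxpool[i]) " +pool" else ""))
  }
})

setMethod("show", "SubNetModule", function(object) {
  cat(sprintf("SubNetModule (%s, in=%d, %s parameters)\n",
              if (object@frozen) "frozen" else "trainable",
              object@inChannels,
              format(countParameters(object), big.mark = ",")))
  show(object@spec)
})
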