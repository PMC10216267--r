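## GraMNet composition trees. A leaf wraps a SubNetModule; "series" feeds
## the first child's feature maps to the second; "parallel" feeds the raw
## tree input to both children and depth-concatenates their (spatially
## aligned) outputs. One global-average-pool + fully-connected + softmax
## head sits at the output.

.leafNode <- function(module) list(op = "leaf", module = module)

.newHead <- function(nFeatures, classes, seed = 1L) {
  set.seed(.deriveSeed(seed, 7L))
  new("ClassificationHead",
      w = matrix(rnorm(length(classes) * nFeatures, sd = 0.01),
                 nrow = length(classes)),
      b = numeric(length(classes)), nClasses = length(classes))
}

## Final feature depth and spatial size (given input H, W) of a tree.
.treeOutShape <- function(node, hw, inChannels) {
  if (node$op == "leaf") {
    s <- node$module@spec
    p <- sum(s@useMaxpool)
    ng <- length(s@layerGroups)
    return(c(hw %/% 2^p, s@layerGroups[[ng]][3]))
  }
  if (node$op == "series") {
    a <- .treeOutShape(node$first, hw, inChannels)
    return(.treeOutShape(node$second, a[1:2], a[3]))
  }
  a <- .treeOutShape(node$first, hw, inChannels)
  b <- .treeOutShape(node$second, hw, inChannels)
  c(pmin(a[1:2], b[1:2]), a[3] + b[3])
}

.treeDepth <- function(node, hw, inChannels) .treeOutShape(node, hw, inChannels)[3]

.treeFreeze <- function(node) {
  if (node$op == "leaf") {
    node$module <- freezeParameters(node$module)
  } else {
    node$first <- .treeFreeze(node$first)
    node$second <- .treeFreeze(node$second)
  }
  node
}

.treeLeaves <- function(node) {
  if (node$op == "leaf") return(list(node$module))
  c(.treeLeaves(node$first), .treeLeaves(node$second))
}

.treeConvLayers <- function(node) {
  sum(vapply(.treeLeaves(node),
             function(m) length(m@spec@layerGroups), numeric(1)))
}

#' Wrap a single SubNet into a GraMNet with a fresh classification head
#'
#' @param module a [SubNetModule-class] (stays trainable).
#' @param classes class names; the head emits one softmax probability per
#'   class, in this order.
#' @param inputSize integer c(H, W) the network will be applied to (the
#'   head is resolution-independent, but the size fixes pooling
#'   feasibility checks).
#' @param seed head initialization seed.
#' @return a [GraMNetGraph-class].
#' @export
gramnetFromSubnet <- function(module, classes = c("benign", "malignant"),
                              inputSize = c(32L, 32L), seed = 1L) {
  tree <- .leafNode(module)
  nf <- .treeDepth(tree, as.integer(inputSize), module@inChannels)
  new("GraMNetGraph", tree = tree,
      head = .newHead(nf, classes, seed), classes = classes,
      inChannels = module@inChannels)
}

#' Grow a GraMNet in series: the new SubNet consumes the frozen network's
#' final feature maps
#'
#' Every parameter of the existing network is frozen; the new SubNet's
#' first convolution reads the existing final feature maps, and a fresh
#' classification head is appended. With L_A conv layers before and L_B
#' in the new SubNet, the combined network has L_A + L_B conv layers plus
#' one fully connected layer.
#'
#' @param base a [GraMNetGraph-class].
#' @param new a [SubNetModule-class] whose `inChannels` equals the base
#'   network's final feature depth.
#' @param inputSize integer c(H, W) raw input size (used to validate the
#'   channel interface and pooling feasibility).
#' @param seed head initialization seed.
#' @return the grown [GraMNetGraph-class]; only `new` and the head are
#'   trainable.
#' @export
combineSeries <- function(base, new, inputSize = c(32L, 32L), seed = 1L) {
  stopifnot(is(base, "GraMNetGraph"), is(new, "SubNetModule"))
  depth <- .treeDepth(base@tree, as.integer(inputSize), base@inChannels)
  if (new@inChannels != depth)
    stop("channel mismatch: base produces ", depth,
         " feature maps but the new SubNet expects ", new@inChannels)
  tree <- list(op = "series", first = .treeFreeze(base@tree),
               second = .leafNode(new))
  nf <- .treeDepth(tree, as.integer(inputSize), base@inChannels)
  new("GraMNetGraph", tree = tree,
      head = .newHead(nf, base@classes, seed), classes = base@classes,
      inChannels = base@inChannels)
}

#' Grow a GraMNet in parallel: the new SubNet reads the raw input
#'
#' Both branches receive the identical network input. Their final feature
#' maps are spatially aligned (the larger map is adaptively
#' average-pooled to the smaller one) and concatenated along depth, and a
#' fresh joint head is appended. The existing branch is frozen.
#'
#' @inheritParams combineSeries
#' @param new a [SubNetModule-class] whose `inChannels` equals the raw
#'   input channel count.
#' @return the grown [GraMNetGraph-class].
#' @export
combineParallel <- function(base, new, inputSize = c(32L, 32L), seed = 1L) {
  stopifnot(is(base, "GraMNetGraph"), is(new, "SubNetModule"))
  if (new@inChannels != base@inChannels)
    stop("parallel SubNet must accept the raw input channel count (",
         base@inChannels, ")")
  hw <- as.integer(inputSize)
  tree <- list(op = "parallel", first = .treeFreeze(base@tree),
               second = .leafNode(new))
  sh <- .treeOutShape(tree, hw, base@inChannels)
  if (any(sh[1:2] < 1L)) stop("alignment impossible: zero-size feature map")
  new("GraMNetGraph", tree = tree,
      head = .newHead(sh[3], base@classes, seed), classes = base@classes,
      inChannels = base@inChannels)
}

## Forward through the tree. grad = TRUE keeps caches for backward.
.treeFw <- function(node, x, train = FALSE, grad = FALSE) {
  if (node$op == "leaf") {
    r <- .subnetFw(node$module, x, train = train, grad = grad)
    return(list(y = r$y, cache = list(sub = r$caches), params = r$params))
  }
  if (node$op == "series") {
    a <- .treeFw(node$first, x, train, grad)
    b <- .treeFw(node$second, a$y, train, grad)
    return(list(y = b$y, cache = list(first = a, second = b)))
  }
  a <- .treeFw(node$first, x, train, grad)
  b <- .treeFw(node$second, x, train, grad)
  da <- dim(a$y); db <- dim(b$y)
  hw <- pmin(da[1:2], db[1:2])
  ya <- if (all(da[1:2] == hw)) a$y else .avgPoolToFw(a$y, hw[1], hw[2])
  yb <- if (all(db[1:2] == hw)) b$y else .avgPoolToFw(b$y, hw[1], hw[2])
  y <- array(0, c(hw, da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- ya
  y[, , da[3] + seq_len(db[3]), ] <- yb
  list(y = y, cache = list(first = a, second = b, da = da, db = db))
}

## Does any leaf under this node remain trainable?
.treeTrainable <- function(node) {
  if (node$op == "leaf") return(!node$module@frozen)
  .treeTrainable(node$first) || .treeTrainable(node$second)
}

## Backward through the tree. Parameter grads of trainable leaves are
## collected into `acc` (an environment keyed by preorder leaf index).
## Returns dx w.r.t. the node input (NULL when nothing below needs it).
.treeBw <- function(node, fw, dy, acc, leafIndex = 1L, needDx = FALSE) {
  if (node$op == "leaf") {
    if (node$module@frozen && !needDx) return(NULL)
    r <- .subnetBw(node$module, fw$cache$sub, dy)
    if (!node$module@frozen) acc[[as.character(leafIndex)]] <- r$grads
    return(r$dx)
  }
  if (node$op == "series") {
    nFirst <- length(.treeLeaves(node$first))
    needMid <- .treeTrainable(node$first) || needDx
    dmid <- .treeBw(node$second, fw$cache$second, dy, acc,
                    leafIndex + nFirst, needDx = needMid)
    if (!needMid) return(NULL)
    return(.treeBw(node$first, fw$cache$first, dmid, acc, leafIndex,
                   needDx = needDx))
  }
  da <- fw$cache$da; db <- fw$cache$db
  hw <- pmin(da[1:2], db[1:2])
  nFirst <- length(.treeLeaves(node$first))
  out <- NULL
  if (.treeTrainable(node$first) || needDx) {
    dya <- dy[, , seq_len(da[3]), , drop = FALSE]
    if (!all(da[1:2] == hw)) dya <- .avgPoolToBw(dya, da[1], da[2])
    out <- .treeBw(node$first, fw$cache$first, dya, acc, leafIndex,
                   needDx = needDx)
  }
  if (.treeTrainable(node$second) || needDx) {
    dyb <- dy[, , da[3] + seq_len(db[3]), , drop = FALSE]
    if (!all(db[1:2] == hw)) dyb <- .avgPoolToBw(dyb, db[1], db[2])
    out2 <- .treeBw(node$second, fw$cache$second, dyb, acc,
                    leafIndex + nFirst, needDx = needDx)
    out <- if (is.null(out)) out2 else out + out2
  }
  out
}

## Store updated parameters (and BN running stats) back into the tree.
## `updates` maps preorder leaf index -> new params list.
.treeSetParams <- function(node, updates, leafIndex = 1L) {
  if (node$op == "leaf") {
    key <- as.character(leafIndex)
    if (!is.null(updates[[key]])) node$module@params <- updates[[key]]
    return(node)
  }
  nFirst <- length(.treeLeaves(node$first))
  node$first <- .treeSetParams(node$first, updates, leafIndex)
  node$second <- .treeSetParams(node$second, updates, leafIndex + nFirst)
  node
}

#' Forward pass through a GraMNet, returning class probabilities
#'
#' Runs the composition tree, global-average-pools the final feature map
#' and applies the fully connected head followed by softmax: every row is
#' a probability vector over the classes and sums to 1.
#'
#' @param net a [GraMNetGraph-class].
#' @param x input tensor, array (H, W, C, N) or a single image
#'   (matrix / H x W x C array).
#' @param train use batch statistics in trainable batch-norm layers.
#' @return N x M matrix of class probabilities (columns named by class).
#' @export
forwardWithHead <- function(net, x, train = FALSE) {
  x <- .asTensor(x, net@inChannels)
  r <- .treeFw(net@tree, x, train = train, grad = FALSE)
  z <- .gapFw(r$y)                       # (F, N)
  logits <- net@head@w %*% z + net@head@b
  probs <- t(.softmaxCols(logits))
  colnames(probs) <- net@classes
  probs
}

## Coerce user input to a (H, W, C, N) tensor.
.asTensor <- function(x, channels) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) {
    x <- if (dim(x)[3] == channels) array(x, c(dim(x), 1L))
         else array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
  }
  if (length(dim(x)) != 4L) stop("expected an (H, W, C, N) tensor")
  if (dim(x)[3] != channels)
    stop("input has ", dim(x)[3], " channels; network expects ", channels)
  x
}

#' @describeIn countParameters a GraMNet graph (all SubNets plus head).
#' @export
setMethod("countParameters", "GraMNetGraph", function(object, ...)
  countParameters(.treeLeaves(object@tree)) + countParameters(object@head))

#' Count only the trainable parameters of a GraMNet
#'
#' The unfrozen SubNet(s) plus the classification head; this is the
#' quantity each staged training step actually updates.
#'
#' @param net a [GraMNetGraph-class].
#' @return numeric scalar.
#' @export
countTrainableParameters <- function(net) {
  leaves <- .treeLeaves(net@tree)
  sum(vapply(leaves, function(m)
    if (m@frozen) 0 else countParameters(m), numeric(1))) +
    countParameters(net@head)
}

#' @describeIn countMAdd a GraMNet graph at the given raw input size.
#' @export
setMethod("countMAdd", "GraMNetGraph", function(object, inputShape, ...) {
  walk <- function(node, hw, cin) {
    if (node$op == "leaf") {
      m <- node$module
      return(list(madd = countMAdd(m, hw),
                  shape = .treeOutShape(node, as.integer(hw), cin)))
    }
    if (node$op == "series") {
      a <- walk(node$first, hw, cin)
      b <- walk(node$second, a$shape[1:2], a$shape[3])
      return(list(madd = a$madd + b$madd, shape = b$shape))
    }
    a <- walk(node$first, hw, cin)
    b <- walk(node$second, hw, cin)
    list(madd = a$madd + b$madd,
         shape = c(pmin(a$shape[1:2], b$shape[1:2]), a$shape[3] + b$shape[3]))
  }
  r <- walk(object@tree, as.numeric(inputShape), object@inChannels)
  r$madd + countMAdd(object@head, NULL)
})

#' @describeIn freezeParameters every SubNet in a GraMNet graph (the
#'   head stays trainable by definition).
#' @export
setMethod("freezeParameters", "GraMNetGraph", function(object) {
  object@tree <- .treeFreeze(object@tree)
  object
})

setMethod("show", "GraMNetGraph", function(object) {
  fmt <- function(node) {
    if (node$op == "leaf")
      return(sprintf("SubNet[%s]", if (node$module@frozen) "frozen" else "train"))
    op <- if (node$op == "series") "+" else "||"
    sprintf("(%s %s %s)", fmt(node$first), op, fmt(node$second))
  }
  cat("GraMNetGraph:", fmt(object@tree), "\n")
  cat(sprintf("  classes: %s | parameters: %s (trainable %s)\n",
              paste(object@classes, collapse = "/"),
              format(countParameters(object), big.mark = ","),
              format(countTrainableParameters(object), big.mark = ",")))
})

#' Save / load a GraMNet graph
#'
#' The topology (specs, frozen flags, classes) is written as YAML and the
#' numeric parameters as RDS blobs inside `dir`.
#'
#' @param net a [GraMNetGraph-class].
#' @param dir output directory (created if needed).
#' @return `saveGramnet` returns `dir` invisibly; `loadGramnet` the graph.
#' @export
saveGramnet <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  topo <- function(node) {
    if (node$op == "leaf")
      list(op = "leaf", frozen = node$module@frozen,
           inChannels = node$module@inChannels,
           useBatchnorm = node$module@spec@useBatchnorm,
           useMaxpool = as.list(node$module@spec@useMaxpool),
           layerGroups = lapply(node$module@spec@layerGroups, as.list))
    else list(op = node$op, first = topo(node$first), second = topo(node$second))
  }
  yaml::write_yaml(list(classes = as.list(net@classes),
                        inChannels = net@inChannels, tree = topo(net@tree)),
                   file.path(dir, "topology.yaml"))
  saveRDS(lapply(.treeLeaves(net@tree), function(m) m@params),
          file.path(dir, "subnet-params.rds"))
  saveRDS(list(w = net@head@w, b = net@head@b), file.path(dir, "head.rds"))
  invisible(dir)
}

#' @rdname saveGramnet
#' @export
loadGramnet <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "topology.yaml"))
  params <- readRDS(file.path(dir, "subnet-params.rds"))
  hp <- readRDS(file.path(dir, "head.rds"))
  i <- 0L
  rebuild <- function(node) {
    if (node$op == "leaf") {
      i <<- i + 1L
      spec <- SubNetSpec(lapply(node$layerGroups, unlist),
                         useBatchnorm = node$useBatchnorm,
                         useMaxpool = unlist(node$useMaxpool))
      mod <- new("SubNetModule", spec = spec,
                 inChannels = as.integer(node$inChannels),
                 params = params[[i]], frozen = isTRUE(node$frozen))
      return(.leafNode(mod))
    }
    list(op = node$op, first = rebuild(node$first), second = rebuild(node$second))
  }
  tree <- rebuild(meta$tree)
  head <- new("ClassificationHead", w = hp$w, b = as.numeric(hp$b),
              nClasses = nrow(hp$w))
  new("GraMNetGraph", tree = tree, head = head,
      classes = unlist(meta$classes), inChannels = as.integer(meta$inChannels))
}
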