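## Internal convolutional-network engine. Tensors are arrays (H, W, C, N).
## Convolution is im2col (C++) + one BLAS GEMM; backward uses the adjoint
## col2im. Only "same" padding with odd kernel sides is needed by the
## package, and 2x2/stride-2 max pooling.

.t2mat <- function(x) {            # (H,W,C,N) -> (C, H*W*N), channel-major
  d <- dim(x)
  matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = d[3])
}

.mat2t <- function(m, H, W, N) {   # inverse of .t2mat
  aperm(array(m, c(nrow(m), H, W, N)), c(2L, 3L, 1L, 4L))
}

.convFw <- function(x, w, b) {
  d <- dim(x); k <- dim(w)
  padh <- (k[1] - 1L) %/% 2L; padw <- (k[2] - 1L) %/% 2L
  K <- .cpp_im2col(x, k[1], k[2], padh, padw)
  wm <- matrix(w, ncol = k[4])
  y <- crossprod(wm, K) + b          # (cout, H*W*N), bias recycles by column
  .mat2t(y, d[1], d[2], d[4])
}

.convBw <- function(x, w, dy) {
  d <- dim(x); k <- dim(w)
  padh <- (k[1] - 1L) %/% 2L; padw <- (k[2] - 1L) %/% 2L
  K <- .cpp_im2col(x, k[1], k[2], padh, padw)
  dym <- .t2mat(dy)                                   # (cout, HWN)
  dw <- array(tcrossprod(K, dym), dim = k)            # (khkwcin, cout)
  db <- rowSums(dym)
  dK <- matrix(w, ncol = k[4]) %*% dym
  dx <- .cpp_col2im(dK, d[1], d[2], d[3], d[4], k[1], k[2], padh, padw)
  list(dx = dx, dw = dw, db = db)
}

## Spatial batch norm over (H, W, N) per channel.
.bnFw <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- .t2mat(x)                                     # (C, HWN)
  if (train) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar  <- (1 - momentum) * p$rvar  + momentum * va
  } else {
    mu <- p$rmean; va <- p$rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  y <- .mat2t(p$gamma * xhat + p$beta, d[1], d[2], d[4])
  list(y = y, cache = list(xhat = xhat, istd = istd, dims = d, train = train),
       params = p)
}

.bnBw <- function(p, cache, dy) {
  d <- cache$dims
  dym <- .t2mat(dy)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$train) {
    M <- ncol(dym)
    dxm <- (p$gamma * cache$istd / M) *
      (M * dym - dbeta - cache$xhat * dgamma)
  } else {
    dxm <- p$gamma * cache$istd * dym
  }
  list(dx = .mat2t(dxm, d[1], d[2], d[4]), dgamma = dgamma, dbeta = dbeta)
}

.reluFw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

.poolFw <- function(x) {
  d <- dim(x)
  if (d[1] < 2L || d[2] < 2L)
    stop("max pooling needs spatial dimensions >= 2 (input is ",
         d[1], "x", d[2], ")")
  .cpp_maxpool_fw(x)
}

.upsample2Fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

.upsample2Bw <- function(dy) {
  d <- dim(dy); H <- d[1] %/% 2L; W <- d[2] %/% 2L
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  e1 <- seq(1L, d[2], 2L); e2 <- seq(2L, d[2], 2L)
  dy[o1, e1, , , drop = FALSE] + dy[o2, e1, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[o2, e2, , , drop = FALSE]
}

## Adaptive average pooling from (H, W) to (h, w) where h | H and w | W.
.avgPoolToFw <- function(x, h, w) {
  d <- dim(x)
  if (d[1] %% h != 0L || d[2] %% w != 0L)
    stop("adaptive average pooling needs integer block factors")
  f1 <- d[1] %/% h; f2 <- d[2] %/% w
  m1 <- colMeans(array(x, c(f1, h, d[2], d[3], d[4])), dims = 1L)   # (h,W,C,N)
  m1p <- aperm(m1, c(2L, 1L, 3L, 4L))                               # (W,h,C,N)
  m2 <- colMeans(array(m1p, c(f2, w, h, d[3], d[4])), dims = 1L)    # (w,h,C,N)
  aperm(m2, c(2L, 1L, 3L, 4L))
}

.avgPoolToBw <- function(dy, H, W) {
  d <- dim(dy)
  f1 <- H %/% d[1]; f2 <- W %/% d[2]
  g <- dy / (f1 * f2)
  g[rep(seq_len(d[1]), each = f1), rep(seq_len(d[2]), each = f2), , ,
    drop = FALSE]
}

.gapFw <- function(x) {            # global average pool -> (C, N)
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
}

.gapBw <- function(dz, H, W) {     # dz is (C, N)
  d <- dim(dz)
  aperm(array(rep(t(dz), each = H * W) / (H * W), c(H, W, d[2], d[1])),
        c(1L, 2L, 4L, 3L))
}

.heConv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

## Adam with optional L2 (added to the gradient, "weight decay" sense).
.adamInit <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         classes = c("numeric", "array", "matrix"), how = "replace")
}

.adamStep <- function(p, g, st, t, lr, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (l2 > 0) g <- g + l2 * p
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

## Apply .adamStep over a parallel (params, grads, state) structure.
## Batch-norm running statistics (rmean/rvar) are not optimized, and L2
## decay applies only to weight tensors, never to biases or BN scalars.
.adamUpdate <- function(params, grads, state, t, lr, l2 = 0) {
  walk <- function(p, g, s, name = "") {
    if (is.numeric(p)) {
      if (name %in% c("rmean", "rvar")) return(list(p = p, st = s))
      r <- .adamStep(p, g, s, t, lr, if (name == "w") l2 else 0)
      return(r)
    }
    out.p <- p; out.s <- s
    nms <- names(p)
    for (i in seq_along(p)) {
      nm <- if (is.null(nms)) "" else nms[i]
      r <- walk(p[[i]], g[[i]], s[[i]], nm)
      if (is.numeric(p[[i]])) {
        out.p[[i]] <- r$p; out.s[[i]] <- r$st
      } else {
        out.p[[i]] <- r$p; out.s[[i]] <- r$s
      }
    }
    list(p = out.p, s = out.s)
  }
  walk(params, grads, state)
}

.softmaxCols <- function(z) {      # columns are samples
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## Derive a per-call RNG seed below 2^31 from a base seed and an index.
.deriveSeed <- function(seed, index = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1664525 + 11) %%
               2147483647)
}
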