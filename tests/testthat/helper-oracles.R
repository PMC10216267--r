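## Independent brute-force oracles used across the suite. These are
## deliberately naive (loops, enumeration) and share no code with the
## package implementations they check.

## Naive direct convolution, "same" padding, loops over every output
## element. x: (H, W, C) array, w: (kh, kw, cin, cout), b: length cout.
naiveConv <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  y <- array(0, c(H, W, cout))
  for (o in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[o]
    for (c in seq_len(cin)) for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      ii <- i + di - 1 - ph; jj <- j + dj - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[di, dj, c, o]
    }
    y[i, j, o] <- acc
  }
  y
}

naiveMaxpool <- function(x) {
  H <- dim(x)[1] %/% 2; W <- dim(x)[2] %/% 2; C <- dim(x)[3]
  y <- array(0, c(H, W, C))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W))
    y[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  y
}

## Forward a SubNet without batch norm via the naive kernels.
naiveSubnetForward <- function(mod, x) {
  stopifnot(!mod@spec@useBatchnorm)
  for (g in seq_along(mod@params)) {
    p <- mod@params[[g]]
    x <- naiveConv(x, p$w, p$b)
    x <- pmax(x, 0)
    if (mod@spec@useMaxpool[g]) x <- naiveMaxpool(x)
  }
  x
}

## Recursive flood fill, 8-connected labelling (matrix of 0/1).
naiveLabel8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

naiveClearFragments <- function(mask, minArea) {
  lab <- naiveLabel8(mask)
  out <- mask * 0
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab)))
    if (sum(lab == k) >= minArea) out[lab == k] <- 1
  out
}

## AUC by enumerating all positive/negative pairs (ties count 1/2).
naiveAUC <- function(scores, labels, positive = "malignant") {
  pos <- scores[labels == positive]; neg <- scores[labels != positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

randomMask <- function(h, w, p = 0.4) matrix(rbinom(h * w, 1, p), h, w)

## Small in-memory phantom sets for training tests.
phantomSet <- function(n, imageSize = 32L, seed = 7L, ...) {
  cfg <- PhantomConfig(imageSize = imageSize, tumorRadius = c(2.5, 5),
                       nTumors = c(0L, 2L), seed = seed, ...)
  lapply(seq_len(n), function(i) generatePhantom(cfg, i))
}

labelsOf <- function(samples) vapply(samples, function(s) s@label, character(1))

## Serialize-and-digest of a parameter list (cryptographic fingerprint).
paramHash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(params, f, compress = FALSE)
  unname(tools::md5sum(f))
}

frozenLeafParams <- function(net) {
  leaves <- GraMNet:::.treeLeaves(net@tree)
  lapply(Filter(function(m) m@frozen, leaves), function(m) m@params)
}
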