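#' Read / write a dataset manifest CSV
#'
#' @param x a [DatasetManifest-class].
#' @param path CSV path.
#' @param provenance free-text source note stored on the object.
#' @return `readManifest` returns a [DatasetManifest-class];
#'   `writeManifest` returns `path` invisibly.
#' @export
writeManifest <- function(x, path) {
  validObject(x)
  write.csv(x@records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path, provenance = path) {
  rec <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  new("DatasetManifest", records = rec, provenance = provenance)
}

#' Construct a manifest from a records data.frame
#' @param records data.frame with columns id, image_path, liver_mask_path,
#'   tumor_mask_path, label, split.
#' @param provenance free-text source note.
#' @return a [DatasetManifest-class].
#' @export
DatasetManifest <- function(records, provenance = "constructed") {
  if (!"split" %in% names(records)) records$split <- "unassigned"
  new("DatasetManifest", records = records, provenance = provenance)
}

setMethod("show", "DatasetManifest", function(object) {
  tab <- table(factor(object@records$split,
                      levels = c("train", "val", "test", "unassigned")))
  cat(sprintf("DatasetManifest: %d records (%s)\n  provenance: %s\n",
              nrow(object@records),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              object@provenance))
})

#' Merge several binary masks into one (pixel-wise logical OR)
#'
#' Used to collapse per-structure annotation masks (e.g. several tumor
#' masks per patient) into a single mask.
#'
#' @param masks list of binary matrices of identical shape.
#' @return a binary matrix.
#' @export
mergeMasks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]])
  out <- matrix(0, d[1], d[2])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("mask shape mismatch in mergeMasks")
    out <- pmax(out, (m != 0) * 1)
  }
  out
}

#' Drop records whose liver mask is empty
#'
#' Removes slices taken at the beginning and end of a scan that contain
#' no liver; record order is preserved.
#'
#' @param manifest a [DatasetManifest-class].
#' @return the filtered manifest.
#' @export
filterEmptySlices <- function(manifest) {
  keep <- vapply(seq_len(nrow(manifest@records)), function(i) {
    r <- manifest@records[i, ]
    if (!file.exists(r$liver_mask_path))
      stop("missing liver mask for record '", r$id, "': ", r$liver_mask_path)
    sum(readImagePNG(r$liver_mask_path)) > 0
  }, logical(1))
  manifest@records <- manifest@records[keep, , drop = FALSE]
  manifest
}

#' Preprocess an image: resize by 0.25 and min-max normalize to [0, 1]
#'
#' Bilinear resampling for intensity images; a constant image maps to
#' all zeros (degenerate min-max range).
#'
#' @param image H x W matrix (or H x W x C array, resized per channel).
#' @param factor spatial scale factor (default 0.25).
#' @return the resized, normalized image.
#' @export
preprocessImage <- function(image, factor = 0.25) {
  if (length(image) == 0L) stop("empty image")
  resize1 <- function(m) {
    h <- max(1L, round(nrow(m) * factor)); w <- max(1L, round(ncol(m) * factor))
    r <- EBImage::resize(EBImage::Image(m), w = h, h = w)
    matrix(EBImage::imageData(r), h, w)
  }
  out <- if (length(dim(image)) == 3L) {
    ch <- lapply(seq_len(dim(image)[3]), function(c) resize1(image[, , c]))
    array(unlist(ch), c(dim(ch[[1]]), length(ch)))
  } else resize1(image)
  rng <- range(out)
  if (diff(rng) == 0) out * 0 else (out - rng[1]) / diff(rng)
}

#' Resize a binary mask with nearest-neighbor sampling
#'
#' Nearest-neighbor keeps masks strictly binary.
#'
#' @param mask binary matrix.
#' @param factor spatial scale factor (default 0.25).
#' @return the resized binary matrix.
#' @export
preprocessMask <- function(mask, factor = 0.25) {
  h <- max(1L, round(nrow(mask) * factor)); w <- max(1L, round(ncol(mask) * factor))
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(mask), w = h,
                                            h = w, filter = "none"))
  (matrix(out, h, w) > 0.5) * 1
}

#' Train/validation/test split ratios
#'
#' Two protocols ship as named presets: `"classification"` (72/8/20, the
#' default for staged GraMNet training) and `"segmentation"` (63/17/20).
#'
#' @param train,val,test fractions in [0, 1] summing to 1 (tolerance 1e-9).
#' @param preset alternatively, a preset name.
#' @return named numeric vector c(train, val, test).
#' @export
splitRatios <- function(train, val, test, preset = NULL) {
  if (!is.null(preset)) {
    r <- switch(preset,
                classification = c(0.72, 0.08, 0.20),
                segmentation = c(0.63, 0.17, 0.20),
                stop("unknown split preset: ", preset))
    return(setNames(r, c("train", "val", "test")))
  }
  r <- c(train = train, val = val, test = test)
  if (any(r < 0) || any(r > 1) || abs(sum(r) - 1) > 1e-9)
    stop("split ratios must lie in [0, 1] and sum to 1")
  r
}

#' Assign train/val/test split tags to a manifest
#'
#' Deterministic for a fixed seed. Counts are rounded to the nearest
#' integer (per class when stratified by label); partitions are disjoint
#' and exhaustive and the record order is preserved.
#'
#' @param manifest a [DatasetManifest-class].
#' @param ratios from [splitRatios()].
#' @param seed RNG seed.
#' @param stratified split each label class separately (default TRUE).
#' @return the manifest with split tags assigned.
#' @export
splitDataset <- function(manifest,
                         ratios = splitRatios(preset = "classification"),
                         seed = 1L, stratified = TRUE) {
  rec <- manifest@records
  n <- nrow(rec)
  set.seed(.deriveSeed(seed, 3L))
  assign1 <- function(idx) {
    m <- length(idx)
    nTrain <- round(ratios[["train"]] * m)
    nVal <- round(ratios[["val"]] * m)
    nTrain <- min(nTrain, m); nVal <- min(nVal, m - nTrain)
    sh <- sample(idx)
    list(train = sh[seq_len(nTrain)],
         val = if (nVal > 0) sh[nTrain + seq_len(nVal)] else integer(),
         test = if (m - nTrain - nVal > 0) sh[(nTrain + nVal + 1):m] else integer())
  }
  if (stratified) {
    classes <- unique(rec$label)
    if (n < length(classes)) stop("fewer samples than classes; cannot stratify")
    parts <- lapply(classes, function(cl) assign1(which(rec$label == cl)))
    rec$split[unlist(lapply(parts, `[[`, "train"))] <- "train"
    rec$split[unlist(lapply(parts, `[[`, "val"))] <- "val"
    rec$split[unlist(lapply(parts, `[[`, "test"))] <- "test"
  } else {
    p <- assign1(seq_len(n))
    rec$split[p$train] <- "train"; rec$split[p$val] <- "val"
    rec$split[p$test] <- "test"
  }
  manifest@records <- rec
  manifest
}

#' K-fold partition of a manifest
#'
#' A driver for cross-validation protocols: returns `k` manifests in
#' which fold `i` is tagged "test" and the rest "train".
#'
#' @param manifest a [DatasetManifest-class].
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` manifests.
#' @export
kfoldSplits <- function(manifest, k = 5L, seed = 1L) {
  n <- nrow(manifest@records)
  set.seed(.deriveSeed(seed, 5L))
  fold <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(i) {
    m <- manifest
    m@records$split <- ifelse(fold == i, "test", "train")
    m
  })
}

## One random joint transform: flips, 90-degree rotations, small integer
## translation (applied to image and masks alike) and intensity jitter
## (image only). Identity when `identity = TRUE`.
.rot90 <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

.shiftPad <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di; sj <- seq_len(ncol(m)) - dj
  ok.i <- si >= 1 & si <= nrow(m); ok.j <- sj >= 1 & sj <= ncol(m)
  out[which(ok.i), which(ok.j)] <- m[si[ok.i], sj[ok.j], drop = FALSE]
  out
}

.applyGeom <- function(m, tr) {
  if (tr$fliph) m <- m[, ncol(m):1, drop = FALSE]
  if (tr$flipv) m <- m[nrow(m):1, , drop = FALSE]
  m <- .rot90(m, tr$rot)
  .shiftPad(m, tr$di, tr$dj)
}

#' Augment in-memory phantom records by a fixed factor
#'
#' Each source record yields `factor` records: the first is the original,
#' the rest apply a random joint transform (horizontal/vertical flips,
#' 90-degree rotations, integer translations up to 3 px) to image and
#' masks together, plus intensity jitter on the image only. Deterministic
#' for a fixed seed; masks stay binary and nested.
#'
#' @param records list of [PhantomSample-class] objects.
#' @param factor integer >= 1, output/input length ratio.
#' @param seed RNG seed.
#' @return list of `length(records) * factor` samples.
#' @export
augmentRecords <- function(records, factor, seed = 1L) {
  if (factor < 1) stop("augmentation factor must be >= 1")
  set.seed(.deriveSeed(seed, 11L))
  out <- vector("list", length(records) * factor)
  k <- 0L
  for (s in records) {
    for (j in seq_len(factor)) {
      k <- k + 1L
      if (j == 1L) { out[[k]] <- s; next }
      tr <- list(fliph = runif(1) < 0.5, flipv = runif(1) < 0.5,
                 rot = sample(0:3, 1), di = sample(-3:3, 1),
                 dj = sample(-3:3, 1))
      gain <- runif(1, 0.9, 1.1); shift <- runif(1, -0.05, 0.05)
      img <- s@image
      for (c in seq_len(dim(img)[3]))
        img[, , c] <- pmin(pmax(.applyGeom(img[, , c], tr) * gain + shift, 0), 1)
      out[[k]] <- new("PhantomSample", image = img,
                      liverMask = .applyGeom(s@liverMask, tr),
                      tumorMask = .applyGeom(s@tumorMask, tr),
                      label = s@label)
    }
  }
  out
}
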