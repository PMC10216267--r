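#' Construct a phantom generator configuration
#'
#' Defaults emulate the statistics the segmentation/classification
#' pipeline assumes: an elliptical liver region brighter than background,
#' hypodense (darker) tumors well separated from parenchyma noise, and an
#' image side of 128 pixels for desk-scale speed (512 is reachable via
#' `imageSize`).
#'
#' @param imageSize pixels per side, >= 32.
#' @param liverAxes ellipse semi-axis range, fraction of the image side.
#' @param nTumors inclusive range of tumor counts per sample.
#' @param tumorRadius tumor radius range in pixels; the default scales
#'   with the image side so geometry is resolution-independent.
#' @param tumorContrast signed intensity offset range (negative =
#'   hypodense, positive = hyperdense); must not straddle zero and must
#'   exceed `2 * noiseSD` in magnitude so tumors are statistically
#'   separable from parenchyma.
#' @param noiseSD additive Gaussian noise scale.
#' @param channels 1, or 2 to append a smoothed contrast-stretched copy
#'   of the slice as a perfusion-map stand-in.
#' @param seed RNG seed; together with the sample index it fully
#'   determines each sample.
#' @return a [PhantomConfig-class].
#' @export
PhantomConfig <- function(imageSize = 128L, liverAxes = c(0.22, 0.38),
                          nTumors = c(0L, 3L),
                          tumorRadius = c(3, 10) * imageSize / 128,
                          tumorContrast = c(-0.35, -0.15), noiseSD = 0.02,
                          channels = 1L, seed = 1L) {
  obj <- new("PhantomConfig", imageSize = as.integer(imageSize),
             liverAxes = as.numeric(liverAxes),
             nTumors = as.integer(nTumors),
             tumorRadius = as.numeric(tumorRadius),
             tumorContrast = as.numeric(sort(tumorContrast)),
             noiseSD = as.numeric(noiseSD), channels = as.integer(channels),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Generate one synthetic phantom sample
#'
#' Deterministic for a fixed (config seed, index): generating the same
#' sample twice gives bit-identical images and masks. The sample is
#' labelled "malignant" exactly when the tumor mask is nonempty.
#'
#' @param cfg a [PhantomConfig-class].
#' @param index sample index (non-negative integer).
#' @return a [PhantomSample-class].
#' @examples
#' s <- generatePhantom(PhantomConfig(imageSize = 64L), 1)
#' mean(s@image[s@tumorMask == 1])   # hypodense: below parenchyma mean
#' @export
generatePhantom <- function(cfg, index) {
  validObject(cfg)
  set.seed(.deriveSeed(cfg@seed, index))
  n <- cfg@imageSize
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))

  ## liver: rotated ellipse, jittered centre
  cx <- n / 2 + runif(1, -0.05, 0.05) * n
  cy <- n / 2 + runif(1, -0.05, 0.05) * n
  ax <- runif(1, cfg@liverAxes[1], cfg@liverAxes[2]) * n
  ay <- runif(1, cfg@liverAxes[1], cfg@liverAxes[2]) * n
  th <- runif(1, 0, pi)
  dx <- xy$x - cx; dy <- xy$y - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  liver <- matrix(as.numeric((u / ax)^2 + (v / ay)^2 <= 1), n, n)

  background <- 0.15; parenchyma <- 0.55
  img <- matrix(background, n, n) + liver * (parenchyma - background)

  ## tumors: disks fully sampled inside the liver ellipse
  k <- if (cfg@nTumors[1] == cfg@nTumors[2]) cfg@nTumors[1] else
    sample(seq(cfg@nTumors[1], cfg@nTumors[2]), 1)
  tumor <- matrix(0, n, n)
  if (k > 0) {
    for (i in seq_len(k)) {
      r <- runif(1, cfg@tumorRadius[1], cfg@tumorRadius[2])
      ## position in ellipse coordinates, margin of one radius
      repeat {
        pu <- runif(1, -1, 1); pv <- runif(1, -1, 1)
        if (pu^2 + pv^2 <= 0.8^2) break
      }
      tx <- cx + pu * ax * cos(th) - pv * ay * sin(th)
      ty <- cy + pu * ax * sin(th) + pv * ay * cos(th)
      contrast <- runif(1, cfg@tumorContrast[1], cfg@tumorContrast[2])
      disk <- matrix(as.numeric((xy$x - tx)^2 + (xy$y - ty)^2 <= r^2), n, n)
      disk <- disk * liver                 # enforce nesting
      img <- img + disk * (1 - tumor) * contrast
      tumor <- pmax(tumor, disk)
    }
  }

  img <- img + matrix(rnorm(n * n, sd = cfg@noiseSD), n, n)
  img <- pmin(pmax(img, 0), 1)

  if (cfg@channels == 2L) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 2))
    rng <- range(sm)
    sm <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else sm * 0
    image <- array(c(img, sm), c(n, n, 2L))
  } else {
    image <- array(img, c(n, n, 1L))
  }

  new("PhantomSample", image = image, liverMask = liver, tumorMask = tumor,
      label = if (sum(tumor) > 0) "malignant" else "benign")
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes 8-bit grayscale PNGs for images and masks and a manifest CSV
#' (columns id, image_path, liver_mask_path, tumor_mask_path, label,
#' split). Default sizes mirror a 2346-image training set and a
#' 392-image test set (2738 records in total).
#'
#' @param cfg a [PhantomConfig-class].
#' @param nTrain,nTest record counts per split.
#' @param outDir output directory (created).
#' @return a [DatasetManifest-class]; the manifest CSV is written to
#'   `file.path(outDir, "manifest.csv")`.
#' @export
generateDataset <- function(cfg, nTrain = 2346L, nTest = 392L, outDir) {
  stopifnot(nTrain >= 0, nTest >= 0)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  splits <- rep(c("train", "test"), c(nTrain, nTest))
  n <- length(splits)
  rec <- data.frame(id = character(n), image_path = character(n),
                    liver_mask_path = character(n),
                    tumor_mask_path = character(n), label = character(n),
                    split = splits, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- generatePhantom(cfg, i)
    id <- sprintf("phantom_%05d", i)
    paths <- file.path(outDir, paste0(id, c(".png", "_liver.png", "_tumor.png")))
    writeImagePNG(s@image, paths[1])
    writeImagePNG(s@liverMask, paths[2])
    writeImagePNG(s@tumorMask, paths[3])
    rec[i, ] <- c(id, paths, s@label, splits[i])
  }
  man <- new("DatasetManifest", records = rec,
             provenance = sprintf("phantomgen seed=%d imageSize=%d",
                                  cfg@seed, cfg@imageSize))
  writeManifest(man, file.path(outDir, "manifest.csv"))
  man
}

#' Read a dataset record back into a PhantomSample
#'
#' @param manifest a [DatasetManifest-class].
#' @param i record index or id.
#' @return a [PhantomSample-class].
#' @export
readPhantomRecord <- function(manifest, i) {
  r <- if (is.character(i))
    manifest@records[manifest@records$id == i, , drop = FALSE]
  else manifest@records[i, , drop = FALSE]
  if (nrow(r) != 1L) stop("record not found: ", i)
  img <- readImagePNG(r$image_path)
  new("PhantomSample", image = if (is.matrix(img))
        array(img, c(dim(img), 1L)) else img,
      liverMask = round(readImagePNG(r$liver_mask_path)),
      tumorMask = round(readImagePNG(r$tumor_mask_path)),
      label = r$label)
}

#' 8-bit grayscale PNG I/O
#'
#' Images are stored row-major by the PNG format; these helpers keep the
#' package's (row, column) matrix orientation stable across a round trip.
#' Multichannel images are written as PNG channels.
#'
#' @param x matrix or H x W x C array with values in [0, 1].
#' @param path file path.
#' @return `readImagePNG` returns a matrix (or array for multichannel
#'   input); `writeImagePNG` returns `path` invisibly.
#' @export
writeImagePNG <- function(x, path) {
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  storage.mode(x) <- "double"
  png::writePNG(x, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  png::readPNG(path)
}

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomSample %dx%d (%d channel%s), label=%s\n",
              d[1], d[2], d[3], if (d[3] > 1) "s" else "", object@label))
  cat(sprintf("  liver %d px, tumor %d px\n",
              sum(object@liverMask), sum(object@tumorMask)))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(paste0("PhantomConfig: %dpx, liver axes [%.2f, %.2f], ",
                     "%d-%d tumors r[%.0f, %.0f]px, contrast [%.2f, %.2f], ",
                     "noise %.3f, %d channel(s), seed %d\n"),
              object@imageSize, object@liverAxes[1], object@liverAxes[2],
              object@nTumors[1], object@nTumors[2], object@tumorRadius[1],
              object@tumorRadius[2], object@tumorContrast[1],
              object@tumorContrast[2], object@noiseSD, object@channels,
              object@seed))
})
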