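## Thin loaders for real-data layouts (DICOM slice series, NIfTI volume +
## mask pairs). These mirror the directory conventions of public liver CT
## collections; they are deliberately minimal and are not exercised
## against real clinical data by default.

#' Read a single uncompressed DICOM slice (explicit VR, little endian)
#'
#' A minimal reader supporting the subset of the format that slice-per-
#' file CT exports use: explicit-VR little-endian transfer syntax,
#' single-frame MONOCHROME pixel data, 8/16-bit allocations, and the
#' rescale slope/intercept tags. Compressed transfer syntaxes and
#' sequences of undefined length are rejected.
#'
#' @param path DICOM file path.
#' @return list with `image` (numeric matrix, rescale applied),
#'   `rows`, `cols`, `instance` (InstanceNumber or NA).
#' @export
readDicomSlice <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  read32 <- function() {
    b <- readBin(con, "raw", 4L)
    sum(as.integer(b) * c(1, 256, 65536, 16777216))
  }
  meta <- list(rows = NA, cols = NA, bits = 16L, signed = FALSE,
               slope = 1, intercept = 0, instance = NA)
  long.vr <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    g <- u16(); if (length(g) == 0L) break
    e <- u16()
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% long.vr) { readBin(con, "raw", 2L); len <- read32() }
    else len <- u16()
    if (len == 4294967295) stop("undefined-length elements are not supported")
    tag <- sprintf("%04x,%04x", g, e)
    if (tag == "7fe0,0010") {
      nraw <- readBin(con, "raw", len)
      npix <- len %/% (meta$bits %/% 8L)
      vals <- readBin(nraw, "integer", npix, size = meta$bits %/% 8L,
                      signed = meta$signed || meta$bits == 32L,
                      endian = "little")
      if (is.na(meta$rows) || is.na(meta$cols))
        stop("PixelData before Rows/Columns in ", path)
      img <- matrix(vals, nrow = meta$rows, byrow = TRUE)
      return(list(image = img * meta$slope + meta$intercept,
                  rows = meta$rows, cols = meta$cols,
                  instance = meta$instance))
    }
    payload <- readBin(con, "raw", len)
    val.str <- function() trimws(rawToChar(payload))
    val.u16 <- function() readBin(payload, "integer", 1L, size = 2L,
                                  signed = FALSE, endian = "little")
    if (tag == "0028,0010") meta$rows <- val.u16()
    if (tag == "0028,0011") meta$cols <- val.u16()
    if (tag == "0028,0100") meta$bits <- val.u16()
    if (tag == "0028,0103") meta$signed <- val.u16() == 1L
    if (tag == "0028,1052") meta$intercept <- as.numeric(val.str())
    if (tag == "0028,1053") meta$slope <- as.numeric(val.str())
    if (tag == "0020,0013") meta$instance <- as.integer(val.str())
  }
  stop("no PixelData element found in ", path)
}

#' Read a DICOM series directory (one file per slice)
#'
#' @param dir directory containing `.dcm` files.
#' @return list of slices from [readDicomSlice()], ordered by
#'   InstanceNumber when present, else by file name.
#' @export
readDicomSeries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no DICOM files in ", dir)
  slices <- lapply(files, readDicomSlice)
  inst <- vapply(slices, function(s) as.numeric(s$instance), numeric(1))
  if (!anyNA(inst)) slices <- slices[order(inst)]
  slices
}

#' Slice a NIfTI volume + mask pair into 2-D records
#'
#' Reads image and mask volumes with RNifti, slices them along the third
#' axis and returns per-slice image/mask matrices (image min-max
#' normalized per slice, masks binarized at > 0).
#'
#' @param imagePath NIfTI image volume.
#' @param liverPath NIfTI liver (or merged) mask volume.
#' @param tumorPath optional NIfTI tumor mask volume.
#' @return list of lists with `image`, `liverMask`, `tumorMask`.
#' @export
readNiftiPair <- function(imagePath, liverPath, tumorPath = NULL) {
  vol <- as.array(RNifti::readNifti(imagePath))
  liv <- as.array(RNifti::readNifti(liverPath))
  tum <- if (!is.null(tumorPath)) as.array(RNifti::readNifti(tumorPath))
  if (!all(dim(vol) == dim(liv))) stop("image/mask dimension mismatch")
  lapply(seq_len(dim(vol)[3]), function(k) {
    sl <- vol[, , k]
    rng <- range(sl)
    list(image = if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0,
         liverMask = (liv[, , k] > 0) * 1,
         tumorMask = if (is.null(tum)) matrix(0, nrow(sl), ncol(sl))
                     else (tum[, , k] > 0) * 1)
  })
}
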