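#' Confusion counts of predicted vs true labels
#'
#' @param predLabels,trueLabels vectors of equal length.
#' @param positiveClass the label counted as positive (e.g. "malignant").
#' @return a [ConfusionCounts-class] with tp + tn + fp + fn = n.
#' @export
confusion <- function(predLabels, trueLabels, positiveClass = "malignant") {
  if (length(predLabels) != length(trueLabels))
    stop("length mismatch in confusion")
  p <- predLabels == positiveClass; y <- trueLabels == positiveClass
  new("ConfusionCounts",
      tp = sum(p & y), tn = sum(!p & !y), fp = sum(p & !y), fn = sum(!p & y))
}

.rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/n, precision TP/(TP+FP), recall (sensitivity)
#' TP/(TP+FN), specificity TN/(TN+FP) and F1 = 2*PRE*REC/(PRE+REC). A
#' metric with a zero denominator is reported as NA with a warning
#' rather than forced to 0 or 1.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricRecord-class] (jsi, dc, auc absent).
#' @export
classificationMetrics <- function(counts) {
  validObject(counts)
  n <- counts@tp + counts@tn + counts@fp + counts@fn
  if (n == 0) stop("no items to evaluate")
  pre <- .rate(counts@tp, counts@tp + counts@fp)
  rec <- .rate(counts@tp, counts@tp + counts@fn)
  spe <- .rate(counts@tn, counts@tn + counts@fp)
  f1 <- if (is.na(pre) || is.na(rec) || pre + rec == 0) NA_real_
        else 2 * pre * rec / (pre + rec)
  if (anyNA(c(pre, rec, spe, f1)))
    warning("degenerate denominator: some metrics reported as NA")
  new("MetricRecord", jsi = NA_real_, dc = NA_real_,
      acc = (counts@tp + counts@tn) / n, pre = pre, rec = rec, spe = spe,
      f1 = f1, auc = NA_real_)
}

#' Segmentation metrics of a predicted vs a reference mask
#'
#' Jaccard similarity |A∩B| / |A∪B|, Dice 2|A∩B| / (|A| + |B|), and
#' pixel-level accuracy / precision / recall / specificity / F1 from the
#' pixel confusion counts.
#'
#' @param predMask,trueMask binary matrices of identical shape.
#' @return a [MetricRecord-class] (auc absent).
#' @export
segmentationMetrics <- function(predMask, trueMask) {
  if (!all(dim(predMask) == dim(trueMask)))
    stop("shape mismatch in segmentationMetrics")
  a <- predMask != 0; b <- trueMask != 0
  inter <- sum(a & b); uni <- sum(a | b)
  jsi <- .rate(inter, uni)
  dc <- .rate(2 * inter, sum(a) + sum(b))
  cc <- new("ConfusionCounts", tp = inter, tn = sum(!a & !b),
            fp = sum(a & !b), fn = sum(!a & b))
  cm <- suppressWarnings(classificationMetrics(cc))
  cm@jsi <- jsi; cm@dc <- dc
  cm
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (ties count 1/2),
#' which equals the trapezoidal area under the ROC curve over all
#' thresholds.
#'
#' @param scores numeric scores, larger = more positive.
#' @param trueLabels labels; `positiveClass` marks the positive class.
#' @param positiveClass label value counted as positive.
#' @return scalar in [0, 1].
#' @export
aucScore <- function(scores, trueLabels, positiveClass = "malignant") {
  y <- trueLabels == positiveClass
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0 || nNeg == 0)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' 95th-percentile symmetric boundary (Hausdorff) distance, in pixels
#'
#' Boundary pixels are foreground pixels with a 4-neighbor outside the
#' mask (or on the image border); for each boundary pixel of one mask
#' the Euclidean distance to the nearest boundary pixel of the other is
#' taken, and HD95 is the 95th percentile of the pooled symmetric
#' distances. An optional metric; identical masks give 0 and the measure
#' is symmetric in its arguments.
#'
#' @param predMask,trueMask nonempty binary matrices of identical shape.
#' @param percentile quantile of the distance distribution (default 0.95).
#' @return non-negative scalar (pixels).
#' @export
hd95 <- function(predMask, trueMask, percentile = 0.95) {
  if (!all(dim(predMask) == dim(trueMask))) stop("shape mismatch in hd95")
  if (sum(predMask) == 0 || sum(trueMask) == 0)
    stop("hd95 requires nonempty masks")
  ba <- .boundary(predMask); bb <- .boundary(trueMask)
  da <- .nnDist(ba, bb); db <- .nnDist(bb, ba)
  as.numeric(quantile(c(da, db), percentile, type = 7))
}

.boundary <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)] & pad[1:H, 2:(W + 1)] &
    pad[3:(H + 2), 2:(W + 1)] & pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !inner, arr.ind = TRUE)
}

.nnDist <- function(from, to) {
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Write an evaluation report CSV (one row per experiment plus a Mean row)
#'
#' Layout `"segmentation"` writes columns Exp, JSI, DC, ACC, REC, PRE;
#' layout `"classification"` writes Exp, ACC, PRE, REC, SPE, F1, AUC.
#' Values are means over NA-free entries, scaled to percent.
#'
#' @param records list of [MetricRecord-class], one per experiment/fold.
#' @param path output CSV path.
#' @param layout "segmentation" or "classification".
#' @return the written data.frame, invisibly.
#' @export
writeEvaluationReport <- function(records, path,
                                  layout = c("segmentation", "classification")) {
  layout <- match.arg(layout)
  cols <- if (layout == "segmentation") c("jsi", "dc", "acc", "rec", "pre")
          else c("acc", "pre", "rec", "spe", "f1", "auc")
  tab <- do.call(rbind, lapply(records, function(r)
    vapply(cols, function(cl) slot(r, cl) * 100, numeric(1))))
  df <- data.frame(Exp = as.character(seq_along(records)), round(tab, 2),
                   check.names = FALSE)
  names(df) <- c("Exp", toupper(cols))
  meanRow <- data.frame(Exp = "Mean",
                        t(round(colMeans(tab, na.rm = TRUE), 2)),
                        check.names = FALSE)
  names(meanRow) <- names(df)
  df <- rbind(df, meanRow)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

setMethod("show", "MetricRecord", function(object) {
  v <- vapply(c("jsi", "dc", "acc", "pre", "rec", "spe", "f1", "auc"),
              function(s) slot(object, s), numeric(1))
  cat("MetricRecord:\n")
  print(round(v, 4))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})
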