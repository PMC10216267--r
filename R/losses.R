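#' Loss configuration for segmentation training
#'
#' The segmentation loss is `BCE + alpha * diceTerm`. With
#' `diceAsLoss = TRUE` (the default) the Dice term is `1 - DC`, so a
#' better overlap lowers the loss; setting it to `FALSE` adds the Dice
#' similarity itself, reproducing the literal printed combination (which
#' rewards bad masks and is provided only for comparison).
#'
#' @param alpha Dice mixing weight (default 0.2).
#' @param diceAsLoss use `1 - DC` as the Dice term (default TRUE).
#' @param smooth small constant added to the soft-Dice numerator and
#'   denominator to keep empty-mask cases finite.
#' @return a list of class "LossConfig".
#' @export
lossConfig <- function(alpha = 0.2, diceAsLoss = TRUE, smooth = 1e-6) {
  stopifnot(alpha >= 0, smooth > 0)
  structure(list(alpha = alpha, diceAsLoss = diceAsLoss, smooth = smooth),
            class = "LossConfig")
}

.clampProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy (negative mean form)
#'
#' `-mean(y * log(p) + (1 - y) * log(1 - p))` with predictions clamped
#' away from 0 and 1 by machine epsilon, so the value is always finite
#' and is 0 exactly when the prediction equals a binary target.
#'
#' @param pred predicted probabilities, any shape.
#' @param target binary targets, same shape.
#' @return non-negative scalar.
#' @examples
#' bce(0.5, 1)  # log(2)
#' @export
bce <- function(pred, target) {
  if (length(pred) != length(target)) stop("shape mismatch in bce")
  p <- .clampProb(as.numeric(pred)); y <- as.numeric(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice coefficient of two masks (soft or hard)
#'
#' `(2|X∩Y| + s) / (|X| + |Y| + s)`. For binary masks this is the usual
#' Dice similarity (1 for identical nonempty masks, 0 for disjoint ones);
#' probability-valued inputs give the soft Dice used inside the training
#' loss, with intersection `sum(pred * target)`.
#'
#' @param pred,target masks (binary) or probability maps, same shape.
#' @param smooth smoothing constant (default 1e-6; governs the
#'   both-empty case).
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(pred, target, smooth = 1e-6) {
  if (length(pred) != length(target)) stop("shape mismatch in diceCoefficient")
  p <- as.numeric(pred); y <- as.numeric(target)
  (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' Combined segmentation loss: BCE plus weighted Dice term
#'
#' `bce(pred, target) + alpha * diceTerm`, where `diceTerm` is
#' `1 - diceCoefficient(pred, target)` under the default configuration.
#'
#' @param pred predicted probabilities.
#' @param target binary targets, same shape.
#' @param cfg a [lossConfig()].
#' @return scalar loss.
#' @export
combinedLoss <- function(pred, target, cfg = lossConfig()) {
  d <- diceCoefficient(pred, target, cfg$smooth)
  term <- if (cfg$diceAsLoss) 1 - d else d
  bce(pred, target) + cfg$alpha * term
}

## Loss and gradient at the sigmoid logits, for the training loop.
## dBCE/dlogit = (p - y)/n; soft-Dice gradient composed with the sigmoid
## derivative p(1-p).
.combinedLossGrad <- function(probs, target, cfg = lossConfig()) {
  p <- as.numeric(probs); y <- as.numeric(target); n <- length(p)
  num <- 2 * sum(p * y) + cfg$smooth
  den <- sum(p) + sum(y) + cfg$smooth
  d <- num / den
  term <- if (cfg$diceAsLoss) 1 - d else d
  loss <- bce(p, y) + cfg$alpha * term
  dD.dp <- (2 * y * den - num) / den^2
  sgn <- if (cfg$diceAsLoss) -1 else 1
  dlogit <- (p - y) / n + cfg$alpha * sgn * dD.dp * p * (1 - p)
  list(loss = loss, dlogits = array(dlogit, dim(probs)))
}

#' Empirical cross-entropy risk of a classification minibatch
#'
#' `-(1/Z) * sum_n sum_m y[n, m] * log(yhat[n, m])` over an N x M matrix
#' of predicted class probabilities and one-hot truths. The default
#' normalization constant Z is the class count M (kept literal to the
#' minibatch risk the staged trainer minimizes); `normalize = "samples"`
#' uses N instead.
#'
#' @param predProbs N x M matrix, rows summing to 1 (tolerance 1e-6).
#' @param truth N x M one-hot matrix.
#' @param normalize "classes" (divide by M, default) or "samples"
#'   (divide by N).
#' @return non-negative scalar; 0 iff every row puts probability 1 on
#'   the true class.
#' @export
crossEntropyRisk <- function(predProbs, truth,
                             normalize = c("classes", "samples")) {
  normalize <- match.arg(normalize)
  predProbs <- as.matrix(predProbs); truth <- as.matrix(truth)
  if (!all(dim(predProbs) == dim(truth)))
    stop("shape mismatch in crossEntropyRisk")
  if (any(abs(rowSums(predProbs) - 1) > 1e-6))
    stop("prediction rows must sum to 1")
  if (!all(truth %in% c(0, 1)) || any(rowSums(truth) != 1))
    stop("truth must be one-hot")
  z <- if (normalize == "classes") ncol(truth) else nrow(truth)
  -sum(truth * log(.clampProb(predProbs))) / z
}
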