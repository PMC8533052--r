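# Training objective (joint Dice + binary cross-entropy) and the
# Dice / sensitivity / Jaccard evaluation metrics with paired
# significance testing.

checkSameShape <- function(X, Y) {
  if (!identical(dim(as4d(X)), dim(as4d(Y))))
    stop("prediction and target shapes differ: ",
         paste(dim(X), collapse = "x"), " vs ",
         paste(dim(Y), collapse = "x"))
}

#' Dice loss
#'
#' `1 - (2 * sum(X*Y) + eps) / (sum(X) + sum(Y) + eps)` with smoothing
#' `eps = 1e-6` so the empty-mask case is defined. For a batch the loss
#' is the mean of per-sample Dice losses. Differentiable in `X`.
#'
#' @param X predicted probability map, values in \[0, 1\].
#' @param Y binary ground-truth mask of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @examples
#' Y <- matrix(rbinom(64, 1, 0.3), 8)
#' diceLoss(Y, Y)   # ~0
#' @export
diceLoss <- function(X, Y, eps = 1e-6) {
  checkSameShape(X, Y)
  X <- as4d(X); Y <- as4d(Y)
  n <- dim(X)[4]
  v <- 0
  for (s in seq_len(n)) {
    xs <- X[, , , s]; ys <- Y[, , , s]
    v <- v + 1 - (2 * sum(xs * ys) + eps) / (sum(xs) + sum(ys) + eps)
  }
  v / n
}

# gradient of diceLoss w.r.t. X
diceLossGrad <- function(X, Y, eps = 1e-6) {
  X <- as4d(X); Y <- as4d(Y)
  n <- dim(X)[4]
  g <- array(0, dim(X))
  for (s in seq_len(n)) {
    xs <- X[, , , s, drop = FALSE]; ys <- Y[, , , s, drop = FALSE]
    num <- 2 * sum(xs * ys) + eps
    den <- sum(xs) + sum(ys) + eps
    g[, , , s] <- (-2 * ys * den + num) / den^2 / n
  }
  g
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(Y log X + (1 - Y) log(1 - X))`, with `X`
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @inheritParams diceLoss
#' @return non-negative scalar.
#' @examples
#' bceLoss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4))  # log(2)
#' @export
bceLoss <- function(X, Y) {
  checkSameShape(X, Y)
  Xc <- pmin(pmax(X, 1e-7), 1 - 1e-7)
  -mean(Y * log(Xc) + (1 - Y) * log(1 - Xc))
}

#' Joint segmentation loss
#'
#' The training objective for real-labeled data: the exact sum
#' `diceLoss(X, Y) + bceLoss(X, Y)`, unweighted.
#'
#' @inheritParams diceLoss
#' @export
jointLoss <- function(X, Y) diceLoss(X, Y) + bceLoss(X, Y)

# d(jointLoss)/d(logits z) where X = sigmoid(z); BCE mean reduction.
jointLossGradLogits <- function(X, Y) {
  dDice <- diceLossGrad(X, Y) * X * (1 - X)
  dBce <- (X - Y) / length(X)
  dDice + dBce
}

#' Pixel confusion counts
#'
#' @param pred,gt binary H x W masks (values in \{0, 1\}).
#' @return named integer vector TP, FP, FN, TN summing to `H * W`.
#' @examples
#' confusionCounts(matrix(c(1, 1, 1, 0), 2), matrix(c(1, 1, 0, 1), 2))
#' @export
confusionCounts <- function(pred, gt) {
  checkSameShape(pred, gt)
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusionCounts expects strictly binary masks")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  c(TP = tp, FP = fp, FN = fn, TN = length(pred) - tp - fp - fn)
}

#' Dice, sensitivity and Jaccard coefficients (percent)
#'
#' Binarizes the probability map at `threshold`, counts pixel
#' confusions and returns `DSC = 2TP/(FP + 2TP + FN)`,
#' `SEN = TP/(TP + FN)`, `JSC = TP/(FP + TP + FN)`, each times 100.
#' When a denominator is zero the metric is 100 if both masks are empty
#' (vacuously perfect) and 0 otherwise.
#'
#' @param prob probability map in \[0, 1\] (or an already binary mask).
#' @param gt binary ground-truth mask.
#' @param threshold binarization cut in (0, 1).
#' @return named numeric vector (DSC, SEN, JSC) in \[0, 100\].
#' @export
segmentationMetrics <- function(prob, gt, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  pred <- (prob >= threshold) * 1
  cc <- confusionCounts(pred, gt)
  safe <- function(num, den) {
    if (den == 0) { if (sum(pred) == 0 && sum(gt) == 0) 100 else 0 }
    else 100 * num / den
  }
  c(DSC = safe(2 * cc[["TP"]], cc[["FP"]] + 2 * cc[["TP"]] + cc[["FN"]]),
    SEN = safe(cc[["TP"]], cc[["TP"]] + cc[["FN"]]),
    JSC = safe(cc[["TP"]], cc[["FP"]] + cc[["TP"]] + cc[["FN"]]))
}

#' Two-sided paired t-test
#'
#' Wrapper around [stats::t.test()] with the degenerate conventions
#' used when comparing per-fold metrics: if every paired difference is
#' exactly zero the p-value is 1; if the differences have zero variance
#' but nonzero mean (infinite t) the smallest representable positive
#' value is returned.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return two-sided p-value.
#' @examples
#' pairedTTest(c(90, 91, 92, 93), c(90.5, 91.2, 92.8, 93.1))
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b))
    stop("paired t-test needs equal-length vectors")
  if (length(a) < 2) stop("paired t-test needs n >= 2")
  d <- a - b
  if (all(d == 0)) return(1.0)
  if (sd(d) == 0) return(.Machine$double.xmin)
  t.test(a, b, paired = TRUE)$p.value
}
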