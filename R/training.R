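# Supervised training (Adam on the joint Dice + BCE loss), model
# checkpointing, evaluation and the k-fold cross-validation harness.

# recursive walk over parallel nested lists of numeric leaves
mapLeaves <- function(f, a, b = NULL, c = NULL, d = NULL) {
  if (!is.list(a)) return(f(a, b, c, d))
  out <- a
  for (nm in names(a))
    out[[nm]] <- mapLeaves(f, a[[nm]],
                           if (is.null(b)) NULL else b[[nm]],
                           if (is.null(c)) NULL else c[[nm]],
                           if (is.null(d)) NULL else d[[nm]])
  out
}

zeroLike <- function(p) mapLeaves(function(x, ...) x * 0, p)

adamInit <- function(params)
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)

# Adam with L2 weight decay folded into the gradient
adamStep <- function(params, grads, opt, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  opt$m <- mapLeaves(function(m, g, p, ...) beta1 * m +
                       (1 - beta1) * (g + weightDecay * p),
                     opt$m, grads, params)
  opt$v <- mapLeaves(function(v, g, p, ...) {
    gd <- g + weightDecay * p
    beta2 * v + (1 - beta2) * gd * gd
  }, opt$v, grads, params)
  params <- mapLeaves(function(p, m, v, ...)
    p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, opt$m, opt$v)
  list(params = params, opt = opt)
}

#' Save / load a model checkpoint
#'
#' @param model an [MFNet-class].
#' @param path checkpoint file (RDS).
#' @return `loadModel` returns the model; a file that does not contain
#'   an MF-Net model raises a checkpoint error.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "MFNet")) stop("checkpoint at ", path,
                            " does not contain an MFNet model")
  m
}

assembleBatch <- function(samples) {
  list(x = tensorFromSamples(samples), y = maskTensor(samples))
}

#' Train MF-Net on labeled samples
#'
#' Adam on the joint Dice + BCE objective. Weight initialization and
#' epoch shuffling are seeded from `config@seed`, so two runs with the
#' same configuration and data are identical. When validation samples
#' are given the returned model is the epoch checkpoint with the best
#' validation DSC; otherwise the final epoch.
#'
#' @param config a [TrainConfig-class].
#' @param trainSamples list of [OCTSample-class] with real labels.
#' @param valSamples optional labeled validation samples.
#' @param checkpointPath optional path to write the best checkpoint.
#' @param model optional warm-start model (default: fresh
#'   initialization from `config@network`).
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (data.frame epoch/trainLoss/
#'   valDSC) and `checkpoint` (path or NA).
#' @export
trainSupervised <- function(config, trainSamples, valSamples = NULL,
                            checkpointPath = NULL, model = NULL,
                            verbose = FALSE) {
  bad <- vapply(trainSamples, function(s) s@provenance != "real_label",
                logical(1))
  if (any(bad))
    stop("training sample(s) without real labels: ",
         paste(vapply(trainSamples[bad], function(s) s@id, ""),
               collapse = ", "))
  fit <- fitLoop(config, trainSamples, valSamples, model = model,
                 verbose = verbose)
  ckpt <- NA_character_
  if (!is.null(checkpointPath)) {
    saveModel(fit$model, checkpointPath)
    ckpt <- checkpointPath
  }
  list(model = fit$model, history = fit$history, checkpoint = ckpt)
}

# core seeded loop; lossWeights gives each sample's weight in the
# batch objective (NULL = uniform joint loss)
fitLoop <- function(config, samples, valSamples = NULL, model = NULL,
                    lossWeights = NULL, verbose = FALSE,
                    epochs = config@epochs) {
  set.seed(config@seed)
  if (is.null(model)) model <- mfNet(config@network)
  opt <- adamInit(model@params)
  n <- length(samples)
  bs <- min(config@batchSize, n)
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valDSC = numeric(0))
  best <- list(dsc = -Inf, model = model)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (b0 in seq(1, n, by = bs)) {
      sel <- ord[b0:min(b0 + bs - 1, n)]
      batch <- assembleBatch(samples[sel])
      out <- netFwd(model, batch$x, training = TRUE)
      model@state <- out$state
      if (is.null(lossWeights)) {
        loss <- jointLoss(out$prob, batch$y)
        dz <- jointLossGradLogits(out$prob, batch$y)
      } else {
        wl <- weightedBatchLoss(out$prob, batch$y, lossWeights[sel])
        loss <- wl$loss
        dz <- wl$dz
      }
      grads <- netBwd(model, out$cache, dz)
      stepped <- adamStep(model@params, grads, opt, config@lr,
                          config@weightDecay)
      model@params <- stepped$params
      opt <- stepped$opt
      losses <- c(losses, loss)
    }
    valDSC <- NA_real_
    if (!is.null(valSamples)) {
      rep <- evaluateModel(model, valSamples)
      valDSC <- rep@mean[["DSC"]]
      if (valDSC > best$dsc) best <- list(dsc = valDSC, model = model)
    }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                   valDSC = valDSC))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f%s", ep, mean(losses),
                      if (is.na(valDSC)) ""
                      else sprintf(", val DSC %.2f", valDSC)))
  }
  list(model = if (is.finite(best$dsc)) best$model else model,
       history = hist)
}

# per-sample weighted joint loss, normalized by the batch size:
# L = (1/n) * sum_s w_s * (dice_s + bce_s); with all w_s = 1 this is
# exactly the uniform batch joint loss.
weightedBatchLoss <- function(prob, Y, w) {
  d <- dim(prob)
  n <- d[4]
  loss <- 0
  dz <- array(0, d)
  npix <- prod(d[1:3])
  for (s in seq_len(n)) {
    xs <- prob[, , , s, drop = FALSE]
    ys <- Y[, , , s, drop = FALSE]
    loss <- loss + w[s] / n * (diceLoss(xs, ys) + bceLoss(xs, ys))
    dzs <- diceLossGrad(xs, ys) * xs * (1 - xs) + (xs - ys) / npix
    dz[, , , s] <- w[s] / n * dzs
  }
  list(loss = loss, dz = dz)
}

#' Evaluate a model on labeled samples
#'
#' Deterministic forward passes in evaluation mode; per-image DSC, SEN
#' and JSC at the given threshold, aggregated as mean and sample SD.
#'
#' @param model an [MFNet-class] (or a checkpoint path).
#' @param samples labeled [OCTSample-class] list.
#' @param threshold binarization threshold.
#' @param foldId optional fold label stored in the report.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, samples, threshold = 0.5,
                          foldId = NA_integer_) {
  if (is.character(model)) model <- loadModel(model)
  if (any(vapply(samples, function(s) is.null(s@mask), logical(1))))
    stop("evaluation requires ground-truth masks for every sample")
  n <- length(samples)
  per <- data.frame(id = vapply(samples, function(s) s@id, ""),
                    DSC = numeric(n), SEN = numeric(n), JSC = numeric(n),
                    stringsAsFactors = FALSE)
  for (b0 in seq(1, n, by = 8)) {
    sel <- b0:min(b0 + 7, n)
    x <- tensorFromSamples(samples[sel])
    prob <- netFwd(model, x, training = FALSE, keepCache = FALSE)$prob
    for (j in seq_along(sel)) {
      m <- segmentationMetrics(prob[, , 1, j], samples[[sel[j]]]@mask,
                               threshold)
      per[sel[j], c("DSC", "SEN", "JSC")] <- as.list(m)
    }
  }
  mu <- c(DSC = mean(per$DSC), SEN = mean(per$SEN), JSC = mean(per$JSC))
  sdv <- c(DSC = sd(per$DSC), SEN = sd(per$SEN), JSC = sd(per$JSC))
  if (n < 2) sdv <- c(DSC = 0, SEN = 0, JSC = 0)
  new("MetricsReport", perImage = per, mean = mu, sd = sdv,
      foldId = as.integer(foldId))
}

#' k-fold cross-validation
#'
#' Samples are split with [makeFolds()]; for each fold the network is
#' trained from scratch on the remaining folds (a fraction of the
#' training part is held out for best-checkpoint selection) and
#' evaluated on the held-out fold. Per-fold metric vectors are suitable
#' for [pairedTTest()] comparisons between methods.
#'
#' @param config a [TrainConfig-class].
#' @param samples labeled samples.
#' @param k number of folds.
#' @param valFraction fraction of the training part reserved for
#'   checkpoint selection (0 disables and keeps the final epoch).
#' @param outDir optional directory for per-image CSVs
#'   (`fold<i>_metrics.csv`).
#' @param verbose print epoch lines.
#' @return list of [MetricsReport-class], one per fold, with attribute
#'   `"summary"`: mean and sample SD across folds per metric.
#' @export
crossValidate <- function(config, samples, k = 4L, valFraction = 0.15,
                          outDir = NULL, verbose = FALSE) {
  if (k > length(samples)) stop("k exceeds the dataset size")
  ids <- vapply(samples, function(s) s@id, "")
  split <- makeFolds(ids, k = k, seed = config@seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(split@assignments[ids] == f)
    trainIdx <- setdiff(seq_along(samples), testIdx)
    nVal <- floor(length(trainIdx) * valFraction)
    valIdx <- if (nVal > 0) tail(trainIdx, nVal) else integer(0)
    trIdx <- setdiff(trainIdx, valIdx)
    fit <- trainSupervised(config, samples[trIdx],
                           valSamples = if (nVal > 0) samples[valIdx],
                           verbose = verbose)
    reports[[f]] <- evaluateModel(fit$model, samples[testIdx],
                                  foldId = f)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      write.csv(reports[[f]]@perImage,
                file.path(outDir, sprintf("fold%d_metrics.csv", f)),
                row.names = FALSE)
    }
  }
  perFold <- t(vapply(reports, function(r) r@mean, numeric(3)))
  attr(reports, "summary") <- list(mean = colMeans(perFold),
                                   sd = apply(perFold, 2, sd),
                                   perFold = perFold)
  reports
}
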