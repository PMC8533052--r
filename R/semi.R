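# SemiMF-Net: three-step pseudo-label pipeline. (1) pre-train MF-Net
# on the limited labeled data; (2) predict masks for the unlabeled
# images and keep them as pseudo-labels; (3) re-train on the pooled
# set under L_pseudo + beta * L_real.

#' Pseudo-labeled samples produced by a pre-trained model
#'
#' @slot samples list of [OCTSample-class], all with provenance
#'   `"pseudo_label"` and binary masks.
#' @slot threshold probability cut used for binarization.
#' @slot source identifier of the generating checkpoint/model.
#' @exportClass PseudoSet
setClass("PseudoSet",
  representation(samples = "list", threshold = "numeric",
                 source = "character"))

setMethod("show", "PseudoSet", function(object) {
  cat(sprintf("PseudoSet: %d pseudo-labeled samples (threshold %.2f)\n",
              length(object@samples), object@threshold))
})

#' Attach model predictions to unlabeled images as pseudo-labels
#'
#' Every unlabeled image is forwarded through the model and the
#' probability map binarized at `threshold`; no confidence filtering is
#' applied. Passing a sample that already carries a label is an error.
#'
#' @param model pre-trained [MFNet-class] (or checkpoint path).
#' @param unlabeled list of [OCTSample-class] with provenance
#'   `"unlabeled"`.
#' @param threshold binarization cut.
#' @param source label recorded for the generating model.
#' @return a [PseudoSet-class] of the same size as `unlabeled`.
#' @export
generatePseudoLabels <- function(model, unlabeled, threshold = 0.5,
                                 source = "pretrained") {
  if (is.character(model)) {
    source <- model
    model <- loadModel(model)
  }
  bad <- vapply(unlabeled, function(s) s@provenance != "unlabeled",
                logical(1))
  if (any(bad))
    stop("labeled sample(s) passed as unlabeled: ",
         paste(vapply(unlabeled[bad], function(s) s@id, ""),
               collapse = ", "))
  out <- vector("list", length(unlabeled))
  for (b0 in seq_len(ceiling(length(unlabeled) / 8)) * 8 - 7) {
    sel <- b0:min(b0 + 7, length(unlabeled))
    x <- tensorFromSamples(unlabeled[sel])
    prob <- netFwd(model, x, training = FALSE, keepCache = FALSE)$prob
    for (j in seq_along(sel)) {
      s <- unlabeled[[sel[j]]]
      out[[sel[j]]] <- octSample(image = s@image,
                                 mask = (prob[, , 1, j] >= threshold) * 1,
                                 id = s@id, provenance = "pseudo_label")
    }
  }
  new("PseudoSet", samples = out, threshold = threshold, source = source)
}

#' Semi-supervised objective
#'
#' Combines the per-provenance loss components as
#' `L_pseudo + beta * L_real`, where each component is the joint
#' Dice + BCE loss averaged over that provenance's samples in the
#' batch; a batch missing one provenance contributes 0 for it.
#'
#' @param lossPseudo,lossReal batch-mean joint losses per provenance
#'   (0 when the provenance is absent from the batch).
#' @param beta weight of the real-label component (>= 0).
#' @return scalar objective.
#' @export
semiObjective <- function(lossPseudo, lossReal, beta = 1.0) {
  if (beta < 0) stop("beta must be >= 0")
  lossPseudo + beta * lossReal
}

#' Full SemiMF-Net training pipeline
#'
#' Step 1 pre-trains MF-Net on the labeled set; step 2 pseudo-labels
#' the unlabeled images; step 3 re-trains (warm start by default) on
#' the pooled set. During retraining each sample contributes its joint
#' loss to the batch objective with weight 1 (pseudo) or `beta` (real),
#' normalized by the batch size, so with `beta = 1` the pooled
#' objective is the uniform mean joint loss over all samples.
#'
#' @param config a [TrainConfig-class] (`beta`, `pseudoThreshold` used
#'   here).
#' @param labeled list of real-labeled samples (non-empty).
#' @param unlabeled list of unlabeled samples (may be empty, in which
#'   case the procedure degenerates to two supervised phases).
#' @param valSamples optional labeled validation samples for checkpoint
#'   selection in both phases.
#' @param retrainEpochs epochs for the pooled phase (default:
#'   `config@epochs`).
#' @param warmStart start retraining from the pre-trained weights
#'   (FALSE re-initializes).
#' @param verbose print epoch lines.
#' @return list with `model` (final), `pretrained` (step-1 model),
#'   `pseudo` (the [PseudoSet-class]) and the two histories.
#' @export
trainSemi <- function(config, labeled, unlabeled, valSamples = NULL,
                      retrainEpochs = config@epochs, warmStart = TRUE,
                      verbose = FALSE) {
  if (length(labeled) == 0L) stop("labeled set must not be empty")
  pre <- trainSupervised(config, labeled, valSamples = valSamples,
                         verbose = verbose)
  ps <- generatePseudoLabels(pre$model, unlabeled,
                             threshold = config@pseudoThreshold)
  pooled <- c(ps@samples, labeled)
  weights <- c(rep(1, length(ps@samples)),
               rep(config@beta, length(labeled)))
  fit <- fitLoop(config, pooled,
                 valSamples = valSamples,
                 model = if (warmStart) pre$model else NULL,
                 lossWeights = weights,
                 verbose = verbose, epochs = retrainEpochs)
  list(model = fit$model, pretrained = pre$model, pseudo = ps,
       historyPretrain = pre$history, historyRetrain = fit$history)
}
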