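setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Network architecture configuration
#'
#' Describes an MF-Net instance: input channels, width of the first
#' encoder stage (doubled at each of the four stages), the two ablation
#' switches, and the spatial input size. `useMAD` inserts the
#' multi-scale adaptive-aware deformation module after Encoder 4;
#' `useSDA` inserts the two semantics--details aggregation skip modules.
#' With both off the network is the plain encoder--decoder backbone.
#'
#' @slot inChannels integer, image channels (1 for grayscale B-scans).
#' @slot baseChannels integer, channels of Encoder 1; must be divisible
#'   by 4 because the MAD dilated branches squeeze to a quarter width.
#' @slot useMAD,useSDA logical ablation switches.
#' @slot inputSize integer(2), (H, W); both divisible by 16 (four 2x
#'   poolings).
#' @exportClass MFNetConfig
setClass("MFNetConfig",
  representation(inChannels = "integer", baseChannels = "integer",
                 useMAD = "logical", useSDA = "logical",
                 inputSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@baseChannels %% 4L != 0L)
      msg <- c(msg, "baseChannels must be divisible by 4")
    if (length(object@inputSize) != 2L)
      msg <- c(msg, "inputSize must be length 2 (H, W)")
    bad <- which(object@inputSize %% 16L != 0L)
    if (length(bad))
      msg <- c(msg, paste0("inputSize axis ", c("H", "W")[bad][1L],
                           " (= ", object@inputSize[bad][1L],
                           ") is not divisible by 16"))
    if (is.null(msg)) TRUE else msg
  })

#' @param inChannels,baseChannels,useMAD,useSDA,inputSize see slots.
#' @return an [MFNetConfig-class] object.
#' @rdname MFNetConfig-class
#' @examples
#' mfNetConfig(baseChannels = 16, inputSize = c(128, 128))
#' @export
mfNetConfig <- function(inChannels = 1L, baseChannels = 64L, useMAD = TRUE,
                        useSDA = TRUE, inputSize = c(256L, 256L)) {
  new("MFNetConfig", inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels), useMAD = useMAD,
      useSDA = useSDA, inputSize = as.integer(inputSize))
}

#' An MF-Net model: configuration, parameters, batch-norm state
#'
#' Parameters live in a nested named list mirroring the architecture
#' (`enc1$conv1$W`, `mad$deform$W`, ...); `state` carries the batch-norm
#' running means/variances updated during training and used at
#' evaluation time. Use [mfNet()] to construct a freshly initialized
#' model and [nParams()] for the trainable parameter count.
#'
#' @slot config an [MFNetConfig-class].
#' @slot params nested named list of numeric arrays.
#' @slot state nested named list of batch-norm running statistics.
#' @exportClass MFNet
setClass("MFNet",
  representation(config = "MFNetConfig", params = "list", state = "list"))

#' One OCT B-scan with optional lesion mask
#'
#' @slot image numeric H x W matrix with values in \[0, 1\].
#' @slot mask binary H x W matrix (0/1) or NULL when unannotated.
#' @slot id sample identifier.
#' @slot provenance one of `"real_label"`, `"pseudo_label"`,
#'   `"unlabeled"` -- whether the mask is a human annotation, a model
#'   prediction, or absent.
#' @exportClass OCTSample
setClass("OCTSample",
  representation(image = "matrix", mask = "matrixOrNULL", id = "character",
                 provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@provenance %in% c("real_label", "pseudo_label", "unlabeled"))
      msg <- c(msg, "provenance must be real_label/pseudo_label/unlabeled")
    if (!is.null(object@mask)) {
      if (!identical(dim(object@mask), dim(object@image)))
        msg <- c(msg, "mask dimensions do not match image dimensions")
      if (!all(object@mask %in% c(0, 1)))
        msg <- c(msg, "mask must be strictly binary (0/1)")
    } else if (object@provenance != "unlabeled") {
      msg <- c(msg, "a sample without a mask must be 'unlabeled'")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @param image,mask,id,provenance see slots.
#' @return an [OCTSample-class].
#' @rdname OCTSample-class
#' @export
octSample <- function(image, mask = NULL, id = "sample",
                      provenance = if (is.null(mask)) "unlabeled"
                                   else "real_label") {
  new("OCTSample", image = image, mask = mask, id = as.character(id),
      provenance = provenance)
}

#' Assignment of sample ids to cross-validation folds
#'
#' @slot assignments named integer vector mapping each id to a fold in
#'   `1..k`.
#' @slot k number of folds.
#' @seealso [makeFolds()]
#' @exportClass FoldSplit
setClass("FoldSplit",
  representation(assignments = "integer", k = "integer"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@assignments)))
      msg <- c(msg, "assignments must be named by sample id")
    if (anyDuplicated(names(object@assignments)))
      msg <- c(msg, "each id must be assigned exactly once")
    if (length(object@assignments) &&
        !all(object@assignments %in% seq_len(object@k)))
      msg <- c(msg, "fold indices must lie in 1..k")
    if (is.null(msg)) TRUE else msg
  })

#' Per-image segmentation metrics with fold-level aggregation
#'
#' Metrics are percentages: DSC (Dice similarity coefficient), SEN
#' (sensitivity/recall), JSC (Jaccard similarity coefficient).
#'
#' @slot perImage data.frame with columns id, DSC, SEN, JSC.
#' @slot mean,sd named numeric(3), mean and sample SD of each metric.
#' @slot foldId integer fold label (NA outside cross-validation).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perImage = "data.frame", mean = "numeric", sd = "numeric",
                 foldId = "integer"))

#' Synthetic B-scan generator settings
#'
#' @slot imageSize integer(2) (H, W).
#' @slot nLayers number of retinal bands.
#' @slot lesionAreaFrac numeric(2), (min, max) admissible lesion area as
#'   a fraction of the image.
#' @slot speckleStrength variance of the multiplicative gamma speckle
#'   (0 = noiseless).
#' @slot blurSigma Gaussian sigma (pixels) blurring the lesion boundary.
#' @slot seed integer seed fully determining the sample.
#' @seealso [synthBscan()]
#' @exportClass SynthParams
setClass("SynthParams",
  representation(imageSize = "integer", nLayers = "integer",
                 lesionAreaFrac = "numeric", speckleStrength = "numeric",
                 blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@lesionAreaFrac[1] >= object@lesionAreaFrac[2])
      msg <- c(msg, "lesionAreaFrac must satisfy min < max")
    if (any(object@lesionAreaFrac <= 0) || any(object@lesionAreaFrac >= 1))
      msg <- c(msg, "lesionAreaFrac must lie in (0, 1)")
    if (object@speckleStrength < 0 || object@blurSigma < 0)
      msg <- c(msg, "speckleStrength and blurSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param imageSize,nLayers,lesionAreaFrac,speckleStrength,blurSigma,seed
#'   see slots.
#' @return a [SynthParams-class].
#' @rdname SynthParams-class
#' @export
synthParams <- function(imageSize = c(256L, 256L), nLayers = 5L,
                        lesionAreaFrac = c(0.03, 0.12),
                        speckleStrength = 0.08, blurSigma = 1.5,
                        seed = 0L) {
  new("SynthParams", imageSize = as.integer(imageSize),
      nLayers = as.integer(nLayers), lesionAreaFrac = lesionAreaFrac,
      speckleStrength = speckleStrength, blurSigma = blurSigma,
      seed = as.integer(seed))
}

#' Training hyper-parameters
#'
#' Defaults follow the reference training recipe: Adam with initial
#' learning rate 5e-4, weight decay 1e-4, batch size 4, 50 epochs; the
#' semi-supervised objective weight `beta` defaults to 1 and
#' pseudo-labels are binarized at 0.5.
#'
#' @slot lr,weightDecay Adam learning rate and L2 weight decay.
#' @slot batchSize,epochs mini-batch size and epoch count.
#' @slot seed master seed for weight init and shuffling.
#' @slot device execution device (`"cpu"`; kept for config fidelity).
#' @slot network an [MFNetConfig-class].
#' @slot beta weight of the real-label loss in the semi-supervised
#'   objective L_pseudo + beta * L_real.
#' @slot pseudoThreshold probability cut for pseudo-label binarization.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer",
                 device = "character", network = "MFNetConfig",
                 beta = "numeric", pseudoThreshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param lr,weightDecay,batchSize,epochs,seed,device,network,beta,pseudoThreshold
#'   see slots.
#' @return a [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(lr = 5e-4, weightDecay = 1e-4, batchSize = 4L,
                        epochs = 50L, seed = 0L, device = "cpu",
                        network = mfNetConfig(), beta = 1.0,
                        pseudoThreshold = 0.5) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), device = device, network = network,
      beta = beta, pseudoThreshold = pseudoThreshold)
}
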