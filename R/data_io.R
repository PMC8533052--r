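# Image/mask readers and writers, preprocessing, the k-fold split
# scheme, the overlay renderer and YAML configuration.
#
# On-disk conventions: grayscale PNG/JPEG/TIFF images; 8-bit PNG masks
# with values {0, 255}; predictions as float32 TIFF (probabilities)
# plus binarized PNG. In-memory matrices are H x W (row = image row);
# EBImage's (x, y) layout is transposed at the boundary.

readGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file ", path)
  img <- readImage(path)
  d <- dim(img)
  if (length(d) == 3L) {
    # RGB(A) to luminance
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  t(imageData(img))
}

#' Load an OCT B-scan (and optional mask) from disk
#'
#' Images are scaled to \[0, 1\]; RGB inputs are converted to
#' luminance. Masks are binarized at pixel value 128 on the 0--255
#' scale, so stray intermediate values snap to the nearest class.
#'
#' @param imagePath PNG/JPEG/TIFF image file.
#' @param maskPath optional mask PNG with the same dimensions.
#' @param id sample identifier (default: image file name).
#' @return an [OCTSample-class].
#' @export
loadSample <- function(imagePath, maskPath = NULL,
                       id = tools::file_path_sans_ext(basename(imagePath))) {
  img <- readGray(imagePath)
  mask <- NULL
  if (!is.null(maskPath)) {
    mask <- loadMask(maskPath)
    if (!identical(dim(mask), dim(img)))
      stop("mask dimensions ", paste(dim(mask), collapse = "x"),
           " do not match image dimensions ",
           paste(dim(img), collapse = "x"), " for ", id)
  }
  octSample(image = img, mask = mask, id = id)
}

#' @rdname loadSample
#' @param path mask PNG path.
#' @export
loadMask <- function(path) {
  m <- readGray(path)
  (m >= 128 / 255) * 1
}

#' Write a binary mask as an 8-bit PNG with values \{0, 255\}
#'
#' @param mask binary H x W matrix.
#' @param path output PNG path.
#' @export
saveMask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  writeImage(Image(t(mask)), path)
  invisible(path)
}

#' Save a predicted probability map
#'
#' Writes the raw probabilities as a float32 TIFF and the binarized
#' mask as a \{0, 255\} PNG.
#'
#' @param prob H x W probability matrix in \[0, 1\].
#' @param tiffPath,pngPath output paths (either may be NULL to skip).
#' @param threshold binarization cut for the PNG.
#' @export
savePrediction <- function(prob, tiffPath = NULL, pngPath = NULL,
                           threshold = 0.5) {
  if (!is.null(tiffPath))
    tiff::writeTIFF(prob, tiffPath, bits.per.sample = 32L)
  if (!is.null(pngPath))
    saveMask((prob >= threshold) * 1, pngPath)
  invisible(NULL)
}

#' Resize a sample to the network input size
#'
#' Bilinear for the image, nearest-neighbor for the mask (preserves
#' binarity). A sample already at the target size is returned
#' unchanged, so the operation is idempotent.
#'
#' @param sample an [OCTSample-class].
#' @param targetSize integer(2) (H, W), both divisible by 16.
#' @return resized [OCTSample-class].
#' @export
preprocessSample <- function(sample, targetSize = c(256L, 256L)) {
  targetSize <- as.integer(targetSize)
  bad <- which(targetSize %% 16L != 0L)
  if (length(bad))
    stop("target ", c("height", "width")[bad][1], " (= ",
         targetSize[bad][1], ") is not divisible by 16")
  if (identical(dim(sample@image), targetSize)) return(sample)
  img <- t(imageData(resize(Image(t(sample@image)),
                            w = targetSize[2], h = targetSize[1],
                            filter = "bilinear")))
  img <- pmin(pmax(img, 0), 1)
  mask <- sample@mask
  if (!is.null(mask))
    mask <- t(imageData(resize(Image(t(mask)), w = targetSize[2],
                               h = targetSize[1], filter = "none")))
  octSample(image = img, mask = mask, id = sample@id,
            provenance = sample@provenance)
}

#' Assign sample ids to k cross-validation folds
#'
#' Ids are shuffled with the given seed; folds `1..k-1` receive
#' `floor(N/k)` ids each and fold `k` the remainder. With 1,522 ids and
#' `k = 4` this yields fold sizes (380, 380, 380, 382).
#'
#' @param ids character vector of unique sample ids.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return a [FoldSplit-class].
#' @examples
#' foldSizes(makeFolds(as.character(1:1522), k = 4, seed = 1))
#' @export
makeFolds <- function(ids, k = 4L, seed = 0L) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("empty id list")
  if (k < 2L) stop("k must be >= 2")
  if (length(ids) < k) stop("fewer ids than folds")
  if (anyDuplicated(ids)) stop("ids must be unique")
  N <- length(ids)
  base <- N %/% k
  sizes <- c(rep(base, k - 1L), N - base * (k - 1L))
  perm <- withSeed(seed, sample(ids))
  assign <- rep(seq_len(k), times = sizes)
  out <- integer(N)
  names(out) <- ids
  out[perm] <- assign
  new("FoldSplit", assignments = out, k = as.integer(k))
}

#' Render a prediction/ground-truth overlay
#'
#' Correctly segmented lesion pixels are yellow, false positives red,
#' false negatives blue; everything else shows the grayscale image.
#'
#' @param pred,gt binary H x W masks.
#' @param image grayscale H x W matrix in \[0, 1\].
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
renderOverlay <- function(pred, gt, image) {
  checkSameShape(pred, gt)
  checkSameShape(pred, image)
  rgb <- array(rep(image, 3), c(dim(image), 3))
  tp <- pred == 1 & gt == 1
  fp <- pred == 1 & gt == 0
  fn <- pred == 0 & gt == 1
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[tp] <- 1; g[tp] <- 1; b[tp] <- 0
  r[fp] <- 1; g[fp] <- 0; b[fp] <- 0
  r[fn] <- 0; g[fn] <- 0; b[fn] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  rgb
}

#' Read a training configuration from YAML
#'
#' Recognized keys: `model.{base_channels,use_mad,use_sda,input_size}`,
#' `optim.{lr,weight_decay,batch_size,epochs}`,
#' `semi.{beta,pseudo_threshold}`, `seed`. Missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [TrainConfig-class].
#' @export
readTrainConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(block, key, default)
    if (!is.null(y[[block]][[key]])) y[[block]][[key]] else default
  net <- mfNetConfig(
    baseChannels = pick("model", "base_channels", 64L),
    useMAD = pick("model", "use_mad", TRUE),
    useSDA = pick("model", "use_sda", TRUE),
    inputSize = unlist(pick("model", "input_size", c(256L, 256L))))
  trainConfig(
    lr = pick("optim", "lr", 5e-4),
    weightDecay = pick("optim", "weight_decay", 1e-4),
    batchSize = pick("optim", "batch_size", 4L),
    epochs = pick("optim", "epochs", 50L),
    seed = if (!is.null(y$seed)) y$seed else 0L,
    network = net,
    beta = pick("semi", "beta", 1.0),
    pseudoThreshold = pick("semi", "pseudo_threshold", 0.5))
}
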