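#' Number of trainable parameters
#'
#' @param object an [MFNet-class] model.
#' @return integer count of scalar trainable parameters (batch-norm
#'   running statistics excluded).
#' @examples
#' m <- mfNet(mfNetConfig(baseChannels = 8, inputSize = c(128, 128)))
#' nParams(m)
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @rdname nParams
#' @export
setMethod("nParams", "MFNet", function(object) {
  sum(rapply(object@params, length, how = "unlist"))
})

#' Fold sizes of a cross-validation split
#'
#' @param object a [FoldSplit-class].
#' @return integer vector of length `k` with the number of ids per fold.
#' @export
setGeneric("foldSizes", function(object) standardGeneric("foldSizes"))

#' @rdname foldSizes
#' @export
setMethod("foldSizes", "FoldSplit", function(object) {
  tabulate(object@assignments, nbins = object@k)
})

setMethod("show", "MFNetConfig", function(object) {
  cat("MFNetConfig:", object@inChannels, "-> base", object@baseChannels,
      "channels,", paste(object@inputSize, collapse = "x"), "input\n")
  cat("  MAD:", object@useMAD, "| SDA:", object@useSDA, "\n")
})

setMethod("show", "MFNet", function(object) {
  v <- if (object@config@useMAD && object@config@useSDA) "MF-Net"
       else if (object@config@useMAD) "Backbone+MAD"
       else if (object@config@useSDA) "Backbone+SDA"
       else "Backbone"
  cat(sprintf("%s model: %d trainable parameters, base %d channels\n",
              v, nParams(object), object@config@baseChannels))
})

setMethod("show", "OCTSample", function(object) {
  cat(sprintf("OCTSample '%s': %dx%d, %s%s\n", object@id,
              nrow(object@image), ncol(object@image), object@provenance,
              if (is.null(object@mask)) ", no mask"
              else sprintf(", lesion %.1f%%", 100 * mean(object@mask))))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d ids in %d folds (sizes %s)\n",
              length(object@assignments), object@k,
              paste(foldSizes(object), collapse = ", ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%d images%s):\n", nrow(object@perImage),
              if (is.na(object@foldId)) "" else
                sprintf(", fold %d", object@foldId)))
  for (m in c("DSC", "SEN", "JSC"))
    cat(sprintf("  %s %6.2f +/- %.2f\n", m, object@mean[[m]],
                object@sd[[m]]))
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(paste0("SynthParams: %dx%d, %d bands, lesion area ",
                     "%.1f-%.1f%%, speckle %.2f, blur %.1f px, seed %d\n"),
              object@imageSize[1], object@imageSize[2], object@nLayers,
              100 * object@lesionAreaFrac[1], 100 * object@lesionAreaFrac[2],
              object@speckleStrength, object@blurSigma, object@seed))
})
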