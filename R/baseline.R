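#' Otsu thresholding baseline
#'
#' A deliberately simple reference segmenter: Gaussian-blur the image,
#' threshold it with Otsu's method, and keep the supra-threshold
#' pixels. Because the retinal bands are also hyperreflective this
#' baseline overshoots heavily on OCT-like images; a trained network
#' should beat it by a wide margin.
#'
#' @param samples labeled [OCTSample-class] list.
#' @param sigma Gaussian blur sigma in pixels.
#' @return a [MetricsReport-class].
#' @export
otsuBaseline <- function(samples, sigma = 2) {
  n <- length(samples)
  per <- data.frame(id = vapply(samples, function(s) s@id, ""),
                    DSC = numeric(n), SEN = numeric(n), JSC = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    img <- gblur(Image(t(samples[[i]]@image)), sigma = sigma)
    pred <- t(imageData(img) >= otsu(img)) * 1
    per[i, c("DSC", "SEN", "JSC")] <-
      as.list(segmentationMetrics(pred, samples[[i]]@mask))
  }
  mu <- c(DSC = mean(per$DSC), SEN = mean(per$SEN), JSC = mean(per$JSC))
  sdv <- if (n > 1) c(DSC = sd(per$DSC), SEN = sd(per$SEN),
                      JSC = sd(per$JSC)) else c(DSC = 0, SEN = 0, JSC = 0)
  new("MetricsReport", perImage = per, mean = mu, sd = sdv,
      foldId = NA_integer_)
}
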