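# Seeded generator of OCT-like B-scans: smooth curved hyperreflective
# retinal bands, one irregular bright lesion (random radial polygon,
# Gaussian-blurred boundary) straddling the band region, multiplicative
# gamma speckle. The exact pre-blur polygon raster is the ground-truth
# mask, so the boundary blur emulates the indistinct lesion margins
# seen in real scans while the label stays crisp.

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth periodic curve over columns: sum of low-frequency sinusoids
smoothCurve <- function(w, amplitude) {
  x <- seq(0, 2 * pi, length.out = w)
  f <- numeric(w)
  for (k in 1:3)
    f <- f + rnorm(1, sd = amplitude / k) * sin(k * x + runif(1, 0, 2 * pi))
  f
}

# star-convex polygon raster: radius as a Fourier series in the angle
lesionMask <- function(H, W, cy, cx, r0, wobble = 0.45) {
  nharm <- 4
  a <- rnorm(nharm, sd = wobble / sqrt(1:nharm))
  ph <- runif(nharm, 0, 2 * pi)
  rows <- matrix(seq_len(H), H, W) - cy
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  theta <- atan2(rows, cols)
  rad <- r0 * pmax(0.25, 1 + Reduce(`+`, lapply(1:nharm, function(k)
    a[k] * sin(k * theta + ph[k]))))
  (rows^2 + cols^2 <= rad^2) * 1
}

#' Generate one synthetic OCT-like B-scan with its lesion mask
#'
#' The sample is fully determined by `params@seed`. Layered background
#' bands imitate retinal layers; the lesion is hyperreflective
#' (brighter than every band) so that in the noiseless, unblurred limit
#' it is the unique brightest region. The lesion area is
#' rejection-sampled into the configured fraction band.
#'
#' @param params a [SynthParams-class].
#' @return an [OCTSample-class] with provenance `"real_label"`.
#' @examples
#' s <- synthBscan(synthParams(imageSize = c(128, 128), seed = 3))
#' mean(s@mask)
#' @export
synthBscan <- function(params = synthParams()) {
  validObject(params)
  H <- params@imageSize[1]; W <- params@imageSize[2]
  withSeed(params@seed, {
    nL <- params@nLayers
    # band boundaries from top of retina downwards
    top <- H * runif(1, 0.18, 0.3)
    thick <- H * runif(1, 0.38, 0.5) / nL
    bounds <- matrix(0, nL + 1, W)
    base <- top + smoothCurve(W, H * 0.04) +
      seq(0, 1, length.out = W) * rnorm(1, sd = H * 0.05)
    for (b in 1:(nL + 1)) {
      base <- base + thick * runif(1, 0.7, 1.3)
      bounds[b, ] <- base + smoothCurve(W, H * 0.01)
    }
    bright <- runif(nL, 0.18, 0.55)
    bright[sample(nL, 1)] <- 0.55          # one strongly reflective band
    img <- matrix(0.06, H, W)              # vitreous
    rows <- matrix(seq_len(H), H, W)
    for (b in 1:nL) {
      sel <- rows > matrix(bounds[b, ], H, W, byrow = TRUE) &
             rows <= matrix(bounds[b + 1, ], H, W, byrow = TRUE)
      img[sel] <- bright[b]
    }
    img[rows > matrix(bounds[nL + 1, ], H, W, byrow = TRUE)] <- 0.14  # choroid
    # lesion: rejection-sample the area into the configured band
    lo <- params@lesionAreaFrac[1] * H * W
    hi <- params@lesionAreaFrac[2] * H * W
    mask <- NULL
    for (attempt in 1:300) {
      frac <- runif(1, params@lesionAreaFrac[1], params@lesionAreaFrac[2])
      r0 <- sqrt(frac * H * W / pi)
      if (2.2 * r0 > min(H, W) - 4)
        stop("lesion_area_frac infeasible for image size ",
             H, "x", W)
      cx <- runif(1, 1.3 * r0 + 2, W - 1.3 * r0 - 2)
      bandMid <- (bounds[1, round(cx)] + bounds[nL + 1, round(cx)]) / 2
      cy <- min(max(bandMid + rnorm(1, sd = H * 0.06), 1.3 * r0 + 2),
                H - 1.3 * r0 - 2)
      m <- lesionMask(H, W, cy, cx, r0)
      if (sum(m) >= lo && sum(m) <= hi) { mask <- m; break }
    }
    if (is.null(mask))
      stop("lesion_area_frac infeasible for image size ", H, "x", W)
    edge <- if (params@blurSigma > 0) {
      t(imageData(gblur(Image(t(mask)), sigma = params@blurSigma)))
    } else mask
    edge <- pmin(pmax(edge, 0), 1)
    img <- img * (1 - edge) + 0.88 * edge
    if (params@speckleStrength > 0) {
      v <- params@speckleStrength
      img <- img * matrix(rgamma(H * W, shape = 1 / v, rate = 1 / v), H, W)
    }
    img <- pmin(pmax(img, 0), 1)
    octSample(image = img, mask = mask,
              id = sprintf("synth%06d", params@seed),
              provenance = "real_label")
  })
}

#' Generate a list of synthetic samples in memory
#'
#' Sample `i` uses seed `params@seed + i - 1`, so any contiguous block
#' of seeds is reproducible independently of the others.
#'
#' @param n number of samples.
#' @param params base [SynthParams-class]; the seed field is the seed of
#'   the first sample.
#' @return list of [OCTSample-class] objects.
#' @export
synthSamples <- function(n, params = synthParams()) {
  lapply(seq_len(n) - 1L, function(i) {
    p <- params
    p@seed <- params@seed + i
    synthBscan(p)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `n` image/mask PNG pairs plus a manifest CSV with columns
#' id, image, mask, lesion_area, seed.
#'
#' @inheritParams synthSamples
#' @param outDir output directory (created if needed).
#' @return the manifest as a data.frame (invisibly written to
#'   `manifest.csv`).
#' @export
synthDataset <- function(n, params = synthParams(), outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  samples <- synthSamples(n, params)
  manifest <- data.frame(id = character(n), image = character(n),
                         mask = character(n), lesion_area = numeric(n),
                         seed = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    ip <- file.path(outDir, paste0(s@id, "_img.png"))
    mp <- file.path(outDir, paste0(s@id, "_mask.png"))
    writeImage(Image(t(s@image)), ip)
    saveMask(s@mask, mp)
    manifest[i, ] <- list(s@id, ip, mp, sum(s@mask),
                          params@seed + i - 1L)
  }
  write.csv(manifest, file.path(outDir, "manifest.csv"),
            row.names = FALSE)
  manifest
}
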