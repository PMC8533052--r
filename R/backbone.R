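# MF-Net encoder-decoder skeleton. Four encoder stages of
# (3x3 conv - BN - ReLU) x2 followed by 2x2 max pooling (channels
# base*2^(k-1)); MAD after Encoder 4; three decoder stages of bilinear
# x2 upsampling + (3x3 conv - BN - ReLU); SDA on the two shallow skip
# paths; a head restoring input resolution with a 1x1 conv + sigmoid.
# Same-level encoder-decoder skip connections are deliberately absent.

#' Construct a freshly initialized MF-Net model
#'
#' Weights use He-normal initialization drawn from the current RNG
#' state (call `set.seed()` first for reproducibility); the MAD offset
#' predictor is zero-initialized and the scalars lambda/gamma start
#' at 1.
#'
#' @param config an [MFNetConfig-class].
#' @return an [MFNet-class] model.
#' @examples
#' set.seed(7)
#' m <- mfNet(mfNetConfig(baseChannels = 8, inputSize = c(128, 128)))
#' m
#' @export
mfNet <- function(config = mfNetConfig()) {
  validObject(config)
  B <- config@baseChannels
  cs <- B * c(1L, 2L, 4L, 8L)
  ins <- c(config@inChannels, cs[1:3])
  params <- list()
  state <- list()
  for (k in 1:4) {
    b1 <- bnInit(cs[k]); b2 <- bnInit(cs[k])
    params[[paste0("enc", k)]] <- list(
      b1 = list(conv = convInit(3, ins[k], cs[k]), bn = b1$params),
      b2 = list(conv = convInit(3, cs[k], cs[k]), bn = b2$params))
    state[[paste0("enc", k)]] <- list(b1 = b1$state, b2 = b2$state)
  }
  if (config@useMAD) params$mad <- madInit(cs[4])
  dins <- c(cs[4], cs[3], cs[2])   # decoder 3, 2, 1 input channels
  douts <- c(cs[3], cs[2], cs[1])
  for (j in 1:3) {
    bn <- bnInit(douts[j])
    params[[paste0("dec", 4 - j)]] <- list(
      conv = convInit(3, dins[j], douts[j]), bn = bn$params)
    state[[paste0("dec", 4 - j)]] <- bn$state
  }
  if (config@useSDA) {
    params$sda1 <- sdaInit(cs[3], cs[2])
    params$sda2 <- sdaInit(cs[2], cs[1])
  }
  params$head <- convInit(1, cs[1], 1L)
  new("MFNet", config = config, params = params, state = state)
}

checkSpatial <- function(x) {
  d <- dim(x)
  for (ax in 1:2) {
    if (d[ax] %% 16L != 0L)
      stop("input ", c("height", "width")[ax], " (= ", d[ax],
           ") is not divisible by 16")
  }
  invisible(d)
}

encStageFwd <- function(x, p, s, training) {
  c1 <- cbrFwd(x, p$b1, s$b1, training)
  c2 <- cbrFwd(c1$y, p$b2, s$b2, training)
  mp <- maxpoolFwd(c2$y)
  list(y = mp$y,
       cache = list(c1 = c1$cache, c2 = c2$cache, idx = mp$idx,
                    hw = dim(c2$y)[1:2]),
       state = list(b1 = c1$state, b2 = c2$state))
}

encStageBwd <- function(dy, cache, p) {
  dpre <- maxpoolBwd(dy, cache$idx, cache$hw[1], cache$hw[2])
  g2 <- cbrBwd(dpre, cache$c2, p$b2)
  g1 <- cbrBwd(g2$dx, cache$c1, p$b1)
  list(dx = g1$dx, grads = list(b1 = g1$grads, b2 = g2$grads))
}

decStageFwd <- function(x, p, s, training) {
  up <- up2Fwd(x)
  cb <- cbrFwd(up, p, s, training)
  list(y = cb$y, cache = cb$cache, state = cb$state)
}

decStageBwd <- function(dy, cache, p) {
  g <- cbrBwd(dy, cache, p)
  list(dx = up2Bwd(g$dx), grads = g$grads)
}

#' Run the encoder path
#'
#' @param model an [MFNet-class].
#' @param image H x W matrix or (h, w, c, n) array; H and W divisible
#'   by 16.
#' @return list of four feature maps `E1..E4`; `Ek` has spatial dims
#'   (H, W)/2^k and `baseChannels * 2^(k-1)` channels.
#' @export
encode <- function(model, image) {
  x <- as4d(image)
  checkSpatial(x)
  out <- vector("list", 4)
  names(out) <- paste0("E", 1:4)
  for (k in 1:4) {
    st <- encStageFwd(x, model@params[[paste0("enc", k)]],
                      model@state[[paste0("enc", k)]], FALSE)
    x <- st$y
    out[[k]] <- x
  }
  out
}

# Full forward pass with optional cache for backprop.
netFwd <- function(model, x, training = FALSE, keepCache = training) {
  p <- model@params
  s <- model@state
  cfg <- model@config
  x <- as4d(x)
  checkSpatial(x)
  cache <- list()
  newState <- s
  E <- vector("list", 4)
  h <- x
  for (k in 1:4) {
    nm <- paste0("enc", k)
    st <- encStageFwd(h, p[[nm]], s[[nm]], training)
    h <- st$y
    E[[k]] <- h
    newState[[nm]] <- st$state
    if (keepCache) cache[[nm]] <- st$cache
  }
  top <- E[[4]]
  if (cfg@useMAD) {
    md <- madFwd(top, p$mad)
    top <- md$y
    if (keepCache) cache$mad <- md
  }
  d3 <- decStageFwd(top, p$dec3, s$dec3, training)
  newState$dec3 <- d3$state
  d2 <- decStageFwd(d3$y, p$dec2, s$dec2, training)
  newState$dec2 <- d2$state
  if (cfg@useSDA) {
    s1 <- sdaFwd(d3$y, E[[2]], d2$y, p$sda1)
    dec1In <- s1$y
  } else {
    dec1In <- d2$y
  }
  d1 <- decStageFwd(dec1In, p$dec1, s$dec1, training)
  newState$dec1 <- d1$state
  if (cfg@useSDA) {
    s2 <- sdaFwd(dec1In, E[[1]], d1$y, p$sda2)
    headIn <- s2$y
  } else {
    headIn <- d1$y
  }
  hu <- up2Fwd(headIn)
  z <- convFwd(hu, p$head, 1L)
  prob <- sigmoidStable(z)
  if (keepCache) {
    cache$dec3 <- d3$cache
    cache$dec2 <- d2$cache
    cache$dec1 <- d1$cache
    if (cfg@useSDA) {
      cache$sda1 <- s1
      cache$sda2 <- s2
    }
    cache$E <- E
    cache$hu <- hu
  }
  list(prob = prob, z = z, cache = if (keepCache) cache else NULL,
       state = newState)
}

# Backward pass from d(loss)/d(logits); returns nested gradient list
# mirroring model@params.
netBwd <- function(model, cache, dz) {
  p <- model@params
  cfg <- model@config
  grads <- list()
  gh <- convBwd(cache$hu, p$head, dz, 1L)
  grads$head <- list(W = gh$dW, b = gh$db)
  dHeadIn <- up2Bwd(gh$dx)
  dE <- vector("list", 4)
  if (cfg@useSDA) {
    sb2 <- sdaBwd(dHeadIn, cache$sda2, p$sda2)
    grads$sda2 <- sb2$grads
    dD1 <- sb2$dD
    dE[[1]] <- sb2$dE
  } else {
    dD1 <- dHeadIn
  }
  g1 <- decStageBwd(dD1, cache$dec1, p$dec1)
  grads$dec1 <- g1$grads
  dDec1In <- if (cfg@useSDA) sb2$dF + g1$dx else g1$dx
  if (cfg@useSDA) {
    sb1 <- sdaBwd(dDec1In, cache$sda1, p$sda1)
    grads$sda1 <- sb1$grads
    dD2 <- sb1$dD
    dE[[2]] <- sb1$dE
  } else {
    dD2 <- dDec1In
  }
  g2 <- decStageBwd(dD2, cache$dec2, p$dec2)
  grads$dec2 <- g2$grads
  dD3 <- if (cfg@useSDA) sb1$dF + g2$dx else g2$dx
  g3 <- decStageBwd(dD3, cache$dec3, p$dec3)
  grads$dec3 <- g3$grads
  dTop <- g3$dx
  if (cfg@useMAD) {
    mb <- madBwd(dTop, cache$mad, p$mad)
    grads$mad <- mb$grads
    dTop <- mb$dx
  }
  dE[[4]] <- if (is.null(dE[[4]])) dTop else dE[[4]] + dTop
  for (k in 4:1) {
    nm <- paste0("enc", k)
    ge <- encStageBwd(dE[[k]], cache[[nm]], p[[nm]])
    grads[[nm]] <- ge$grads
    if (k > 1) {
      dE[[k - 1]] <- if (is.null(dE[[k - 1]])) ge$dx
                     else dE[[k - 1]] + ge$dx
    }
  }
  grads
}

#' MF-Net forward pass
#'
#' Runs the full network in evaluation mode (batch-norm running
#' statistics) and returns the per-pixel lesion probability map.
#'
#' @param model an [MFNet-class].
#' @param image H x W matrix (or (h, w, c, n) array for a batch); both
#'   spatial dims divisible by 16.
#' @return probability map in \[0, 1\] with the spatial shape of the
#'   input: an H x W matrix for matrix input, an (h, w, 1, n) array for
#'   batch input.
#' @examples
#' set.seed(1)
#' m <- mfNet(mfNetConfig(baseChannels = 8, inputSize = c(64, 64)))
#' p <- mfNetForward(m, matrix(runif(64 * 64), 64))
#' range(p)
#' @export
mfNetForward <- function(model, image) {
  wasMatrix <- is.matrix(image)
  out <- netFwd(model, image, training = FALSE, keepCache = FALSE)
  if (wasMatrix) matrix(out$prob, nrow(image), ncol(image)) else out$prob
}
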