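# Multi-scale adaptive-aware deformation module (MAD), inserted after
# Encoder 4. Four parts: parallel dilated branches -> deformable fusion
# -> dual global attention (spatial + channel) -> adaptive residual.

# broadcast a (h,w,1,n) spatial map over channels
bcastS <- function(S, cc) S[, , rep(1L, cc), , drop = FALSE]
# broadcast a (1,1,c,n) channel vector over space
bcastC <- function(C, h, w) C[rep(1L, h), rep(1L, w), , , drop = FALSE]

sumChannels <- function(x) {
  d <- dim(x)
  array(apply(x, c(1, 2, 4), sum), c(d[1], d[2], 1L, d[4]))
}
sumSpatial <- function(x) {
  d <- dim(x)
  array(apply(x, c(3, 4), sum), c(1L, 1L, d[3], d[4]))
}

#' Initialize the parameters of a MAD module
#'
#' @param c number of input/output channels (divisible by 4; each
#'   dilated branch squeezes to `c/4`).
#' @return nested parameter list with components `branch1..branch4`
#'   (`sq` 1x1 squeeze, `dil` 3x3 dilated conv at rates 1/3/5/7),
#'   `deformOff` (zero-initialized 3x3 offset predictor), `deform`
#'   (3x3 deformable conv), `sattn` (7x7 spatial-attention conv),
#'   `cattnConv`/`cattnFc` (channel attention), `res` (3x3 smoothing
#'   conv), and the learnable scalars `lambda` and `gamma`, both
#'   initialized to 1.
#' @examples
#' set.seed(1)
#' p <- madInit(16L)
#' y <- madForward(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)), p)
#' @export
madInit <- function(c) {
  if (c %% 4L != 0L) stop("MAD channel count must be divisible by 4")
  cq <- c %/% 4L
  p <- list()
  for (k in 1:4) {
    p[[paste0("branch", k)]] <- list(sq = convInit(1, c, cq),
                                     dil = convInit(3, cq, cq))
  }
  p$deformOff <- zeroConvInit(3, c, 18L)   # zero offsets at init
  p$deform <- convInit(3, c, c)
  p$sattn <- convInit(7, 2L, 1L)
  p$cattnConv <- convInit(1, 2L * c, c)
  p$cattnFc <- fcInit(c, c)
  p$res <- convInit(3, c, c)
  p$lambda <- 1.0
  p$gamma <- 1.0
  p
}

#' Parallel dilated convolution branches
#'
#' Splits the input through four parallel 1x1 squeeze convolutions
#' (`c -> c/4`) followed by 3x3 convolutions with dilation rates 1, 3,
#' 5 and 7 (rate of branch k is 2k-1), then concatenates the branch
#' outputs back to `c` channels. Spatial size is preserved ("same"
#' padding equal to the dilation rate).
#'
#' @param x input feature map, (h, w, c, n) array with c divisible by 4.
#' @param params a MAD parameter list from [madInit()].
#' @return (h, w, c, n) array.
#' @export
parallelDilatedBranches <- function(x, params) {
  madBranchesFwd(as4d(x), params)$y
}

madBranchesFwd <- function(x, p) {
  cc <- dim(x)[3]
  if (cc %% 4L != 0L)
    stop("parallel dilated branches need channels divisible by 4, got ", cc)
  cq <- cc %/% 4L
  outs <- vector("list", 4)
  caches <- vector("list", 4)
  for (k in 1:4) {
    bp <- p[[paste0("branch", k)]]
    a <- convFwd(x, bp$sq, 1L)
    dlt <- 2L * k - 1L
    outs[[k]] <- convFwd(a, bp$dil, dlt)
    caches[[k]] <- list(a = a, dilation = dlt)
  }
  d <- dim(x)
  y <- array(0, d)
  for (k in 1:4) y[, , ((k - 1) * cq + 1):(k * cq), ] <- outs[[k]]
  list(y = y, x = x, caches = caches, cq = cq)
}

madBranchesBwd <- function(dy, cache, p) {
  cq <- cache$cq
  dx <- array(0, dim(cache$x))
  grads <- list()
  for (k in 1:4) {
    bp <- p[[paste0("branch", k)]]
    dyk <- dy[, , ((k - 1) * cq + 1):(k * cq), , drop = FALSE]
    gd <- convBwd(cache$caches[[k]]$a, bp$dil, dyk,
                  cache$caches[[k]]$dilation)
    gs <- convBwd(cache$x, bp$sq, gd$dx, 1L)
    dx <- dx + gs$dx
    grads[[paste0("branch", k)]] <-
      list(sq = list(W = gs$dW, b = gs$db),
           dil = list(W = gd$dW, b = gd$db))
  }
  list(dx = dx, grads = grads)
}

#' Deformable fusion convolution
#'
#' A 3x3 deformable convolution whose per-location 2D sampling offsets
#' are predicted from the same input by an auxiliary 3x3 convolution.
#' The offset predictor is zero-initialized, so at initialization the
#' layer equals a standard 3x3 convolution with the same kernel.
#'
#' @inheritParams parallelDilatedBranches
#' @return (h, w, c, n) fused feature map B.
#' @export
deformableFusion <- function(x, params) {
  madDeformFwd(as4d(x), params)$y
}

madDeformFwd <- function(x, p) {
  offs <- convFwd(x, p$deformOff, 1L)
  y <- deformFwd(x, offs, p$deform)
  list(y = y, x = x, offs = offs)
}

madDeformBwd <- function(dy, cache, p) {
  gd <- deformBwd(cache$x, cache$offs, p$deform, dy)
  go <- convBwd(cache$x, p$deformOff, gd$doffs, 1L)
  list(dx = gd$dx + go$dx,
       grads = list(deform = list(W = gd$dW, b = gd$db),
                    deformOff = list(W = go$dW, b = go$db)))
}

#' Multiple global spatial attention
#'
#' Per-position channel-wise max and mean maps are concatenated and
#' passed through a 7x7 convolution and a sigmoid, yielding a spatial
#' attention map in (0, 1).
#'
#' @param B fused feature map, (h, w, c, n).
#' @param params a MAD parameter list.
#' @return (h, w, 1, n) attention map S.
#' @export
spatialAttentionMap <- function(B, params) {
  madSattnFwd(as4d(B), params)$S
}

madSattnFwd <- function(B, p) {
  d <- dim(B)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  xmat <- matrix(aperm(B, c(1, 2, 4, 3)), ncol = cc)  # (h*w*n) x c
  amax <- max.col(xmat, ties.method = "first")
  s1 <- xmat[cbind(seq_len(nrow(xmat)), amax)]
  s2 <- rowMeans(xmat)
  cat2 <- aperm(array(cbind(s1, s2), c(h, w, n, 2L)), c(1, 2, 4, 3))
  u <- convFwd(cat2, p$sattn, 1L)
  S <- sigmoidStable(u)
  list(S = S, cat2 = cat2, amax = amax, B = B)
}

madSattnBwd <- function(dS, cache, p) {
  S <- cache$S
  du <- dS * S * (1 - S)
  g <- convBwd(cache$cat2, p$sattn, du, 1L)
  d <- dim(cache$B)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  dcat <- aperm(g$dx, c(1, 2, 4, 3))            # (h,w,n,2)
  dmax <- as.vector(dcat[, , , 1L])
  dmean <- as.vector(dcat[, , , 2L])
  dmat <- matrix(0, h * w * n, cc)
  dmat[cbind(seq_len(h * w * n), cache$amax)] <- dmax
  dmat <- dmat + dmean / cc
  dB <- aperm(array(dmat, c(h, w, n, cc)), c(1, 2, 4, 3))
  list(dB = dB, grads = list(sattn = list(W = g$dW, b = g$db)))
}

#' Multiple global channel attention
#'
#' Global max- and average-pooled channel descriptors are concatenated
#' (2c), squeezed by a 1x1 convolution to c, passed through a fully
#' connected layer (c -> c) and a sigmoid.
#'
#' @inheritParams spatialAttentionMap
#' @return (1, 1, c, n) attention vector C.
#' @export
channelAttentionMap <- function(B, params) {
  madCattnFwd(as4d(B), params)$C
}

madCattnFwd <- function(B, p) {
  d <- dim(B)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  xm <- matrix(B, nrow = h * w)                  # columns: (c, n)
  mx <- apply(xm, 2, max)
  amax <- apply(xm, 2, which.max)
  mn <- colMeans(xm)
  C1 <- array(mx, c(1, 1, cc, n))
  C2 <- array(mn, c(1, 1, cc, n))
  cat2 <- array(0, c(1, 1, 2L * cc, n))
  cat2[, , 1:cc, ] <- C1
  cat2[, , (cc + 1):(2 * cc), ] <- C2
  v <- convFwd(cat2, p$cattnConv, 1L)            # (1,1,c,n)
  vmat <- matrix(v, nrow = cc)                   # c x n
  fmat <- p$cattnFc$W %*% vmat + p$cattnFc$b     # c x n
  C <- sigmoidStable(array(fmat, c(1, 1, cc, n)))
  list(C = C, cat2 = cat2, v = v, vmat = vmat, amax = amax, B = B)
}

madCattnBwd <- function(dC, cache, p) {
  C <- cache$C
  d <- dim(cache$B)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  dfmat <- matrix(dC * C * (1 - C), nrow = cc)
  dW_fc <- dfmat %*% t(cache$vmat)
  db_fc <- rowSums(dfmat)
  dvmat <- t(p$cattnFc$W) %*% dfmat
  dv <- array(dvmat, c(1, 1, cc, n))
  g <- convBwd(cache$cat2, p$cattnConv, dv, 1L)
  dcat <- g$dx
  dC1 <- matrix(dcat[, , 1:cc, ], nrow = cc)
  dC2 <- matrix(dcat[, , (cc + 1):(2 * cc), ], nrow = cc)
  dB <- array(0, d)
  dxm <- matrix(dB, nrow = h * w)
  dxm[cbind(cache$amax, seq_len(cc * n))] <- as.vector(dC1)
  dxm <- dxm + matrix(as.vector(dC2) / (h * w), nrow = h * w,
                      ncol = cc * n, byrow = TRUE)
  dB <- array(dxm, d)
  list(dB = dB,
       grads = list(cattnConv = list(W = g$dW, b = g$db),
                    cattnFc = list(W = dW_fc, b = db_fc)))
}

#' Adaptive residual combination
#'
#' Computes `O = B + conv(lambda * (B x S) + gamma * (B x C))` where S
#' is broadcast over channels, C over space, and `conv` is a 3x3
#' smoothing convolution. `lambda` and `gamma` are learnable scalars
#' initialized to 1.
#'
#' @param B fused feature map (h, w, c, n).
#' @param S spatial attention map (h, w, 1, n).
#' @param C channel attention vector (1, 1, c, n).
#' @param lambda,gamma scalar mixing weights (default: taken from
#'   `params`).
#' @param params a MAD parameter list (for the smoothing conv).
#' @return (h, w, c, n) output O.
#' @export
adaptiveResidual <- function(B, S, C, params, lambda = params$lambda,
                             gamma = params$gamma) {
  B <- as4d(B); S <- as4d(S); C <- as4d(C)
  d <- dim(B)
  if (!identical(dim(S), c(d[1], d[2], 1L, d[4])) &&
      !identical(dim(S)[1:2], d[1:2]))
    stop("spatial attention S does not broadcast over B: dims ",
         paste(dim(S), collapse = "x"), " vs ", paste(d, collapse = "x"))
  if (dim(C)[3] != d[3])
    stop("channel attention C does not broadcast over B: ",
         dim(C)[3], " channels vs ", d[3])
  madResFwd(B, S, C, params, lambda, gamma)$y
}

madResFwd <- function(B, S, C, p, lambda = p$lambda, gamma = p$gamma) {
  d <- dim(B)
  BS <- B * bcastS(S, d[3])
  BC <- B * bcastC(C, d[1], d[2])
  t_ <- lambda * BS + gamma * BC
  r <- convFwd(t_, p$res, 1L)
  list(y = B + r, B = B, S = S, C = C, BS = BS, BC = BC, t_ = t_,
       lambda = lambda, gamma = gamma)
}

madResBwd <- function(dy, cache, p) {
  g <- convBwd(cache$t_, p$res, dy, 1L)
  dt <- g$dx
  dlambda <- sum(dt * cache$BS)
  dgamma <- sum(dt * cache$BC)
  d <- dim(cache$B)
  Sx <- bcastS(cache$S, d[3])
  Cx <- bcastC(cache$C, d[1], d[2])
  dB <- dy + cache$lambda * dt * Sx + cache$gamma * dt * Cx
  dS <- sumChannels(cache$lambda * dt * cache$B)
  dC <- sumSpatial(cache$gamma * dt * cache$B)
  list(dB = dB, dS = dS, dC = dC,
       grads = list(res = list(W = g$dW, b = g$db), lambda = dlambda,
                    gamma = dgamma))
}

#' Full MAD module forward pass
#'
#' Composition of [parallelDilatedBranches()], [deformableFusion()],
#' the two attention maps and [adaptiveResidual()]. Output replaces the
#' Encoder 4 feature map at the top of the decoder path.
#'
#' @param x (h, w, c, n) feature map (Encoder 4 output).
#' @param params a MAD parameter list from [madInit()].
#' @return (h, w, c, n) array of the same shape as `x`.
#' @export
madForward <- function(x, params) {
  madFwd(as4d(x), params)$y
}

madFwd <- function(x, p) {
  br <- madBranchesFwd(x, p)
  df <- madDeformFwd(br$y, p)
  sa <- madSattnFwd(df$y, p)
  ca <- madCattnFwd(df$y, p)
  rs <- madResFwd(df$y, sa$S, ca$C, p)
  list(y = rs$y, br = br, df = df, sa = sa, ca = ca, rs = rs)
}

madBwd <- function(dy, cache, p) {
  rb <- madResBwd(dy, cache$rs, p)
  sb <- madSattnBwd(rb$dS, cache$sa, p)
  cb <- madCattnBwd(rb$dC, cache$ca, p)
  dB <- rb$dB + sb$dB + cb$dB
  db <- madDeformBwd(dB, cache$df, p)
  bb <- madBranchesBwd(db$dx, cache$br, p)
  grads <- c(bb$grads, db$grads, sb$grads, cb$grads, rb$grads)
  list(dx = bb$dx, grads = grads)
}
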