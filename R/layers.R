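# Thin R wrappers around the C++ layer kernels, plus parameter
# initializers. Tensors are (h, w, c, n) double arrays throughout.

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("tensor must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("tensor must have 2-4 dims")
  x
}

tensorFromSamples <- function(samples) {
  # stack images of equal size into (h, w, 1, n)
  imgs <- lapply(samples, function(s) s@image)
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) x[, , 1L, i] <- imgs[[i]]
  x
}

maskTensor <- function(samples) {
  d <- dim(samples[[1]]@image)
  y <- array(0, c(d[1], d[2], 1L, length(samples)))
  for (i in seq_along(samples)) y[, , 1L, i] <- samples[[i]]@mask
  y
}

# He-normal initialization for a (kh, kh, cin, cout) kernel
convInit <- function(kh, cin, cout) {
  sd <- sqrt(2 / (kh * kh * cin))
  list(W = array(rnorm(kh * kh * cin * cout, sd = sd),
                 c(kh, kh, cin, cout)),
       b = numeric(cout))
}

zeroConvInit <- function(kh, cin, cout) {
  list(W = array(0, c(kh, kh, cin, cout)), b = numeric(cout))
}

fcInit <- function(cin, cout) {
  list(W = matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

bnInit <- function(c) {
  list(params = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(mean = numeric(c), var = rep(1, c)))
}

# option MFNet.conv.double = TRUE forces double-precision conv GEMMs
# (slower; used by verification tests)
convFwd <- function(x, p, dilation = 1L)
  .cpp_conv2d_fwd(as4d(x), p$W, p$b, as.integer(dilation),
                  isTRUE(getOption("MFNet.conv.double")))

convBwd <- function(x, p, dy, dilation = 1L)
  .cpp_conv2d_bwd(as4d(x), p$W, as4d(dy), as.integer(dilation),
                  isTRUE(getOption("MFNet.conv.double")))

maxpoolFwd <- function(x) .cpp_maxpool2_fwd(as4d(x))
maxpoolBwd <- function(dy, idx, h, w)
  .cpp_maxpool2_bwd(as4d(dy), idx, as.integer(h), as.integer(w))

up2Fwd <- function(x) .cpp_upsample2_fwd(as4d(x))
up2Bwd <- function(dy) .cpp_upsample2_bwd(as4d(dy))

bnFwd <- function(x, p, s, training, momentum = 0.1, eps = 1e-5)
  .cpp_bn_fwd(as4d(x), p$gamma, p$beta, s$mean, s$var, eps, momentum,
              training)
bnBwd <- function(dy, cache, p)
  .cpp_bn_bwd(as4d(dy), cache$xhat, cache$invstd, p$gamma)

deformFwd <- function(x, offs, p)
  .cpp_deform_conv_fwd(as4d(x), as4d(offs), p$W, p$b)
deformBwd <- function(x, offs, p, dy)
  .cpp_deform_conv_bwd(as4d(x), as4d(offs), p$W, as4d(dy))

reluFwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
reluBwd <- function(dy, mask) dy * mask

sigmoidStable <- function(z) 1 / (1 + exp(-z))

# conv -> batch-norm -> ReLU composite used by every encoder/decoder stage
cbrFwd <- function(x, p, s, training, dilation = 1L) {
  z <- convFwd(x, p$conv, dilation)
  bn <- bnFwd(z, p$bn, s, training)
  r <- reluFwd(bn$y)
  list(y = r$y,
       cache = list(x = x, z = z, bn = bn, mask = r$mask,
                    dilation = dilation),
       state = list(mean = bn$rmean, var = bn$rvar))
}

cbrBwd <- function(dy, cache, p) {
  dz <- reluBwd(dy, cache$mask)
  bnb <- bnBwd(dz, cache$bn, p$bn)
  cb <- convBwd(cache$x, p$conv, bnb$dx, cache$dilation)
  list(dx = cb$dx,
       grads = list(conv = list(W = cb$dW, b = cb$db),
                    bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
}
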