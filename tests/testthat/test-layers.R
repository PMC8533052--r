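# The numerical layer kernels against brute-force oracles and
# central-difference gradients. Gradient checks run with the
# double-precision GEMM path so numeric differentiation is not
# drowned by float32 forward noise.

convFwd <- mf("convFwd"); convBwd <- mf("convBwd")
convInit <- mf("convInit")
bnInit <- mf("bnInit"); bnFwd <- mf("bnFwd"); bnBwd <- mf("bnBwd")
maxpoolFwd <- mf("maxpoolFwd"); maxpoolBwd <- mf("maxpoolBwd")
up2Fwd <- mf("up2Fwd"); up2Bwd <- mf("up2Bwd")
deformFwd <- mf("deformFwd"); deformBwd <- mf("deformBwd")

test_that("convolution matches the brute-force oracle for all dilations used", {
  withr::local_options(MFNet.conv.double = TRUE)
  set.seed(1)
  x <- randTensor(7, 6, 3, 2)
  p <- convInit(3, 3, 4)
  for (d in c(1L, 2L, 3L, 5L, 7L)) {
    expect_lt(maxRelErr(convFwd(x, p, d), naiveConv(x, p$W, p$b, d)),
              1e-12)
  }
  # 1x1 and 7x7 kernels
  p1 <- convInit(1, 3, 2)
  expect_lt(maxRelErr(convFwd(x, p1), naiveConv(x, p1$W, p1$b)), 1e-12)
  p7 <- convInit(7, 3, 2)
  expect_lt(maxRelErr(convFwd(x, p7), naiveConv(x, p7$W, p7$b)), 1e-12)
})

test_that("single-precision convolution agrees with the oracle to float tolerance", {
  set.seed(2)
  x <- randTensor(8, 8, 4, 1)
  p <- convInit(3, 4, 4)
  expect_lt(maxRelErr(convFwd(x, p, 2L), naiveConv(x, p$W, p$b, 2)), 1e-5)
})

test_that("convolution gradients match numeric differentiation", {
  withr::local_options(MFNet.conv.double = TRUE)
  set.seed(3)
  x <- randTensor(6, 5, 2, 2)
  p <- convInit(3, 2, 3)
  R <- randTensor(6, 5, 3, 2)
  for (d in c(1L, 7L)) {
    g <- convBwd(x, p, R, d)
    expect_lt(maxRelErr(g$dx,
      numGrad(function(v) sum(convFwd(v, p, d) * R), x)), 1e-6)
    expect_lt(maxRelErr(g$dW, array(
      numGrad(function(v) { q <- p; q$W[] <- v; sum(convFwd(x, q, d) * R) },
              as.vector(p$W)), dim(p$W))), 1e-6)
    expect_lt(maxRelErr(g$db,
      numGrad(function(v) { q <- p; q$b <- v; sum(convFwd(x, q, d) * R) },
              p$b)), 1e-6)
  }
})

test_that("batch-norm forward normalizes and backward matches numeric gradients", {
  set.seed(4)
  x <- randTensor(5, 4, 3, 2)
  bn <- bnInit(3)
  p <- bn$params; s <- bn$state
  p$gamma <- runif(3, 0.5, 1.5); p$beta <- rnorm(3)
  fwd <- bnFwd(x, p, s, training = TRUE)
  # per-channel standardization
  for (cc in 1:3) {
    v <- fwd$xhat[, , cc, ]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(mean(v^2) - 1), 1e-3)   # eps-deflated unit variance
  }
  # eval mode uses running statistics
  ev <- bnFwd(x, p, s, training = FALSE)
  expect_equal(ev$y, array(rep(p$gamma, each = 20) * ((x - 0) / sqrt(1 + 1e-5)) +
                           rep(p$beta, each = 20), dim(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  R <- randTensor(5, 4, 3, 2)
  g <- bnBwd(R, fwd, p)
  expect_lt(maxRelErr(g$dx,
    numGrad(function(v) sum(bnFwd(v, p, s, TRUE)$y * R), x, 1e-4)), 1e-5)
  expect_lt(maxRelErr(g$dgamma,
    numGrad(function(v) { q <- p; q$gamma <- v; sum(bnFwd(x, q, s, TRUE)$y * R) },
            p$gamma, 1e-4)), 1e-6)
})

test_that("max-pool and bilinear upsample are exact transposes of their backward", {
  set.seed(5)
  x <- randTensor(8, 6, 2, 2)
  mp <- maxpoolFwd(x)
  expect_identical(dim(mp$y), c(4L, 3L, 2L, 2L))
  R <- randTensor(4, 3, 2, 2)
  expect_lt(maxRelErr(maxpoolBwd(R, mp$idx, 8, 6),
    numGrad(function(v) sum(maxpoolFwd(v)$y * R), x, 1e-3)), 1e-8)

  xu <- randTensor(5, 4, 2, 2)
  yu <- up2Fwd(xu)
  expect_identical(dim(yu), c(10L, 8L, 2L, 2L))
  # constant field is preserved exactly
  expect_equal(up2Fwd(array(3, c(4, 4, 1, 1))),
               array(3, c(8, 8, 1, 1)), ignore_attr = TRUE)
  Ru <- randTensor(10, 8, 2, 2)
  expect_lt(maxRelErr(up2Bwd(Ru),
    numGrad(function(v) sum(up2Fwd(v) * Ru), xu)), 1e-8)
  # adjointness: <up(x), R> == <x, up^T(R)>
  expect_equal(sum(yu * Ru), sum(xu * up2Bwd(Ru)), tolerance = 1e-12)
})

test_that("deformable convolution gradients match numeric differentiation off-lattice", {
  set.seed(6)
  x <- randTensor(7, 6, 2, 2)
  p <- convInit(3, 2, 3)
  offs <- array(runif(7 * 6 * 18 * 2, -0.6, 0.6), c(7, 6, 18, 2))
  y <- deformFwd(x, offs, p)
  R <- randTensor(7, 6, 3, 2)
  g <- deformBwd(x, offs, p, R)
  expect_lt(maxRelErr(g$dx,
    numGrad(function(v) sum(deformFwd(v, offs, p) * R), x)), 1e-6)
  expect_lt(maxRelErr(g$doffs,
    numGrad(function(v) sum(deformFwd(x, v, p) * R), offs)), 1e-6)
  expect_lt(maxRelErr(g$dW, array(
    numGrad(function(v) { q <- p; q$W[] <- v; sum(deformFwd(x, offs, q) * R) },
            as.vector(p$W)), dim(p$W))), 1e-6)
})
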