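# The multi-scale adaptive-aware deformation module: dilation rates,
# deformable fusion degeneracies, both attention maps with controlled
# weights, adaptive residual identities.

convInit <- mf("convInit")
madFwd <- mf("madFwd"); madBwd <- mf("madBwd")

test_that("branch k dilates at rate 2k-1: impulse-response support check", {
  # 4 channels -> each branch squeezes to 1; identity squeeze, all-ones
  # dilated kernel; a centered impulse must light up offsets +/- rate
  # in the branch output and nothing further out.
  p <- list()
  for (k in 1:4) {
    sq <- list(W = array(0, c(1, 1, 4, 1)), b = 0)
    sq$W[1, 1, 1, 1] <- 1                 # pass channel 1 through
    dil <- list(W = array(1, c(3, 3, 1, 1)), b = 0)
    p[[paste0("branch", k)]] <- list(sq = sq, dil = dil)
  }
  x <- array(0, c(31, 31, 4, 1))
  x[16, 16, 1, 1] <- 1
  y <- parallelDilatedBranches(x, p)
  for (k in 1:4) {
    rate <- 2 * k - 1
    resp <- y[, , k, 1]
    hit <- which(resp != 0, arr.ind = TRUE)
    expect_identical(sort(unique(abs(hit[, 1] - 16))), sort(c(0, rate)))
    expect_identical(sort(unique(abs(hit[, 2] - 16))), sort(c(0, rate)))
    expect_equal(resp[16 + rate, 16 + rate], 1)
    expect_equal(resp[16, 16], 1)
  }
})

test_that("branch output preserves shape and requires channels divisible by 4", {
  set.seed(1)
  p <- madInit(8L)
  x <- randTensor(16, 16, 8, 2)
  expect_identical(dim(parallelDilatedBranches(x, p)), dim(x))
  expect_error(parallelDilatedBranches(randTensor(8, 8, 6, 1), p),
               "divisible by 4")
})

test_that("deformable fusion equals a standard convolution at zero offsets", {
  set.seed(2)
  p <- madInit(8L)                        # offset predictor zero-initialized
  x <- randTensor(12, 12, 8, 2)
  ours <- deformableFusion(x, p)
  oracle <- naiveConv(x, p$deform$W, p$deform$b, 1)
  expect_lt(max(abs(ours - oracle)), 1e-5)
})

test_that("deformable fusion of a constant field is constant in the interior", {
  set.seed(3)
  p <- madInit(4L)
  p$deformOff$b <- runif(18, -0.4, 0.4)   # arbitrary learned offsets
  x <- array(2.5, c(12, 12, 4, 1))
  y <- deformableFusion(x, p)
  for (ch in 1:4) {
    interior <- y[4:9, 4:9, ch, 1]
    expect_lt(max(interior) - min(interior), 1e-10)
  }
})

test_that("spatial attention: shape, open-interval range, hand-computed value", {
  set.seed(4)
  p <- madInit(8L)
  B <- randTensor(10, 9, 8, 2)
  S <- spatialAttentionMap(B, p)
  expect_identical(dim(S), c(10L, 9L, 1L, 2L))
  expect_true(all(S > 0 & S < 1))
  # constant input -> spatially constant map in the interior (the 7x7
  # kernel sees zero padding within 3 px of the border)
  Sc <- spatialAttentionMap(array(1.7, c(20, 20, 8, 1)), p)
  expect_lt(max(Sc[4:17, 4:17, 1, 1]) - min(Sc[4:17, 4:17, 1, 1]),
            1e-12)
  # 2-channel 1x1 field (4, 2): max 4, mean 3; center weights (0.5, 0.5)
  q <- list(sattn = list(W = array(0, c(7, 7, 2, 1)), b = 0))
  q$sattn$W[4, 4, 1, 1] <- 0.5
  q$sattn$W[4, 4, 2, 1] <- 0.5
  B1 <- array(c(4, 2), c(1, 1, 2, 1))
  expect_equal(as.numeric(spatialAttentionMap(B1, q)),
               1 / (1 + exp(-3.5)), tolerance = 1e-6)
})

test_that("channel attention: shape, range, pooling and hand-computed value", {
  set.seed(5)
  p <- madInit(8L)
  B <- randTensor(10, 9, 8, 2)
  C <- channelAttentionMap(B, p)
  expect_identical(dim(C), c(1L, 1L, 8L, 2L))
  expect_true(all(C > 0 & C < 1))
  # a channel identically 5 pools to max 5 and mean 5
  Bc <- randTensor(6, 6, 4, 1)
  Bc[, , 2, ] <- 5
  fc <- mf("madCattnFwd")(Bc, madInit(4L))
  expect_equal(fc$cat2[1, 1, 2, 1], 5)        # C1 (max)
  expect_equal(fc$cat2[1, 1, 4 + 2, 1], 5)    # C2 (mean)
  # identity passthrough of the mean descriptor: channel means (0, 1)
  cc <- 2L
  q <- list(cattnConv = list(W = array(0, c(1, 1, 2 * cc, cc)),
                             b = numeric(cc)),
            cattnFc = list(W = diag(cc), b = numeric(cc)))
  q$cattnConv$W[1, 1, cc + 1, 1] <- 1   # select mean of channel 1
  q$cattnConv$W[1, 1, cc + 2, 2] <- 1   # select mean of channel 2
  B2 <- array(0, c(2, 2, cc, 1))
  B2[, , 2, ] <- c(0.5, 0.5, 1.5, 1.5)  # mean 1
  out <- as.numeric(channelAttentionMap(B2, q))
  expect_equal(out, c(0.5, 1 / (1 + exp(-1))), tolerance = 1e-6)
})

test_that("adaptive residual: identity at lambda=gamma=0, tripling under unit gates", {
  set.seed(6)
  cc <- 4L
  p <- madInit(cc)
  B <- randTensor(6, 6, cc, 2)
  S <- array(runif(6 * 6 * 2), c(6, 6, 1, 2))
  C <- array(runif(cc * 2), c(1, 1, cc, 2))
  p0 <- p; p0$res$b <- numeric(cc)
  expect_equal(adaptiveResidual(B, S, C, p0, lambda = 0, gamma = 0), B,
               tolerance = 1e-5, ignore_attr = TRUE)
  # S = C = 1, lambda = gamma = 1, conv = per-channel identity -> 3B
  pid <- p
  pid$res$W <- array(0, c(3, 3, cc, cc))
  for (ch in 1:cc) pid$res$W[2, 2, ch, ch] <- 1
  pid$res$b <- numeric(cc)
  O <- adaptiveResidual(B, array(1, c(6, 6, 1, 2)),
                        array(1, c(1, 1, cc, 2)), pid,
                        lambda = 1, gamma = 1)
  expect_equal(O, 3 * B, tolerance = 1e-5, ignore_attr = TRUE)
  # lambda and gamma start at 1 by construction
  expect_identical(madInit(8L)$lambda, 1.0)
  expect_identical(madInit(8L)$gamma, 1.0)
})

test_that("shape mismatches in the residual raise informative errors", {
  set.seed(7)
  p <- madInit(4L)
  B <- randTensor(6, 6, 4, 1)
  expect_error(adaptiveResidual(B, array(1, c(3, 3, 1, 1)),
                                array(1, c(1, 1, 4, 1)), p),
               "broadcast")
  expect_error(adaptiveResidual(B, array(1, c(6, 6, 1, 1)),
                                array(1, c(1, 1, 3, 1)), p),
               "broadcast")
})

test_that("full MAD pass: shape preserved, finite on large inputs, trainable scalars", {
  set.seed(8)
  p <- madInit(8L)
  x <- randTensor(8, 8, 8, 2) * 1e3
  out <- madFwd(x, p)
  expect_identical(dim(out$y), dim(x))
  expect_true(all(is.finite(out$y)))
  g <- madBwd(array(1, dim(x)), out, p)
  expect_true(is.finite(g$grads$lambda) && g$grads$lambda != 0)
  expect_true(is.finite(g$grads$gamma) && g$grads$gamma != 0)
  expect_equal(madForward(x, p), out$y)
})

test_that("disabling MAD bypasses the module entirely", {
  set.seed(9)
  cfg <- mfNetConfig(baseChannels = 8L, inputSize = c(64L, 64L),
                     useMAD = FALSE, useSDA = TRUE)
  m <- mfNet(cfg)
  expect_false("mad" %in% names(m@params))
  p <- mfNetForward(m, matrix(runif(64 * 64), 64))
  expect_identical(dim(p), c(64L, 64L))
})
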