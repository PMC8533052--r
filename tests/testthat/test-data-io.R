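# File round-trips, preprocessing, the fold scheme and the overlay
# renderer.

test_that("mask save/load round-trips binary content exactly", {
  set.seed(1)
  mask <- matrix(rbinom(48 * 40, 1, 0.3), 48, 40)
  p <- withr::local_tempfile(fileext = ".png")
  saveMask(mask, p)
  expect_identical(loadMask(p), mask * 1)
  expect_error(saveMask(matrix(0.5, 2, 2), p), "binary")
})

test_that("images load scaled to [0, 1]; masks binarize at 128/255", {
  img <- matrix(seq(0, 1, length.out = 32 * 32), 32)
  p <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(img)), p)
  s <- loadSample(p)
  expect_equal(max(s@image), 1, tolerance = 1e-6)  # 8-bit 255 -> 1.0
  expect_identical(s@provenance, "unlabeled")
  # stray gray value 200 snaps to 1; 100 snaps to 0
  stray <- matrix(c(0, 200, 100, 255) / 255, 2, 2)
  pm <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(stray)), pm)
  expect_identical(loadMask(pm), matrix(c(0, 1, 0, 1), 2, 2))
  # mask/image dimension mismatch is a named error
  expect_error(loadSample(p, maskPath = pm), "dimensions")
  expect_error(loadSample("no/such/file.png"), "cannot read")
})

test_that("preprocessing resizes bilinearly, keeps masks binary, is idempotent", {
  set.seed(2)
  img <- matrix(runif(96 * 80), 96, 80)
  mask <- matrix(0, 96, 80); mask[30:60, 20:50] <- 1
  s <- octSample(img, mask, id = "t")
  r <- preprocessSample(s, targetSize = c(64L, 64L))
  expect_identical(dim(r@image), c(64L, 64L))
  expect_true(all(r@mask %in% c(0, 1)))
  expect_gt(mean(r@mask), 0)
  r2 <- preprocessSample(r, targetSize = c(64L, 64L))
  expect_identical(r2@image, r@image)
  expect_error(preprocessSample(s, targetSize = c(100L, 64L)),
               "height.*100")
})

test_that("fold scheme reproduces the published split sizes", {
  split <- makeFolds(as.character(1:1522), k = 4, seed = 0)
  expect_identical(foldSizes(split), c(380L, 380L, 380L, 382L))
  expect_identical(foldSizes(makeFolds(letters[1:4], k = 4, seed = 1)),
                   rep(1L, 4))
  expect_identical(foldSizes(makeFolds(as.character(1:10), k = 4,
                                       seed = 2)),
                   c(2L, 2L, 2L, 4L))
  expect_error(makeFolds(character(0)), "empty")
  expect_error(makeFolds(letters[1:3], k = 4), "fewer ids")
})

test_that("folds are reproducible per seed with seed-invariant size multiset", {
  ids <- sprintf("s%03d", 1:53)
  a <- makeFolds(ids, k = 4, seed = 7)
  b <- makeFolds(ids, k = 4, seed = 7)
  expect_identical(a@assignments, b@assignments)
  c2 <- makeFolds(ids, k = 4, seed = 8)
  expect_false(identical(a@assignments, c2@assignments))
  expect_identical(sort(foldSizes(a)), sort(foldSizes(c2)))
  # every id assigned exactly once
  expect_identical(sort(names(a@assignments)), sort(ids))
})

test_that("overlay renderer follows the yellow/red/blue convention", {
  img <- matrix(0.5, 2, 2)
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  ov <- renderOverlay(ones, ones, img)
  expect_true(all(ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 0))
  ov2 <- renderOverlay(ones, zeros, img)
  expect_true(all(ov2[, , 1] == 1 & ov2[, , 2] == 0 & ov2[, , 3] == 0))
  # the 2x2 confusion toy: 2 yellow, 1 red, 1 blue
  pred <- matrix(c(1, 1, 1, 0), 2, byrow = TRUE)
  gt <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  ov3 <- renderOverlay(pred, gt, img)
  colAt <- function(i, j) ov3[i, j, ]
  yellow <- sum(apply(ov3, c(1, 2), function(v) all(v == c(1, 1, 0))))
  red <- sum(apply(ov3, c(1, 2), function(v) all(v == c(1, 0, 0))))
  blue <- sum(apply(ov3, c(1, 2), function(v) all(v == c(0, 0, 1))))
  expect_identical(c(yellow, red, blue), c(2L, 1L, 1L))
  expect_error(renderOverlay(pred, matrix(0, 3, 3), img), "shape")
})

test_that("predictions save as float TIFF plus binarized PNG", {
  set.seed(3)
  prob <- matrix(runif(32 * 32), 32)
  tp <- withr::local_tempfile(fileext = ".tiff")
  pp <- withr::local_tempfile(fileext = ".png")
  savePrediction(prob, tiffPath = tp, pngPath = pp)
  back <- tiff::readTIFF(tp)
  expect_equal(back, prob, tolerance = 1e-6)       # float32 round-trip
  expect_identical(loadMask(pp), (prob >= 0.5) * 1)
})

test_that("YAML training configuration round-trips the documented keys", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model:", "  base_channels: 16", "  use_mad: false",
               "  input_size: [128, 128]",
               "optim:", "  lr: 0.001", "  epochs: 3",
               "semi:", "  beta: 0.5", "seed: 42"), y)
  cfg <- readTrainConfig(y)
  expect_identical(cfg@network@baseChannels, 16L)
  expect_false(cfg@network@useMAD)
  expect_true(cfg@network@useSDA)       # default retained
  expect_equal(cfg@lr, 0.001)
  expect_identical(cfg@epochs, 3L)
  expect_equal(cfg@beta, 0.5)
  expect_identical(cfg@seed, 42L)
  expect_equal(cfg@weightDecay, 1e-4)   # documented default
})
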