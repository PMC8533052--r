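# Independent oracles and small utilities shared by the tests.

# brute-force "same"-padded convolution, double precision
naiveConv <- function(x, W, b, d = 1) {
  dm <- dim(x); h <- dm[1]; w <- dm[2]; cin <- dm[3]; n <- dm[4]
  kh <- dim(W)[1]; cout <- dim(W)[4]; ctr <- (kh - 1) / 2
  y <- array(0, c(h, w, cout, n))
  for (s in 1:n) for (co in 1:cout) for (j in 1:w) for (i in 1:h) {
    acc <- b[co]
    for (ci in 1:cin) for (kj in 1:kh) for (ki in 1:kh) {
      ii <- i + (ki - 1 - ctr) * d; jj <- j + (kj - 1 - ctr) * d
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        acc <- acc + x[ii, jj, ci, s] * W[ki, kj, ci, co]
    }
    y[i, j, co, s] <- acc
  }
  y
}

# per-pixel double-loop confusion counting
naiveConfusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
    else if (pred[i, j] == 1) fp <- fp + 1L
    else if (gt[i, j] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# closed-form paired t-test p-value via the t CDF
naivePairedT <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

# central-difference gradient
numGrad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

maxRelErr <- function(a, b) max(abs(a - b)) / max(1e-7, max(abs(b)))

randTensor <- function(...) {
  d <- c(...)
  array(rnorm(prod(d)), d)
}

# access internal (unexported) functions under test
mf <- function(name) get(name, envir = asNamespace("MFNet"))

smallSynth <- function(n, seed = 0L, size = 64L) {
  synthSamples(n, synthParams(imageSize = c(size, size), seed = seed))
}
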