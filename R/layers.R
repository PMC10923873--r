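# ConvBlock primitives: 3x3x3 convolution -> LeakyReLU -> instance norm,
# with hand-derived backward passes. The convolutions run through the
# compiled im2col/GEMM kernels; the activation and normalization are cheap
# element-wise / per-channel operations done here.

.IN_EPS <- 1e-5

.leaky <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

# forward through one ConvBlock; returns output and the cache needed for
# the backward pass
.convBlockF <- function(p, x, stride, slope, useIN) {
  y <- .conv3Forward(x, dim(x), p$W, p$b, as.integer(stride))
  a <- .leaky(y, slope)
  if (useIN) {
    C <- dim(a)[1]
    m <- matrix(a, nrow = C)
    mu <- rowMeans(m)
    xc <- m - mu
    sd <- sqrt(rowMeans(xc * xc) + .IN_EPS)
    xh <- xc / sd
    out <- array(p$g * xh + p$be, dim = dim(a))
    list(out = out, cache = list(x = x, y = y, xh = xh, sd = sd,
                                 stride = stride))
  } else {
    list(out = a, cache = list(x = x, y = y, stride = stride))
  }
}

.convBlockB <- function(p, cache, dout, slope, useIN) {
  if (useIN) {
    C <- nrow(cache$xh)
    dm <- matrix(dout, nrow = C)
    dg <- rowSums(dm * cache$xh)
    dbe <- rowSums(dm)
    dxh <- dm * p$g
    da <- (dxh - rowMeans(dxh) - cache$xh * rowMeans(dxh * cache$xh)) /
      cache$sd
    da <- array(da, dim = dim(cache$y))
  } else {
    dg <- numeric(0); dbe <- numeric(0)
    da <- dout
  }
  dy <- da * ifelse(cache$y > 0, 1, slope)
  cb <- .conv3Backward(cache$x, dim(cache$x), p$W, dy,
                       as.integer(cache$stride))
  grads <- list(W = cb$dW, b = cb$db)
  if (useIN) { grads$g <- dg; grads$be <- dbe }
  list(dx = cb$dx, grads = grads)
}

# channel-wise concatenation of two (C, D, H, W) arrays
.concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  out <- array(0, c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

.splitC <- function(x, c1) {
  d <- dim(x)
  list(a = array(x[seq_len(c1), , , ], c(c1, d[-1])),
       b = array(x[(c1 + 1):d[1], , , ], c(d[1] - c1, d[-1])))
}
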