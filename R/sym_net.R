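# The symmetric-aware dual-path 3D encoder-decoder.
#
# One encoder instance (shared weights by construction) processes the
# original stack and its width-mirrored copy. At every level above the
# bottleneck the two per-path feature maps are concatenated channel-wise and
# fused by a BridgeBlock of two ConvBlocks; the decoder concatenates each
# bridge output with the x2-upsampled features from the level below and
# emits a per-channel sigmoid probability map in the original orientation.
# Downsampling is by stride-2 convolution, upsampling by kernel-2/stride-2
# transposed convolution. Only the original-path bottleneck features feed
# the decoder unless `fuseBottom` is set.

#' Mirror a stack across the width (left-right) axis
#'
#' Flips every channel along the last (width) axis; an involution, so
#' `mirrorStack(mirrorStack(x))` is `x` exactly.
#'
#' @param stack a (C, D, H, W) multi-channel stack or a (D, H, W) volume.
#' @return The flipped array, same shape.
#' @export
mirrorStack <- function(stack) {
  nd <- length(dim(stack))
  if (nd == 3L) return(stack[, , dim(stack)[3]:1, drop = FALSE])
  if (nd == 4L) return(stack[, , , dim(stack)[4]:1, drop = FALSE])
  stop("stack must be a 3-D volume or 4-D channel stack", call. = FALSE)
}

#' Build the 5-channel input stack of a case
#'
#' Channel order: T2WI, ADC, high-b DWI, TZ mask, PZ mask.
#'
#' @param case an [MpMRICase-class] (already preprocessed/normalized).
#' @return A (5, D, H, W) array.
#' @export
inputStack <- function(case) {
  d <- dim(case@t2w)
  out <- array(0, c(5L, d))
  out[1, , , ] <- case@t2w
  out[2, , , ] <- case@adc
  out[3, , , ] <- case@highb
  out[4, , , ] <- case@tzMask
  out[5, , , ] <- case@pzMask
  out
}

.initBlock <- function(cin, cout, useIN) {
  p <- list(
    W = matrix(stats::rnorm(cout * cin * 27, sd = sqrt(2 / (cin * 27))),
               nrow = cout),
    b = numeric(cout))
  if (useIN) { p$g <- rep(1, cout); p$be <- numeric(cout) }
  p
}

.initUp <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cout * 8 * cin, sd = sqrt(2 / cin)),
                  nrow = cout * 8),
       b = numeric(cout))
}

#' Build a symmetric-aware network
#'
#' Weight sharing between the two encoder paths holds by construction: there
#' is a single set of encoder parameters, applied to both inputs.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed optional integer; when given, initialization is reproducible.
#' @param finalInit "small" (Gaussian, sd 0.01) or "zero"; with "zero" the
#'   untrained network outputs exactly 0.5 everywhere (sigmoid of 0).
#' @return A [SymNet-class].
#' @export
buildModel <- function(cfg = modelConfig(), seed = NULL,
                       finalInit = c("small", "zero")) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  finalInit <- match.arg(finalInit)
  build <- function() {
    ch <- cfg@encoderChannels
    L <- length(ch)
    useIN <- cfg@instanceNorm
    B <- cfg@blocksPerLevel
    Bd <- cfg@decoderBlocksPerLevel
    p <- list()
    p$enc <- lapply(seq_len(L), function(l) {
      cin <- if (l == 1L) cfg@inChannels else ch[l]
      lapply(seq_len(B), function(b) {
        .initBlock(if (b == 1L) cin else ch[l], ch[l], useIN)
      })
    })
    p$down <- lapply(seq_len(L - 1L), function(l) {
      .initBlock(ch[l], ch[l + 1L], useIN)
    })
    nBridge <- if (cfg@fuseBottom) L else L - 1L
    p$bridge <- lapply(seq_len(nBridge), function(i) {
      list(.initBlock(2L * ch[i], ch[i], useIN),
           .initBlock(ch[i], ch[i], useIN))
    })
    p$up <- lapply(seq_len(L - 1L), function(i) {
      .initUp(ch[i + 1L], ch[i])
    })
    p$dec <- lapply(seq_len(L - 1L), function(i) {
      lapply(seq_len(Bd), function(b) {
        .initBlock(if (b == 1L) 2L * ch[i] else ch[i], ch[i], useIN)
      })
    })
    p$fin <- list(
      W = if (finalInit == "zero") {
        matrix(0, nrow = cfg@outChannels, ncol = ch[1])
      } else {
        matrix(stats::rnorm(cfg@outChannels * ch[1], sd = 0.01),
               nrow = cfg@outChannels)
      },
      b = numeric(cfg@outChannels))
    p
  }
  params <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  new("SymNet", config = cfg, params = params)
}

#' Total number of trainable parameters
#' @param model a [SymNet-class].
#' @export
countParams <- function(model) length(.flattenParams(model@params))

.checkDivisible <- function(d, L) {
  f <- 2^(L - 1L)
  nm <- c("depth", "height", "width")
  for (i in 1:3) {
    if (d[i] %% f != 0L)
      stop("input ", nm[i], " (", d[i], ") is not divisible by ", f,
           call. = FALSE)
  }
}

# encoder over one path; returns per-level features (and caches)
.encForward <- function(p, cfg, x) {
  L <- length(cfg@encoderChannels)
  slope <- cfg@negativeSlope
  useIN <- cfg@instanceNorm
  feats <- vector("list", L)
  cEnc <- vector("list", L)
  cDown <- vector("list", L - 1L)
  cur <- x
  for (l in seq_len(L)) {
    if (l > 1L) {
      r <- .convBlockF(p$down[[l - 1L]], cur, 2L, slope, useIN)
      cDown[[l - 1L]] <- r$cache
      cur <- r$out
    }
    cEnc[[l]] <- vector("list", cfg@blocksPerLevel)
    for (b in seq_len(cfg@blocksPerLevel)) {
      r <- .convBlockF(p$enc[[l]][[b]], cur, 1L, slope, useIN)
      cEnc[[l]][[b]] <- r$cache
      cur <- r$out
    }
    feats[[l]] <- cur
  }
  list(feats = feats, cEnc = cEnc, cDown = cDown)
}

# backward through one encoder path given per-level output gradients;
# returns parameter gradients (enc/down subtrees) for this path
.encBackward <- function(p, cfg, enc, dfeats) {
  L <- length(cfg@encoderChannels)
  slope <- cfg@negativeSlope
  useIN <- cfg@instanceNorm
  gEnc <- vector("list", L)
  gDown <- vector("list", L - 1L)
  d <- dfeats[[L]]
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d  # gradient already accumulated below
    gEnc[[l]] <- vector("list", cfg@blocksPerLevel)
    for (b in rev(seq_len(cfg@blocksPerLevel))) {
      r <- .convBlockB(p$enc[[l]][[b]], enc$cEnc[[l]][[b]], d, slope, useIN)
      gEnc[[l]][[b]] <- r$grads
      d <- r$dx
    }
    if (l > 1L) {
      r <- .convBlockB(p$down[[l - 1L]], enc$cDown[[l - 1L]], d, slope, useIN)
      gDown[[l - 1L]] <- r$grads
      d <- r$dx + dfeats[[l - 1L]]
    }
  }
  list(enc = gEnc, down = gDown)
}

#' Forward pass of the symmetric-aware network
#'
#' Runs the shared-weight encoder on both stacks, fuses the paths through
#' the BridgeBlocks and decodes to a probability map aligned with the
#' original orientation. Deterministic given weights and inputs.
#'
#' @param model a [SymNet-class].
#' @param stackOri (C, D, H, W) input stack; spatial dims must be divisible
#'   by 2^(levels-1).
#' @param stackMir the mirrored stack; defaults to `mirrorStack(stackOri)`.
#'   Passing `stackOri` itself gives the parameter-matched single-path
#'   ablation.
#' @param spacingMm voxel spacing attached to the returned map.
#' @param cache return intermediate activations (for training/backprop).
#' @return A [ProbMap-class]; with `cache = TRUE`, a list with elements
#'   `probMap` and `cache`.
#' @export
forwardSymNet <- function(model, stackOri, stackMir = NULL,
                          spacingMm = c(3, 0.625, 0.625), cache = FALSE) {
  stopifnot(is(model, "SymNet"))
  cfg <- model@config
  p <- model@params
  d <- dim(stackOri)
  if (length(d) != 4L || d[1] != cfg@inChannels)
    stop("input must be a (", cfg@inChannels, ", D, H, W) stack",
         call. = FALSE)
  L <- length(cfg@encoderChannels)
  .checkDivisible(d[-1], L)
  if (is.null(stackMir)) stackMir <- mirrorStack(stackOri)
  slope <- cfg@negativeSlope
  useIN <- cfg@instanceNorm

  eo <- .encForward(p, cfg, stackOri)
  em <- .encForward(p, cfg, stackMir)

  nBridge <- if (cfg@fuseBottom) L else L - 1L
  bridgeOut <- vector("list", nBridge)
  cBridge <- vector("list", nBridge)
  for (i in seq_len(nBridge)) {
    cat1 <- .concatC(eo$feats[[i]], em$feats[[i]])
    r1 <- .convBlockF(p$bridge[[i]][[1]], cat1, 1L, slope, useIN)
    r2 <- .convBlockF(p$bridge[[i]][[2]], r1$out, 1L, slope, useIN)
    bridgeOut[[i]] <- r2$out
    cBridge[[i]] <- list(r1$cache, r2$cache)
  }

  cur <- if (cfg@fuseBottom) bridgeOut[[L]] else eo$feats[[L]]
  cDec <- vector("list", L - 1L)
  cUp <- vector("list", L - 1L)
  for (i in rev(seq_len(L - 1L))) {
    u <- .tconv2Forward(cur, dim(cur), p$up[[i]]$W, p$up[[i]]$b)
    cUp[[i]] <- list(x = cur)
    cat2 <- .concatC(bridgeOut[[i]], u)
    cDec[[i]] <- vector("list", cfg@decoderBlocksPerLevel)
    cur <- cat2
    for (b in seq_len(cfg@decoderBlocksPerLevel)) {
      r <- .convBlockF(p$dec[[i]][[b]], cur, 1L, slope, useIN)
      cDec[[i]][[b]] <- r$cache
      cur <- r$out
    }
  }

  c1 <- dim(cur)[1]
  zmat <- p$fin$W %*% matrix(cur, nrow = c1) + p$fin$b
  pr <- 1 / (1 + exp(-zmat))
  out <- array(pr, c(cfg@outChannels, d[-1]))
  pm <- new("ProbMap", values = out, spacingMm = as.numeric(spacingMm))
  if (!cache) return(pm)
  list(probMap = pm,
       cache = list(eo = eo, em = em, cBridge = cBridge, cUp = cUp,
                    cDec = cDec, finIn = cur, prob = out))
}

# backward pass: gradient of the scalar loss w.r.t. all parameters, given
# dL/d(probability map). Encoder gradients from the two paths are summed
# (weight sharing).
.backwardSymNet <- function(model, fw, dProb) {
  cfg <- model@config
  p <- model@params
  slope <- cfg@negativeSlope
  useIN <- cfg@instanceNorm
  L <- length(cfg@encoderChannels)
  ca <- fw$cache

  # sigmoid head
  pr <- ca$prob
  dz <- dProb * pr * (1 - pr)
  c1 <- dim(ca$finIn)[1]
  zin <- matrix(ca$finIn, nrow = c1)
  dzm <- matrix(dz, nrow = cfg@outChannels)
  gFin <- list(W = dzm %*% t(zin), b = rowSums(dzm))
  dcur <- array(t(p$fin$W) %*% dzm, dim = dim(ca$finIn))

  nBridge <- if (cfg@fuseBottom) L else L - 1L
  gDec <- vector("list", L - 1L)
  gUp <- vector("list", L - 1L)
  dBridgeOut <- vector("list", nBridge)

  for (i in seq_len(L - 1L)) {
    gDec[[i]] <- vector("list", cfg@decoderBlocksPerLevel)
    for (b in rev(seq_len(cfg@decoderBlocksPerLevel))) {
      r <- .convBlockB(p$dec[[i]][[b]], ca$cDec[[i]][[b]], dcur, slope, useIN)
      gDec[[i]][[b]] <- r$grads
      dcur <- r$dx
    }
    ci <- cfg@encoderChannels[i]
    sp <- .splitC(dcur, ci)
    dBridgeOut[[i]] <- sp$a
    ub <- .tconv2Backward(ca$cUp[[i]]$x, dim(ca$cUp[[i]]$x), p$up[[i]]$W,
                          sp$b)
    gUp[[i]] <- list(W = ub$dW, b = ub$db)
    dcur <- ub$dx
  }
  dBottom <- dcur
  if (cfg@fuseBottom) dBridgeOut[[L]] <- dBottom

  dfeatsO <- vector("list", L)
  dfeatsM <- vector("list", L)
  gBridge <- vector("list", nBridge)
  for (i in seq_len(nBridge)) {
    r2 <- .convBlockB(p$bridge[[i]][[2]], ca$cBridge[[i]][[2]],
                      dBridgeOut[[i]], slope, useIN)
    r1 <- .convBlockB(p$bridge[[i]][[1]], ca$cBridge[[i]][[1]], r2$dx,
                      slope, useIN)
    gBridge[[i]] <- list(r1$grads, r2$grads)
    ci <- cfg@encoderChannels[i]
    sp <- .splitC(r1$dx, ci)
    dfeatsO[[i]] <- sp$a
    dfeatsM[[i]] <- sp$b
  }
  zeroBottom <- array(0, dim = dim(ca$eo$feats[[L]]))
  if (!cfg@fuseBottom) {
    dfeatsO[[L]] <- dBottom
    dfeatsM[[L]] <- zeroBottom
  } else if (is.null(dfeatsO[[L]])) {
    dfeatsO[[L]] <- zeroBottom
    dfeatsM[[L]] <- zeroBottom
  }

  gEncO <- .encBackward(p, cfg, ca$eo, dfeatsO)
  gEncM <- .encBackward(p, cfg, ca$em, dfeatsM)

  list(enc = .plusParams(gEncO$enc, gEncM$enc),
       down = if (L > 1L) .plusParams(gEncO$down, gEncM$down) else list(),
       bridge = gBridge, up = gUp, dec = gDec, fin = gFin)
}

#' Predict a probability map for a case
#'
#' @param model a [SymNet-class].
#' @param case an [MpMRICase-class] (preprocessed).
#' @param symmetric use the mirrored stack as the second input (TRUE, the
#'   symmetric-aware mode) or the original stack twice (the single-path
#'   ablation).
#' @return A [ProbMap-class] carrying the case's spacing.
#' @export
predictProbMap <- function(model, case, symmetric = TRUE) {
  stack <- inputStack(case)
  mir <- if (symmetric) mirrorStack(stack) else stack
  forwardSymNet(model, stack, mir, spacingMm = case@spacingMm)
}

#' Save / load a model checkpoint
#'
#' A single RDS file holding the configuration and all weights; restoring
#' reproduces evaluation outputs exactly.
#'
#' @param model a [SymNet-class].
#' @param path checkpoint file path.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "SymNet"))
  cfg <- model@config
  saveRDS(list(
    config = list(inChannels = cfg@inChannels,
                  encoderChannels = cfg@encoderChannels,
                  blocksPerLevel = cfg@blocksPerLevel,
                  decoderBlocksPerLevel = cfg@decoderBlocksPerLevel,
                  outChannels = cfg@outChannels,
                  negativeSlope = cfg@negativeSlope,
                  instanceNorm = cfg@instanceNorm,
                  fuseBottom = cfg@fuseBottom),
    params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path, call. = FALSE)
  ck <- readRDS(path)
  cfg <- do.call(modelConfig, ck$config)
  new("SymNet", config = cfg, params = ck$params)
}
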