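# The zonal loss: a modified cross-entropy whose inter-class probability
# constraints suppress the undefined label pattern (0, 1), plus its focal
# form, and the plain binary focal-loss baseline.
#
# Per voxel, with label m = (m0, m1) and prediction p = (p0, p1), the
# constrained probabilities are
#   p0' = p0             if m0 = 1,   max(p0, p1) otherwise
#   p1' = min(p0, p1)    if m1 = 1,   p1          otherwise
# so that any prediction with p1 > p0 (which would assert TZ-specific T2WI
# evidence without the common DWI evidence) is penalized. The focal form
# weights each term by (1-p')^gamma resp. p'^gamma.

.asArray2 <- function(x) {
  if (is(x, "ProbMap") || is(x, "HierLabelMap")) x <- x@values
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("expected a 2-vector or (2, ...) array",
                              call. = FALSE)
    x <- array(x, c(2L, 1L, 1L, 1L))
  }
  if (dim(x)[1] != 2L) stop("first dimension must be the 2 channels",
                            call. = FALSE)
  x
}

.splitChannels <- function(a) {
  n <- length(a) / 2L
  m <- matrix(a, nrow = 2L)
  list(c0 = m[1L, ], c1 = m[2L, ], n = n)
}

#' Apply the inter-class probability constraints
#'
#' Element-wise over a probability/label pair: replaces p0 by max(p0, p1)
#' wherever m0 = 0, and p1 by min(p0, p1) wherever m1 = 1. Ties are resolved
#' toward channel 0 (relevant only for gradient routing).
#'
#' @param p probabilities: a 2-vector, a (2, D, H, W) array or a
#'   [ProbMap-class].
#' @param m labels in \{(0,0), (1,0), (1,1)\}: same shapes, or a
#'   [HierLabelMap-class]. The undefined pattern (0, 1) raises an error.
#' @return The constrained probabilities in the same shape as `p`.
#' @examples
#' constrainProbs(c(0.3, 0.6), c(0, 0))  # c(0.6, 0.6)
#' constrainProbs(c(0.2, 0.8), c(1, 1))  # c(0.2, 0.2)
#' @export
constrainProbs <- function(p, m) {
  shapeIn <- if (is.null(dim(p)) && length(p) == 2L) "vector" else "array"
  pa <- .asArray2(p); ma <- .asArray2(m)
  if (!identical(dim(pa), dim(ma)))
    stop("probability and label shapes differ", call. = FALSE)
  ps <- .splitChannels(pa); ms <- .splitChannels(ma)
  if (any(ms$c1 == 1 & ms$c0 == 0))
    stop("undefined label pattern (0, 1)", call. = FALSE)
  q0 <- ifelse(ms$c0 == 1, ps$c0, pmax(ps$c0, ps$c1))
  q1 <- ifelse(ms$c1 == 1, pmin(ps$c0, ps$c1), ps$c1)
  out <- array(rbind(q0, q1), dim = dim(pa))
  if (shapeIn == "vector") c(out) else out
}

# loss, plus d(loss)/d(p) routed through the max/min selections.
# Returns list(loss, grad) with grad an array congruent to p.
.zonalLossGrad <- function(p, m, cfg) {
  pa <- .asArray2(p); ma <- .asArray2(m)
  if (!identical(dim(pa), dim(ma)))
    stop("probability and label shapes differ", call. = FALSE)
  gamma <- cfg@gamma; eps <- cfg@eps
  ps <- .splitChannels(pa); ms <- .splitChannels(ma)
  if (any(ms$c1 == 1 & ms$c0 == 0))
    stop("undefined label pattern (0, 1)", call. = FALSE)
  p0 <- ps$c0; p1 <- ps$c1; m0 <- ms$c0; m1 <- ms$c1

  q0 <- .clamp(ifelse(m0 == 1, p0, pmax(p0, p1)), eps, 1 - eps)
  q1 <- .clamp(ifelse(m1 == 1, pmin(p0, p1), p1), eps, 1 - eps)

  lossTerm <- function(q, m) {
    -m * (1 - q)^gamma * log(q) - (1 - m) * q^gamma * log(1 - q)
  }
  dTerm <- function(q, m) {
    # d/dq of the focal term; the gamma = 0 products vanish exactly
    pos <- gamma * (1 - q)^(pmax(gamma - 1, 0)) * log(q) - (1 - q)^gamma / q
    neg <- -gamma * q^(pmax(gamma - 1, 0)) * log(1 - q) + q^gamma / (1 - q)
    m * pos + (1 - m) * neg
  }

  l <- sum(lossTerm(q0, m0)) + sum(lossTerm(q1, m1))
  g0 <- dTerm(q0, m0)
  g1 <- dTerm(q1, m1)

  # selection masks; ties pass the gradient to channel 0
  sel0ToP0 <- ifelse(m0 == 1, 1, as.numeric(p0 >= p1))
  sel1ToP0 <- ifelse(m1 == 1, as.numeric(p0 <= p1), 0)
  dP0 <- g0 * sel0ToP0 + g1 * sel1ToP0
  dP1 <- g0 * (1 - sel0ToP0) + g1 * ifelse(m1 == 1, 1 - sel1ToP0, 1)

  grad <- array(rbind(dP0, dP1), dim = dim(pa))
  if (cfg@reduction == "mean") {
    nv <- ps$n
    l <- l / nv
    grad <- grad / nv
  }
  list(loss = l, grad = grad)
}

#' Zonal loss (constrained focal cross-entropy)
#'
#' Sums, over voxels and both label channels, the focal cross-entropy of the
#' constrained probabilities. With `gamma = 0` this reduces exactly to the
#' modified cross-entropy [modifiedCE()].
#'
#' @param p a [ProbMap-class] or (2, D, H, W) array (a 2-vector works for a
#'   single voxel).
#' @param m a [HierLabelMap-class] or congruent label array.
#' @param cfg a [LossConfig-class]; `cfg@reduction` selects sum over voxels
#'   (the definition) or mean per voxel.
#' @return A non-negative finite scalar.
#' @examples
#' zonalLoss(c(0.3, 0.6), c(0, 0), lossConfig(gamma = 0))  # 2 * -log(0.4)
#' zonalLoss(c(0.5, 0.5), c(1, 1), lossConfig(gamma = 2))  # 2 * 0.25 * -log(0.5)
#' @export
zonalLoss <- function(p, m, cfg = lossConfig()) {
  stopifnot(is(cfg, "LossConfig"))
  .zonalLossGrad(p, m, cfg)$loss
}

#' Modified cross-entropy with inter-class constraints
#'
#' The unfocused (`gamma = 0`) form of the zonal loss.
#'
#' @inheritParams zonalLoss
#' @export
modifiedCE <- function(p, m, cfg = lossConfig(gamma = 0)) {
  cfg@gamma <- 0
  zonalLoss(p, m, cfg)
}

# single-channel focal loss with gradient; shared by the baseline loss and
# the training loop
.focalBinaryGrad <- function(p, m, cfg) {
  gamma <- cfg@gamma; eps <- cfg@eps
  q <- .clamp(as.numeric(p), eps, 1 - eps)
  mv <- as.numeric(m)
  l <- sum(-mv * (1 - q)^gamma * log(q) - (1 - mv) * q^gamma * log(1 - q))
  pos <- gamma * (1 - q)^(pmax(gamma - 1, 0)) * log(q) - (1 - q)^gamma / q
  neg <- -gamma * q^(pmax(gamma - 1, 0)) * log(1 - q) + q^gamma / (1 - q)
  grad <- mv * pos + (1 - mv) * neg
  if (!is.null(dim(p))) dim(grad) <- dim(p)
  if (cfg@reduction == "mean") {
    nv <- length(q)
    l <- l / nv
    grad <- grad / nv
  }
  list(loss = l, grad = grad)
}

#' Binary focal loss (baseline)
#'
#' Standard focal loss on the plain binary labeling; `gamma = 0` gives the
#' binary cross-entropy. This is the ablation baseline the zonal loss is
#' compared against.
#'
#' @param p single-channel probabilities: scalar, (D, H, W) array, or a
#'   1-channel [ProbMap-class].
#' @param m matching binary labels or a [BinaryLabelMap-class].
#' @param cfg a [LossConfig-class].
#' @export
focalLossBinary <- function(p, m, cfg = lossConfig()) {
  stopifnot(is(cfg, "LossConfig"))
  if (is(p, "ProbMap")) {
    if (dim(p@values)[1] != 1L)
      stop("focalLossBinary expects a single-channel map", call. = FALSE)
    p <- array(p@values[1, , , ], dim(p@values)[-1])
  }
  if (is(m, "BinaryLabelMap")) m <- m@values
  if (!is.null(dim(p)) && !is.null(dim(m)) && !identical(dim(p), dim(m)))
    stop("probability and label shapes differ", call. = FALSE)
  if (is.null(dim(p)) && length(p) != length(m))
    stop("probability and label shapes differ", call. = FALSE)
  .focalBinaryGrad(p, m, cfg)$loss
}
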