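# Synthetic anatomical phantom generation.
#
# The phantom is the test bed for the whole pipeline: a centered prostate
# ellipsoid split into an inner TZ ellipsoid and a PZ shell, with asymmetric
# lesions and exactly mirror-symmetric benign mimic pairs. Intensities are
# additive offsets on zone-wise base levels (with a smooth radial taper) plus
# i.i.d. Gaussian noise; all randomness flows from the spec's single seed.

# flip a (D, H, W) volume along the width (left-right) axis
.flipW3 <- function(a) a[, , dim(a)[3]:1, drop = FALSE]

# voxel-center coordinate arrays in mm, one per axis, each of dim (D, H, W)
.coordArrays <- function(shape, spacing) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  list(
    z = array((seq_len(D) - 1) * spacing[1], c(D, H, W)),
    y = array(rep((seq_len(H) - 1) * spacing[2], each = D), c(D, H, W)),
    x = array(rep((seq_len(W) - 1) * spacing[3], each = D * H), c(D, H, W))
  )
}

.ellipsoid <- function(co, center, semi) {
  ((co$z - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$x - center[3]) / semi[3])^2 <= 1
}

# quadratic form of the prostate ellipsoid, used for the smooth taper
.ellipsoidRho2 <- function(co, center, semi) {
  ((co$z - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$x - center[3]) / semi[3])^2
}

#' Generate a synthetic mpMRI phantom case
#'
#' Builds a three-channel (T2WI, ADC, high-b DWI) volume with TZ/PZ masks, a
#' lesion mask and a per-lesion table according to `spec`. The anatomy is
#' exactly mirror-symmetric about the mid-width axis; lesions are placed at
#' least 3 mm off the midline so each one breaks the symmetry, while every
#' mimic pair consists of two blobs at exact mirror positions with
#' lesion-like contrast, excluded from the lesion mask. The same spec (same
#' seed) reproduces the identical case bit for bit.
#'
#' @param spec a [PhantomSpec-class].
#' @return An [MpMRICase-class].
#' @examples
#' case <- generatePhantom(phantomSpec(volumeShape = c(8L, 32L, 32L),
#'                                     spacingMm = c(3, 2.5, 2.5),
#'                                     nLesionsPZ = 1L, seed = 3L))
#' case
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, .generatePhantom(spec))
}

.generatePhantom <- function(spec) {
  shape <- spec@volumeShape
  sp <- spec@spacingMm
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  co <- .coordArrays(shape, sp)
  center <- c((D - 1) / 2 * sp[1], (H - 1) / 2 * sp[2], (W - 1) / 2 * sp[3])

  # prostate scaled to the field of view; TZ nested and shifted anteriorly
  # (along height), which preserves left-right symmetry
  semiP <- c(0.35 * D * sp[1], 0.27 * H * sp[2], 0.30 * W * sp[3])
  semiT <- 0.55 * semiP
  centerT <- center + c(0, -0.08 * H * sp[2], 0)

  prostate <- .ellipsoid(co, center, semiP)
  tz <- .ellipsoid(co, centerT, semiT) & prostate
  pz <- prostate & !tz

  # zone-wise base intensities (native units) with a smooth radial taper
  rho2 <- pmin(.ellipsoidRho2(co, center, semiP), 1)
  taper <- 1 - 0.12 * rho2
  base <- list(
    t2w = c(bg = 100, tz = 180, pz = 260),
    adc = c(bg = 600, tz = 1200, pz = 1500),
    highb = c(bg = 60, tz = 90, pz = 70)
  )
  chan <- lapply(base, function(b) {
    v <- array(b["bg"], dim = shape)
    v[tz] <- (b["tz"] * taper)[tz]
    v[pz] <- (b["pz"] * taper)[pz]
    v
  })

  occupied <- array(FALSE, dim = shape)
  lesionMask <- array(0, dim = shape)
  rows <- list()
  midX <- center[3]

  sampleCenter <- function(eligible) {
    idx <- which(eligible)
    i <- idx[sample.int(length(idx), 1L)]
    c(co$z[i], co$y[i], co$x[i])
  }

  placeBlob <- function(zone, what) {
    # rejection-sample a blob center until all placement constraints hold;
    # lesions must carry a majority-zone attribution, mimics (BPH-like
    # nodules / CZ-like wings) may sit anywhere inside the gland. Centers
    # are drawn from the prostate ellipsoid shrunk by the blob radius, so
    # the containment constraint holds by construction.
    zoneMask <- if (what == "mimic") prostate else if (zone == "TZ") tz
                else pz
    for (attempt in seq_len(500L)) {
      r <- stats::runif(1, spec@lesionRadiusMm[1], spec@lesionRadiusMm[2])
      if (any(semiP - r < 0.5 * sp)) next            # radius cannot fit
      host <- .ellipsoid(co, center, semiP - r)
      eligible <- zoneMask & host & abs(co$x - midX) >= 3
      if (!any(eligible)) next
      ctr <- sampleCenter(eligible)
      blob <- .ellipsoid(co, ctr, c(r, r, r))
      margin <- .ellipsoid(co, ctr, c(r, r, r) + sp)  # keep components apart
      if (!any(blob)) next
      if (any(blob & !prostate)) next
      if (any(margin & occupied)) next
      if (what == "mimic") {
        mblob <- .flipW3(blob)
        mmargin <- .flipW3(margin)
        # the pair must not touch: its two blobs are distinct symmetric
        # nodules, not one midline mass
        if (any(mmargin & occupied) || any(mblob & margin)) next
        return(list(blob = blob, mirror = mblob, r = r,
                    margin = margin | mmargin))
      }
      nTZ <- sum(tz[blob]); nPZ <- sum(pz[blob])
      if ((zone == "TZ") != (nTZ >= nPZ)) next
      return(list(blob = blob, r = r, margin = margin))
    }
    stop("could not place a ", what, " after 500 attempts; ",
         "the phantom spec is over-crowded", call. = FALSE)
  }

  addContrast <- function(mask, offsets) {
    chan$t2w[mask] <<- chan$t2w[mask] + offsets[1]
    chan$adc[mask] <<- chan$adc[mask] + offsets[2]
    chan$highb[mask] <<- chan$highb[mask] + offsets[3]
  }

  nextId <- 0L
  addLesion <- function(zone, offsets) {
    b <- placeBlob(zone, "lesion")
    addContrast(b$blob, offsets)
    occupied <<- occupied | b$margin
    lesionMask[b$blob] <<- 1
    nextId <<- nextId + 1L
    idx <- which(b$blob, arr.ind = TRUE)
    rows[[nextId]] <<- data.frame(
      lesionId = nextId, zone = zone,
      cz = mean(idx[, 1]), cy = mean(idx[, 2]), cx = mean(idx[, 3]),
      radiusMm = b$r)
  }

  for (i in seq_len(spec@nLesionsTZ)) addLesion("TZ", spec@lesionContrastTZ)
  for (i in seq_len(spec@nLesionsPZ)) addLesion("PZ", spec@lesionContrastPZ)
  for (i in seq_len(spec@nMimicPairs)) {
    b <- placeBlob("TZ", "mimic")
    addContrast(b$blob, spec@mimicContrast)
    addContrast(b$mirror, spec@mimicContrast)
    occupied <- occupied | b$margin
  }

  if (spec@noiseSigma > 0) {
    chan <- lapply(chan, function(v) {
      sd <- spec@noiseSigma * diff(range(v))
      v + array(stats::rnorm(length(v), 0, sd), dim = shape)
    })
  }

  tab <- if (nextId > 0L) do.call(rbind, rows) else
    data.frame(lesionId = integer(), zone = character(), cz = numeric(),
               cy = numeric(), cx = numeric(), radiusMm = numeric())

  new("MpMRICase",
      t2w = chan$t2w, adc = chan$adc, highb = chan$highb,
      tzMask = array(as.numeric(tz), dim = shape),
      pzMask = array(as.numeric(pz), dim = shape),
      lesionMask = lesionMask,
      lesionTable = tab, spacingMm = sp,
      caseId = sprintf("phantom-%d", spec@seed))
}

#' Left-right mirror-symmetry score of a channel
#'
#' Pearson correlation between a volume and its width-axis flip; 1 for an
#' exactly symmetric volume. Lesions, being unilateral, lower the score,
#' while mimic pairs do not.
#'
#' @param vol a (D, H, W) array.
#' @return correlation in [-1, 1].
#' @export
mirrorSymmetryScore <- function(vol) {
  stats::cor(as.vector(vol), as.vector(.flipW3(vol)))
}
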