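#' @useDynLib SymZonal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic mpMRI phantom
#'
#' Describes the geometry, lesion/mimic content, contrast model and noise of a
#' synthetic multi-parametric MRI case. The phantom emulates the statistical
#' structure the detection method assumes: a centered prostate ellipsoid split
#' into an inner transition zone (TZ) and a surrounding peripheral zone (PZ)
#' shell, asymmetric hypointense-ADC lesions in either zone, and bilaterally
#' symmetric benign mimic pairs (BPH-like nodules) that look lesion-like on
#' every channel but are excluded from the lesion mask.
#'
#' @slot volumeShape integer(3), (depth, height, width) voxel counts.
#' @slot spacingMm numeric(3), (through-plane, in-plane, in-plane) mm.
#' @slot nLesionsTZ,nLesionsPZ number of asymmetric lesions per zone.
#' @slot nMimicPairs number of mirror-image benign mimic pairs.
#' @slot lesionRadiusMm numeric(2), range the equivalent lesion radius is
#'   drawn from (mm).
#' @slot lesionContrastTZ,lesionContrastPZ numeric(3) additive intensity
#'   offsets on (T2WI, ADC, high-b DWI) for TZ-type and PZ-type lesions, in
#'   the phantom's native intensity units.
#' @slot mimicContrast numeric(3), offsets for benign mimics (lesion-like:
#'   dark on T2WI and ADC, bright on high-b DWI).
#' @slot noiseSigma additive Gaussian noise, expressed as a fraction of each
#'   channel's noiseless dynamic range so the signal-to-noise ratio is
#'   comparable across channels.
#' @slot seed integer; one RNG stream derived from it governs every placement
#'   and noise draw, so the same spec reproduces the identical case.
#'
#' @export
setClass("PhantomSpec",
  representation(
    volumeShape = "integer",
    spacingMm = "numeric",
    nLesionsTZ = "integer",
    nLesionsPZ = "integer",
    nMimicPairs = "integer",
    lesionRadiusMm = "numeric",
    lesionContrastTZ = "numeric",
    lesionContrastPZ = "numeric",
    mimicContrast = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 4L))
    msg <- c(msg, "volumeShape must be 3 positive voxel counts")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be strictly positive")
  if (object@nLesionsTZ < 0L || object@nLesionsPZ < 0L ||
      object@nMimicPairs < 0L)
    msg <- c(msg, "counts must be >= 0")
  if (length(object@lesionRadiusMm) != 2L || any(object@lesionRadiusMm <= 0) ||
      diff(object@lesionRadiusMm) < 0)
    msg <- c(msg, "lesionRadiusMm must be a positive, ordered range")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  for (s in c("lesionContrastTZ", "lesionContrastPZ", "mimicContrast"))
    if (length(slot(object, s)) != 3L)
      msg <- c(msg, paste(s, "must have one offset per channel"))
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' Defaults mirror the acquisition the method targets: 128 x 128 in-plane
#' crops at 0.625 mm in-plane and 3 mm through-plane spacing. Contrast
#' defaults follow the qualitative appearance of clinically significant
#' prostate cancer on mpMRI: TZ lesions are dark on T2WI and ADC and bright
#' on high-b DWI; PZ lesions perturb ADC/high-b strongly but T2WI only
#' weakly. Mimics carry the TZ-lesion-like contrast so a symmetry-blind
#' model cannot distinguish them from true lesions by local appearance.
#'
#' @param volumeShape (depth, height, width) voxel counts; each in-plane and
#'   through-plane extent must be divisible by 4 for the 3-level network.
#' @param spacingMm voxel spacing in mm, (through-plane, in-plane, in-plane).
#' @param nLesionsTZ,nLesionsPZ,nMimicPairs object counts.
#' @param lesionRadiusMm range of equivalent lesion radii (mm).
#' @param lesionContrastTZ,lesionContrastPZ,mimicContrast per-channel signed
#'   intensity offsets (T2WI, ADC, high-b DWI) in native units.
#' @param noiseSigma Gaussian noise SD as a fraction of each channel's
#'   noiseless dynamic range.
#' @param seed integer seed for the phantom's private RNG stream.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(nLesionsTZ = 1L, nMimicPairs = 1L, seed = 7L)
#' @export
phantomSpec <- function(volumeShape = c(16L, 128L, 128L),
                        spacingMm = c(3, 0.625, 0.625),
                        nLesionsTZ = 0L, nLesionsPZ = 1L,
                        nMimicPairs = 1L,
                        lesionRadiusMm = c(5, 7),
                        lesionContrastTZ = c(-80, -600, 100),
                        lesionContrastPZ = c(-30, -700, 120),
                        mimicContrast = c(-80, -600, 100),
                        noiseSigma = 0.04, seed = 1L) {
  new("PhantomSpec",
      volumeShape = as.integer(volumeShape), spacingMm = as.numeric(spacingMm),
      nLesionsTZ = as.integer(nLesionsTZ), nLesionsPZ = as.integer(nLesionsPZ),
      nMimicPairs = as.integer(nMimicPairs),
      lesionRadiusMm = as.numeric(lesionRadiusMm),
      lesionContrastTZ = as.numeric(lesionContrastTZ),
      lesionContrastPZ = as.numeric(lesionContrastPZ),
      mimicContrast = as.numeric(mimicContrast),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## MpMRICase
## ---------------------------------------------------------------------------

#' A co-registered multi-parametric MRI case
#'
#' Holds a patient's aligned channel stack (T2WI, ADC, high-b DWI), the
#' binary transition-zone and peripheral-zone masks, the binary lesion mask,
#' the per-lesion annotation table and the voxel spacing. Volumes are
#' (depth, height, width) arrays indexed (z, y, x); the width axis is the
#' left-right (mirror) axis.
#'
#' @slot t2w,adc,highb numeric 3-D intensity volumes of identical dimensions.
#' @slot tzMask,pzMask,lesionMask binary volumes; TZ and PZ are disjoint and
#'   every lesion voxel lies inside TZ or PZ.
#' @slot lesionTable data.frame with columns lesionId, zone ("TZ"/"PZ"),
#'   cz, cy, cx (1-based centroid voxel coordinates), radiusMm.
#' @slot spacingMm numeric(3), voxel spacing (z, y, x) in mm.
#' @slot caseId character scalar.
#' @export
setClass("MpMRICase",
  representation(
    t2w = "array", adc = "array", highb = "array",
    tzMask = "array", pzMask = "array", lesionMask = "array",
    lesionTable = "data.frame",
    spacingMm = "numeric",
    caseId = "character"
  )
)

setValidity("MpMRICase", function(object) {
  msg <- character()
  d0 <- dim(object@t2w)
  vols <- list(adc = object@adc, highb = object@highb, tzMask = object@tzMask,
               pzMask = object@pzMask, lesionMask = object@lesionMask)
  for (nm in names(vols))
    if (!identical(dim(vols[[nm]]), d0))
      msg <- c(msg, paste0(nm, " dimensions differ from t2w"))
  for (nm in c("tzMask", "pzMask", "lesionMask"))
    if (!.isBinary(slot(object, nm)))
      msg <- c(msg, paste0(nm, " must be binary"))
  if (any(object@tzMask == 1 & object@pzMask == 1))
    msg <- c(msg, "tzMask and pzMask must be disjoint")
  if (any(object@lesionMask == 1 &
          object@tzMask == 0 & object@pzMask == 0))
    msg <- c(msg, "every lesion voxel must lie inside TZ or PZ")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive values")
  needed <- c("lesionId", "zone", "cz", "cy", "cx", "radiusMm")
  if (!all(needed %in% names(object@lesionTable)))
    msg <- c(msg, paste("lesionTable must have columns",
                        paste(needed, collapse = ", ")))
  if (length(msg)) return(msg)
  # every table row must correspond to exactly one connected component of the
  # lesion mask, with a matching majority zone
  if (any(object@lesionMask == 1)) {
    lab <- .labelComponents26(array(as.integer(object@lesionMask), d0),
                              as.integer(d0))
    ncomp <- max(lab)
    if (ncomp != nrow(object@lesionTable))
      return(sprintf("lesionTable has %d rows but lesionMask has %d connected components",
                     nrow(object@lesionTable), ncomp))
    for (i in seq_len(nrow(object@lesionTable))) {
      ctr <- as.numeric(object@lesionTable[i, c("cz", "cy", "cx")])
      comp <- lab[round(ctr[1]), round(ctr[2]), round(ctr[3])]
      if (comp == 0)
        return(sprintf("lesion %s centroid does not fall on the lesion mask",
                       object@lesionTable$lesionId[i]))
      inTZ <- sum(object@tzMask[lab == comp])
      inPZ <- sum(object@pzMask[lab == comp])
      zone <- if (inTZ >= inPZ) "TZ" else "PZ"
      if (zone != object@lesionTable$zone[i])
        return(sprintf("lesion %s zone label does not match majority zone",
                       object@lesionTable$lesionId[i]))
    }
  } else if (nrow(object@lesionTable) > 0L) {
    return("lesionTable is non-empty but lesionMask is all zero")
  }
  TRUE
})

#' @describeIn MpMRICase case identifier
#' @export
setMethod("caseId", "MpMRICase", function(x) x@caseId)

#' @describeIn MpMRICase voxel spacing (z, y, x) in mm
#' @export
setMethod("spacingMm", "MpMRICase", function(x) x@spacingMm)

#' @describeIn MpMRICase per-lesion annotation table
#' @export
setMethod("lesionTable", "MpMRICase", function(x) x@lesionTable)

#' Channel and mask accessors for an MpMRICase
#'
#' @param x an [MpMRICase-class].
#' @return The requested 3-D array.
#' @export
t2w <- function(x) x@t2w
#' @rdname t2w
#' @export
adc <- function(x) x@adc
#' @rdname t2w
#' @export
highb <- function(x) x@highb
#' @rdname t2w
#' @export
tzMask <- function(x) x@tzMask
#' @rdname t2w
#' @export
pzMask <- function(x) x@pzMask
#' @rdname t2w
#' @export
lesionMask <- function(x) x@lesionMask

setMethod("show", "MpMRICase", function(object) {
  d <- dim(object@t2w)
  cat("MpMRICase '", object@caseId, "'\n", sep = "")
  cat("  volume: ", paste(d, collapse = " x "), " voxels at ",
      paste(format(object@spacingMm, digits = 3), collapse = " x "),
      " mm (z, y, x)\n", sep = "")
  cat("  zones:  TZ ", sum(object@tzMask), " voxels, PZ ",
      sum(object@pzMask), " voxels\n", sep = "")
  cat("  lesions: ", nrow(object@lesionTable), sep = "")
  if (nrow(object@lesionTable))
    cat(" (", paste(object@lesionTable$zone, collapse = ", "), ")", sep = "")
  cat("\n")
})

## ---------------------------------------------------------------------------
## Label maps and probability maps
## ---------------------------------------------------------------------------

#' Hierarchical zonal label map
#'
#' Per voxel a two-component binary label vector m = (m0, m1): m = (1, 1) for
#' lesion voxels in the transition zone, (1, 0) for lesion voxels in the
#' peripheral zone, and (0, 0) elsewhere. The first channel (m0) carries the
#' DWI-related lesion evidence common to all lesions, the second (m1) the
#' additional T2WI evidence required for TZ lesions; the pattern (0, 1) is
#' undefined and never occurs, hence m1 <= m0 everywhere.
#'
#' @slot values binary array of dim (2, D, H, W); channel order (m0, m1).
#' @export
setClass("HierLabelMap", representation(values = "array"))

setValidity("HierLabelMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || d[1] != 2L)
    return("values must be a (2, D, H, W) array")
  if (!.isBinary(object@values)) return("values must be binary")
  m0 <- object@values[1, , , ]
  m1 <- object@values[2, , , ]
  if (any(m1 > m0))
    return("undefined label pattern (0, 1): m1 must never exceed m0")
  TRUE
})

#' @describeIn HierLabelMap the (2, D, H, W) label array
#' @export
setMethod("labelValues", "HierLabelMap", function(x) x@values)

#' Plain binary lesion label map (single channel)
#'
#' @slot values binary array of dim (D, H, W); 1 exactly at lesion voxels.
#' @export
setClass("BinaryLabelMap", representation(values = "array"))

setValidity("BinaryLabelMap", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a (D, H, W) array")
  if (!.isBinary(object@values)) return("values must be binary")
  TRUE
})

#' @describeIn BinaryLabelMap the (D, H, W) label array
#' @export
setMethod("labelValues", "BinaryLabelMap", function(x) x@values)

#' Model output probability map
#'
#' A per-voxel probability vector p = (p0, p1) in [0,1]^2 (or a single
#' channel for the binary baseline). Channel p0 scores "lesion anywhere",
#' p1 the additional TZ-lesion evidence.
#'
#' @slot values numeric array of dim (K, D, H, W), K = 1 or 2, values in
#'   [0, 1].
#' @slot spacingMm voxel spacing (z, y, x) mm, carried along so detections
#'   can be placed in world coordinates.
#' @export
setClass("ProbMap",
  representation(values = "array", spacingMm = "numeric"))

setValidity("ProbMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L || !(d[1] %in% c(1L, 2L)))
    return("values must be a (K, D, H, W) array with K in {1, 2}")
  if (any(object@values < 0 | object@values > 1))
    return("probabilities must lie in [0, 1]")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  TRUE
})

#' @describeIn ProbMap the (K, D, H, W) probability array
#' @export
setMethod("probValues", "ProbMap", function(x) x@values)

#' @describeIn ProbMap voxel spacing
#' @export
setMethod("spacingMm", "ProbMap", function(x) x@spacingMm)

#' Construct a ProbMap from an array
#' @param values (K, D, H, W) array of probabilities, or (D, H, W) for a
#'   single-channel map.
#' @param spacingMm voxel spacing (z, y, x) in mm.
#' @export
probMap <- function(values, spacingMm = c(3, 0.625, 0.625)) {
  if (length(dim(values)) == 3L)
    values <- array(values, c(1L, dim(values)))
  new("ProbMap", values = values, spacingMm = as.numeric(spacingMm))
}

## ---------------------------------------------------------------------------
## Loss / model / preprocess / training configuration
## ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @slot gamma focal exponent (>= 0); 0 recovers the plain (modified)
#'   cross-entropy.
#' @slot eps probability clamp before logarithms, in (0, 1e-3].
#' @slot reduction "sum" (sum over voxels) or "mean" (divide by the voxel
#'   count, batch-size independent).
#' @export
setClass("LossConfig",
  representation(gamma = "numeric", eps = "numeric", reduction = "character"))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@eps <= 0 || object@eps > 1e-3)
    msg <- c(msg, "eps must lie in (0, 1e-3]")
  if (!object@reduction %in% c("sum", "mean"))
    msg <- c(msg, "reduction must be 'sum' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' @rdname LossConfig-class
#' @param gamma,eps,reduction see slots.
#' @export
lossConfig <- function(gamma = 2, eps = 1e-7, reduction = "sum") {
  new("LossConfig", gamma = as.numeric(gamma), eps = as.numeric(eps),
      reduction = reduction)
}

#' Network configuration
#'
#' Defaults reproduce the full-size architecture: a three-level
#' encoder-decoder with channel widths (64, 128, 256), four ConvBlocks per
#' encoder level, and a five-channel input stack (T2WI, ADC, high-b DWI, TZ
#' mask, PZ mask). Each ConvBlock is a 3x3x3 convolution followed by a
#' LeakyReLU and an instance normalization. Reduced widths (for CPU-scale
#' experiments) are set through `encoderChannels`.
#'
#' @slot inChannels input channels (default 5).
#' @slot encoderChannels per-level encoder widths, lowest resolution last.
#' @slot decoderChannels per-level decoder widths (reverse of encoder).
#' @slot blocksPerLevel ConvBlocks per encoder level.
#' @slot decoderBlocksPerLevel ConvBlocks per decoder level.
#' @slot outChannels 2 for the hierarchical zonal head, 1 for the binary
#'   baseline.
#' @slot negativeSlope LeakyReLU slope.
#' @slot instanceNorm whether ConvBlocks end with instance normalization.
#' @slot fuseBottom whether to fuse the two paths at the bottleneck as well
#'   (by default only the original-path bottom features feed the decoder).
#' @export
setClass("ModelConfig",
  representation(
    inChannels = "integer", encoderChannels = "integer",
    decoderChannels = "integer", blocksPerLevel = "integer",
    decoderBlocksPerLevel = "integer", outChannels = "integer",
    negativeSlope = "numeric", instanceNorm = "logical",
    fuseBottom = "logical"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  L <- length(object@encoderChannels)
  if (L < 2L) msg <- c(msg, "at least two resolution levels are required")
  if (length(object@decoderChannels) != L)
    msg <- c(msg, "encoder and decoder must have the same number of levels")
  if (!identical(rev(object@encoderChannels), object@decoderChannels))
    msg <- c(msg, "decoderChannels must mirror encoderChannels")
  if (!(object@outChannels %in% c(1L, 2L)))
    msg <- c(msg, "outChannels must be 1 or 2")
  if (object@blocksPerLevel < 1L || object@decoderBlocksPerLevel < 1L)
    msg <- c(msg, "block counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelConfig-class
#' @param inChannels,encoderChannels,blocksPerLevel,decoderBlocksPerLevel,outChannels,negativeSlope,instanceNorm,fuseBottom
#'   see the class slots.
#' @export
modelConfig <- function(inChannels = 5L, encoderChannels = c(64L, 128L, 256L),
                        blocksPerLevel = 4L, decoderBlocksPerLevel = 2L,
                        outChannels = 2L, negativeSlope = 0.01,
                        instanceNorm = TRUE, fuseBottom = FALSE) {
  new("ModelConfig",
      inChannels = as.integer(inChannels),
      encoderChannels = as.integer(encoderChannels),
      decoderChannels = rev(as.integer(encoderChannels)),
      blocksPerLevel = as.integer(blocksPerLevel),
      decoderBlocksPerLevel = as.integer(decoderBlocksPerLevel),
      outChannels = as.integer(outChannels),
      negativeSlope = as.numeric(negativeSlope),
      instanceNorm = isTRUE(instanceNorm), fuseBottom = isTRUE(fuseBottom))
}

#' The symmetric-aware dual-path network
#'
#' One encoder instance processes both the original and the width-mirrored
#' input stack (weight sharing by construction); at every level above the
#' bottleneck the two feature maps are concatenated channel-wise and fused by
#' a BridgeBlock of two ConvBlocks before joining the decoder.
#'
#' @slot config a [ModelConfig-class].
#' @slot params nested list of weight matrices and vectors.
#' @export
setClass("SymNet", representation(config = "ModelConfig", params = "list"))

setMethod("show", "SymNet", function(object) {
  cfg <- object@config
  cat("SymNet: symmetric-aware 3D encoder-decoder\n")
  cat("  levels: ", length(cfg@encoderChannels),
      "  encoder channels: ", paste(cfg@encoderChannels, collapse = ", "),
      "\n", sep = "")
  cat("  input channels: ", cfg@inChannels,
      "  output channels: ", cfg@outChannels, "\n", sep = "")
  cat("  parameters: ", length(.flattenParams(object@params)), "\n", sep = "")
})

#' Preprocessing configuration
#'
#' @slot cropSize (height, width) of the in-plane center crop.
#' @slot adcClipValue patient-independent upper clip for the quantitative ADC
#'   channel, in 1e-6 mm^2/s (default 3000).
#' @slot rotate whether to apply the center-line alignment rotation.
#' @export
setClass("PreprocessConfig",
  representation(cropSize = "integer", adcClipValue = "numeric",
                 rotate = "logical"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (length(object@cropSize) != 2L || any(object@cropSize < 1L))
    msg <- c(msg, "cropSize must be two positive voxel counts")
  if (object@adcClipValue <= 0) msg <- c(msg, "adcClipValue must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PreprocessConfig-class
#' @param cropSize,adcClipValue,rotate see slots.
#' @export
preprocessConfig <- function(cropSize = c(128L, 128L), adcClipValue = 3000,
                             rotate = TRUE) {
  new("PreprocessConfig", cropSize = as.integer(cropSize),
      adcClipValue = as.numeric(adcClipValue), rotate = isTRUE(rotate))
}

#' Training configuration
#'
#' The optimization protocol: Adam, at most 60 epochs, early stopping after
#' 30 epochs without improvement of the training loss (both bounds
#' configurable downwards for CPU-scale runs).
#'
#' @slot epochs maximum epochs.
#' @slot earlyStopPatience epochs without loss improvement before stopping;
#'   0 stops after the first non-improving epoch.
#' @slot learningRate Adam step size.
#' @slot batchSize samples per gradient step.
#' @slot loss "zonal" (hierarchical constrained focal loss, 2-channel head)
#'   or "focal_binary" (plain focal loss on binary labels, 1-channel head).
#' @slot symmetric TRUE for the dual-path (original + mirrored) input; FALSE
#'   feeds the original stack to both encoder inputs, the parameter-matched
#'   single-path ablation.
#' @slot gamma focal exponent used for the training loss.
#' @slot seed governs weight initialization and data order.
#' @export
setClass("TrainConfig",
  representation(
    epochs = "integer", earlyStopPatience = "integer",
    learningRate = "numeric", batchSize = "integer",
    loss = "character", symmetric = "logical", gamma = "numeric",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@earlyStopPatience < 0L ||
      object@earlyStopPatience > object@epochs)
    msg <- c(msg, "earlyStopPatience must lie in [0, epochs]")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@loss %in% c("zonal", "focal_binary"))
    msg <- c(msg, "loss must be 'zonal' or 'focal_binary'")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param epochs,earlyStopPatience,learningRate,batchSize,loss,symmetric,gamma,seed
#'   see the class slots.
#' @export
trainConfig <- function(epochs = 60L, earlyStopPatience = 30L,
                        learningRate = 1e-3, batchSize = 2L,
                        loss = "zonal", symmetric = TRUE, gamma = 2,
                        seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), loss = loss,
      symmetric = isTRUE(symmetric), gamma = as.numeric(gamma),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Detection / FROC results
## ---------------------------------------------------------------------------

#' Adjudicated detections for one case
#'
#' @slot caseId character scalar.
#' @slot points data.frame with one row per detection: z, y, x (1-based voxel
#'   coordinates), score, adjudication ("TP"/"FP"), lesionId (NA for FP).
#' @slot lesions data.frame with one row per ground-truth lesion: lesionId,
#'   bestScore (highest score among its TP detections, NA if none),
#'   detected (any TP at threshold 0).
#' @export
setClass("DetectionSet",
  representation(caseId = "character", points = "data.frame",
                 lesions = "data.frame"))

setValidity("DetectionSet", function(object) {
  msg <- character()
  if (nrow(object@points)) {
    if (!all(object@points$adjudication %in% c("TP", "FP")))
      msg <- c(msg, "every point must be adjudicated TP or FP")
    tp <- object@points$adjudication == "TP"
    if (any(is.na(object@points$lesionId[tp])))
      msg <- c(msg, "TP points must reference a lesion")
    if (any(!is.na(object@points$lesionId[!tp])))
      msg <- c(msg, "FP points must not reference a lesion")
  }
  if (nrow(object@lesions)) {
    det <- object@lesions$lesionId %in%
      object@points$lesionId[object@points$adjudication == "TP"]
    if (!identical(det, object@lesions$detected))
      msg <- c(msg, "detected flags inconsistent with TP assignments")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionSet case identifier
#' @export
setMethod("caseId", "DetectionSet", function(x) x@caseId)

#' @describeIn DetectionSet the adjudicated detection table
#' @export
setMethod("detectionPoints", "DetectionSet", function(x) x@points)

setMethod("show", "DetectionSet", function(object) {
  tp <- sum(object@points$adjudication == "TP")
  fp <- sum(object@points$adjudication == "FP")
  cat("DetectionSet '", object@caseId, "': ", nrow(object@points),
      " points (", tp, " TP, ", fp, " FP); ",
      sum(object@lesions$detected), "/", nrow(object@lesions),
      " lesions detected\n", sep = "")
})

#' FROC analysis result
#'
#' @slot curve data.frame of the full threshold sweep: threshold, meanFP
#'   (mean false positives per patient), sensitivity (lesion-level).
#' @slot operating data.frame with sensitivity (and optional bootstrap CI) at
#'   the standard operating points 0.5, 1, 1.5, 2, 2.5 FP/patient.
#' @slot nCases,nLesions totals over the evaluated set.
#' @export
setClass("FROCResult",
  representation(curve = "data.frame", operating = "data.frame",
                 nCases = "integer", nLesions = "integer"))

setValidity("FROCResult", function(object) {
  s <- object@curve$sensitivity
  if (length(s) && (any(s < 0 | s > 1)))
    return("sensitivities must lie in [0, 1]")
  o <- object@curve[order(object@curve$meanFP), ]
  if (nrow(o) > 1L && any(diff(o$sensitivity) < -1e-12))
    return("sensitivity must be non-decreasing in FP/patient")
  TRUE
})

#' @describeIn FROCResult the full (threshold, meanFP, sensitivity) sweep
#' @export
setMethod("frocCurve", "FROCResult", function(x) x@curve)

#' @describeIn FROCResult step-function sensitivity at a given mean
#'   FP-per-patient budget
#' @param fpPerPatient numeric vector of FP/patient operating points.
#' @export
setMethod("sensitivityAt", "FROCResult", function(x, fpPerPatient) {
  vapply(fpPerPatient, function(f) {
    ok <- x@curve$meanFP <= f + 1e-12
    if (!any(ok)) 0 else max(x@curve$sensitivity[ok])
  }, numeric(1))
})

setMethod("show", "FROCResult", function(object) {
  cat("FROCResult over ", object@nCases, " cases, ", object@nLesions,
      " lesions\n", sep = "")
  op <- object@operating
  for (i in seq_len(nrow(op))) {
    cat(sprintf("  sens @ %.1f FP/patient: %.3f", op$fpPerPatient[i],
                op$sensitivity[i]))
    if (!is.null(op$ciLo) && !is.na(op$ciLo[i]))
      cat(sprintf("  (95%% CI %.3f-%.3f)", op$ciLo[i], op$ciHi[i]))
    cat("\n")
  }
})
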