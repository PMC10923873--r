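# Geometric and intensity standardization: center-line alignment rotation,
# in-plane center cropping, per-modality normalization.
#
# Bias-field correction and inter-sequence registration are upstream
# responsibilities; phantoms are generated pre-aligned.

# in-plane centroid (y, x), intensity-weighted, over a binary volume
.inPlaneCentroid <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  c(mean(idx[, 2]), mean(idx[, 3]))
}

# Rotate every slice of a (D, H, W) volume by `angle` radians about the
# in-plane center. The rotation maps the direction (cos a, sin a) in (h, w)
# onto the +height axis. Bilinear interpolation for images, nearest neighbor
# for masks; out-of-bounds source pixels read as 0.
.rotateInPlane <- function(vol, angle, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(vol)
  H <- d[2]; W <- d[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  u <- g$y - cy; v <- g$x - cx
  ca <- cos(angle); sa <- sin(angle)
  # inverse mapping: source = R(-angle) . out
  sy <- ca * u + sa * v + cy
  sx <- -sa * u + ca * v + cx
  out <- array(0, d)
  if (interp == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    tgt <- cbind(g$y[ok], g$x[ok])
    src <- cbind(ry[ok], rx[ok])
    for (z in seq_len(d[1])) {
      sl <- matrix(0, H, W)
      plane <- vol[z, , ]
      sl[tgt] <- plane[src]
      out[z, , ] <- sl
    }
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    gather <- function(plane, yy, xx) {
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      vals <- numeric(length(yy))
      vals[ok] <- plane[cbind(yy[ok], xx[ok])]
      vals
    }
    tgt <- cbind(g$y, g$x)
    for (z in seq_len(d[1])) {
      plane <- vol[z, , ]
      val <- (1 - fy) * (1 - fx) * gather(plane, y0, x0) +
        (1 - fy) * fx * gather(plane, y0, x0 + 1) +
        fy * (1 - fx) * gather(plane, y0 + 1, x0) +
        fy * fx * gather(plane, y0 + 1, x0 + 1)
      sl <- matrix(0, H, W)
      sl[tgt] <- val
      out[z, , ] <- sl
    }
  }
  out
}

# rebuild the lesion table after a geometric transform by re-labelling the
# transformed lesion mask and matching components to expected centroids
.relabelLesionTable <- function(oldTab, lesionMask, tzMask, pzMask,
                                expected) {
  if (nrow(oldTab) == 0L) return(oldTab)
  d <- dim(lesionMask)
  lab <- .labelComponents26(array(as.integer(lesionMask), d), as.integer(d))
  ncomp <- max(lab)
  cent <- matrix(NA_real_, ncomp, 3)
  zone <- character(ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    cent[k, ] <- colMeans(idx)
    zone[k] <- if (sum(tzMask[lab == k]) >= sum(pzMask[lab == k]))
      "TZ" else "PZ"
  }
  tab <- oldTab
  used <- rep(FALSE, ncomp)
  for (i in seq_len(nrow(tab))) {
    dmat <- sweep(cent, 2, expected[i, ], `-`)
    dist <- rowSums(dmat^2)
    dist[used] <- Inf
    k <- which.min(dist)
    used[k] <- TRUE
    tab$cz[i] <- cent[k, 1]; tab$cy[i] <- cent[k, 2]; tab$cx[i] <- cent[k, 3]
    tab$zone[i] <- zone[k]
  }
  tab
}

#' Align the prostate center line with the vertical axis
#'
#' Computes the in-plane line joining the volumetric centroid of the whole
#' prostate and the centroid of the TZ, and rotates all channels and masks
#' about the in-plane volume center so this line becomes vertical (parallel
#' to the height axis). Images are interpolated bilinearly, masks with
#' nearest neighbor. The applied angle (radians) is attached as attribute
#' `"rotationAngle"`.
#'
#' @param case an [MpMRICase-class].
#' @param prostateMask optional whole-gland binary mask; defaults to the
#'   union of the TZ and PZ masks.
#' @return The rotated [MpMRICase-class].
#' @export
alignCenterAxis <- function(case, prostateMask = NULL) {
  stopifnot(is(case, "MpMRICase"))
  if (is.null(prostateMask))
    prostateMask <- (case@tzMask + case@pzMask > 0) + 0
  if (!any(prostateMask == 1)) stop("empty prostate mask", call. = FALSE)
  if (!any(case@tzMask == 1)) stop("empty TZ mask", call. = FALSE)
  pc <- .inPlaneCentroid(prostateMask)
  tc <- .inPlaneCentroid(case@tzMask)
  dh <- tc[1] - pc[1]; dw <- tc[2] - pc[2]
  angle <- if (abs(dh) < 1e-9 && abs(dw) < 1e-9) 0 else atan2(dw, dh)
  if (abs(angle) < 1e-9) {
    attr(case, "rotationAngle") <- 0
    return(case)
  }
  # applying R(-angle) maps the (dh, dw) centroid direction onto +height
  rotImg <- function(v) .rotateInPlane(v, -angle, "linear")
  rotMsk <- function(v) .rotateInPlane(v, -angle, "nearest")
  newLesion <- rotMsk(case@lesionMask)
  newTz <- rotMsk(case@tzMask)
  newPz <- rotMsk(case@pzMask)
  # zonal masks can overlap by a voxel after independent NN rotation
  newPz[newTz == 1] <- 0
  # lesion voxels rotated out of the zones would violate the case contract
  newLesion[newTz == 0 & newPz == 0] <- 0

  d <- dim(case@lesionMask)
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  ca <- cos(angle); sa <- sin(angle)
  expected <- as.matrix(case@lesionTable[, c("cz", "cy", "cx")])
  if (nrow(expected)) {
    u <- expected[, 2] - cy; v <- expected[, 3] - cx
    expected[, 2] <- ca * u + sa * v + cy
    expected[, 3] <- -sa * u + ca * v + cx
  }
  out <- new("MpMRICase",
             t2w = rotImg(case@t2w), adc = rotImg(case@adc),
             highb = rotImg(case@highb),
             tzMask = newTz, pzMask = newPz, lesionMask = newLesion,
             lesionTable = .relabelLesionTable(case@lesionTable, newLesion,
                                               newTz, newPz, expected),
             spacingMm = case@spacingMm, caseId = case@caseId)
  attr(out, "rotationAngle") <- angle
  out
}

#' Center crop in-plane
#'
#' Crops all channels and masks identically about the in-plane center; the
#' depth axis is untouched. A 320 x 320 plane cropped to 128 x 128 retains
#' index range 97..224 on each in-plane axis (1-based).
#'
#' @param case an [MpMRICase-class].
#' @param cropSize (height, width) in voxels; must not exceed the input.
#' @return The cropped [MpMRICase-class]; lesion centroids are shifted
#'   accordingly.
#' @export
centerCrop <- function(case, cropSize = c(128L, 128L)) {
  stopifnot(is(case, "MpMRICase"))
  d <- dim(case@t2w)
  ch <- as.integer(cropSize[1]); cw <- as.integer(cropSize[2])
  if (ch > d[2] || cw > d[3])
    stop("crop size exceeds input size", call. = FALSE)
  y0 <- (d[2] - ch) %/% 2L
  x0 <- (d[3] - cw) %/% 2L
  ys <- (y0 + 1L):(y0 + ch)
  xs <- (x0 + 1L):(x0 + cw)
  cr <- function(v) v[, ys, xs, drop = FALSE]
  tab <- case@lesionTable
  if (nrow(tab)) { tab$cy <- tab$cy - y0; tab$cx <- tab$cx - x0 }
  new("MpMRICase",
      t2w = cr(case@t2w), adc = cr(case@adc), highb = cr(case@highb),
      tzMask = cr(case@tzMask), pzMask = cr(case@pzMask),
      lesionMask = cr(case@lesionMask),
      lesionTable = tab, spacingMm = case@spacingMm, caseId = case@caseId)
}

#' Normalize the channel intensities
#'
#' T2WI and high-b DWI are min-max scaled to [0, 1] per patient. ADC is
#' quantitative, so it is clipped at the patient-independent
#' `cfg@adcClipValue` and divided by it, preserving the absolute scale
#' across patients. Masks are untouched. Min-max channels are idempotent
#' under re-normalization.
#'
#' @param case an [MpMRICase-class].
#' @param cfg a [PreprocessConfig-class].
#' @return The normalized [MpMRICase-class].
#' @export
normalizeCase <- function(case, cfg = preprocessConfig()) {
  stopifnot(is(case, "MpMRICase"), is(cfg, "PreprocessConfig"))
  minmax <- function(v, nm) {
    r <- range(v)
    if (diff(r) == 0)
      stop("constant ", nm, " volume: normalization is degenerate",
           call. = FALSE)
    (v - r[1]) / diff(r)
  }
  adc <- pmin(pmax(case@adc, 0), cfg@adcClipValue) / cfg@adcClipValue
  new("MpMRICase",
      t2w = minmax(case@t2w, "t2w"), adc = adc,
      highb = minmax(case@highb, "highb"),
      tzMask = case@tzMask, pzMask = case@pzMask,
      lesionMask = case@lesionMask,
      lesionTable = case@lesionTable, spacingMm = case@spacingMm,
      caseId = case@caseId)
}

#' Full preprocessing chain
#'
#' Rotation (optional), center crop, normalization. Provenance (rotation
#' angle, crop, clip value) can be written to a JSON sidecar.
#'
#' @param case an [MpMRICase-class].
#' @param cfg a [PreprocessConfig-class].
#' @param sidecar optional path of a JSON provenance file.
#' @return The preprocessed [MpMRICase-class].
#' @export
preprocessCase <- function(case, cfg = preprocessConfig(), sidecar = NULL) {
  angle <- 0
  if (cfg@rotate) {
    case <- alignCenterAxis(case)
    angle <- attr(case, "rotationAngle")
  }
  case <- centerCrop(case, cfg@cropSize)
  case <- normalizeCase(case, cfg)
  if (!is.null(sidecar)) {
    jsonlite::write_json(
      list(case_id = case@caseId, rotation_angle_rad = angle,
           crop_size = as.integer(cfg@cropSize),
           adc_clip_value = cfg@adcClipValue),
      sidecar, auto_unbox = TRUE, digits = NA)
  }
  case
}
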