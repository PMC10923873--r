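# Label encodings: the plain binary lesion labeling and the hierarchical
# zonal labeling the zonal loss trains against.

#' Encode the hierarchical zonal label map
#'
#' Per voxel v the two-channel label is (1, 1) if v is a lesion voxel in the
#' transition zone, (1, 0) if a lesion voxel in the peripheral zone, and
#' (0, 0) otherwise. Channel m0 is the DWI-related evidence shared by all
#' lesions; m1 is the additional T2WI evidence specific to TZ lesions, so
#' the pattern (0, 1) cannot occur.
#'
#' Lesion voxels falling outside both zonal masks (zonal-mask imperfection in
#' real data) are encoded (1, 0): they still carry the common lesion signal
#' but no TZ-specific evidence. A warning reports how many voxels took this
#' fallback.
#'
#' @param lesionMask,tzMask,pzMask binary (D, H, W) arrays on the same grid;
#'   TZ and PZ must be disjoint.
#' @return A [HierLabelMap-class].
#' @examples
#' m <- array(0, c(2, 4, 4)); m[1, 2, 2] <- 1
#' tz <- array(0, c(2, 4, 4)); tz[1, , ] <- 1
#' pz <- array(0, c(2, 4, 4)); pz[2, , ] <- 1
#' labelValues(encodeHierarchical(m, tz, pz))[, 1, 2, 2]  # c(1, 1)
#' @export
encodeHierarchical <- function(lesionMask, tzMask, pzMask) {
  d <- .checkSameDim(lesionMask, tzMask, pzMask)
  for (m in list(lesionMask, tzMask, pzMask))
    if (!.isBinary(m)) stop("masks must be binary", call. = FALSE)
  if (any(tzMask == 1 & pzMask == 1))
    stop("tzMask and pzMask overlap", call. = FALSE)
  outside <- sum(lesionMask == 1 & tzMask == 0 & pzMask == 0)
  if (outside > 0)
    warning(outside, " lesion voxel(s) outside TZ and PZ encoded as (1, 0)",
            call. = FALSE)
  vals <- array(0, c(2L, d))
  vals[1, , , ] <- lesionMask
  vals[2, , , ] <- lesionMask * tzMask
  new("HierLabelMap", values = vals)
}

#' Encode the plain binary lesion label map
#'
#' The identity encoding: 1 at lesion voxels, 0 elsewhere. Used by the
#' binary focal-loss baseline.
#'
#' @param lesionMask binary (D, H, W) array.
#' @return A [BinaryLabelMap-class].
#' @export
encodeBinary <- function(lesionMask) {
  if (length(dim(lesionMask)) != 3L)
    stop("lesionMask must be a 3-D array", call. = FALSE)
  if (!.isBinary(lesionMask))
    stop("lesionMask must be binary", call. = FALSE)
  new("BinaryLabelMap", values = lesionMask + 0)
}
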