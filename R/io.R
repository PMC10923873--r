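# On-disk representation of a case: one NIfTI volume per channel and mask,
# the lesion table as CSV, and a small YAML header. Internal arrays are
# (depth, height, width) = (z, y, x); NIfTI stores (x, y, z), so volumes are
# transposed on the way in and out and pixdim carries the spacing.

.niftiNames <- c(t2w = "t2w.nii.gz", adc = "adc.nii.gz",
                 highb = "highb.nii.gz", tzMask = "tz_mask.nii.gz",
                 pzMask = "pz_mask.nii.gz", lesionMask = "lesion_mask.nii.gz")

.writeVolumeNifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(aperm(vol, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(spacing)
  RNifti::writeNifti(img, path)
}

.readVolumeNifti <- function(path) {
  if (!file.exists(path))
    stop("missing volume file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  list(vol = aperm(as.array(img), c(3, 2, 1)),
       spacing = rev(RNifti::pixdim(img)[1:3]))
}

#' Write a case to a directory
#'
#' Writes one gzipped NIfTI file per channel and mask, the lesion table as
#' `lesions.csv` (columns case_id, lesion_id, zone, cz, cy, cx, radius_mm)
#' and a `case.yaml` header with the case id and spacing.
#'
#' @param case an [MpMRICase-class].
#' @param directory output directory, created if needed.
#' @return Invisibly, the paths written.
#' @seealso [readCase()]
#' @export
writeCase <- function(case, directory) {
  stopifnot(is(case, "MpMRICase"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(.niftiNames)) {
    p <- file.path(directory, .niftiNames[[nm]])
    .writeVolumeNifti(slot(case, nm), case@spacingMm, p)
    paths <- c(paths, p)
  }
  tab <- case@lesionTable
  csv <- data.frame(case_id = rep(case@caseId, nrow(tab)),
                    lesion_id = tab$lesionId, zone = tab$zone,
                    cz = tab$cz, cy = tab$cy, cx = tab$cx,
                    radius_mm = tab$radiusMm)
  csvPath <- file.path(directory, "lesions.csv")
  utils::write.csv(csv, csvPath, row.names = FALSE)
  metaPath <- file.path(directory, "case.yaml")
  yaml::write_yaml(list(case_id = case@caseId,
                        spacing_mm = as.numeric(case@spacingMm)), metaPath)
  invisible(c(paths, csvPath, metaPath))
}

#' Read a case written by [writeCase()]
#'
#' @param directory directory containing the case files; a missing volume,
#'   table or header raises an error naming the offending path.
#' @return An [MpMRICase-class].
#' @export
readCase <- function(directory) {
  vols <- list()
  spacing <- NULL
  for (nm in names(.niftiNames)) {
    r <- .readVolumeNifti(file.path(directory, .niftiNames[[nm]]))
    vols[[nm]] <- r$vol
    spacing <- r$spacing
  }
  csvPath <- file.path(directory, "lesions.csv")
  if (!file.exists(csvPath))
    stop("missing lesion table: ", csvPath, call. = FALSE)
  csv <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  metaPath <- file.path(directory, "case.yaml")
  if (!file.exists(metaPath))
    stop("missing case header: ", metaPath, call. = FALSE)
  meta <- yaml::read_yaml(metaPath)
  tab <- data.frame(lesionId = as.integer(csv$lesion_id),
                    zone = as.character(csv$zone),
                    cz = csv$cz, cy = csv$cy, cx = csv$cx,
                    radiusMm = csv$radius_mm)
  new("MpMRICase",
      t2w = vols$t2w, adc = vols$adc, highb = vols$highb,
      tzMask = round(vols$tzMask), pzMask = round(vols$pzMask),
      lesionMask = round(vols$lesionMask),
      lesionTable = tab,
      spacingMm = as.numeric(meta$spacing_mm),
      caseId = as.character(meta$case_id))
}

#' Read or write a phantom spec as YAML
#' @param spec a [PhantomSpec-class].
#' @param path YAML file path.
#' @export
writePhantomSpec <- function(spec, path) {
  yaml::write_yaml(list(
    volume_shape = as.integer(spec@volumeShape),
    spacing_mm = as.numeric(spec@spacingMm),
    n_lesions_tz = spec@nLesionsTZ, n_lesions_pz = spec@nLesionsPZ,
    n_symmetric_mimic_pairs = spec@nMimicPairs,
    lesion_radius_mm = as.numeric(spec@lesionRadiusMm),
    lesion_contrast_tz = as.numeric(spec@lesionContrastTZ),
    lesion_contrast_pz = as.numeric(spec@lesionContrastPZ),
    mimic_contrast = as.numeric(spec@mimicContrast),
    noise_sigma = spec@noiseSigma, seed = spec@seed), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  phantomSpec(volumeShape = y$volume_shape, spacingMm = y$spacing_mm,
              nLesionsTZ = y$n_lesions_tz, nLesionsPZ = y$n_lesions_pz,
              nMimicPairs = y$n_symmetric_mimic_pairs,
              lesionRadiusMm = y$lesion_radius_mm,
              lesionContrastTZ = y$lesion_contrast_tz,
              lesionContrastPZ = y$lesion_contrast_pz,
              mimicContrast = y$mimic_contrast,
              noiseSigma = y$noise_sigma, seed = y$seed)
}
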