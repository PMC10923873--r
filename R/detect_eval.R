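# Detection and evaluation: local-maxima candidate extraction, 5 mm
# adjudication against ground truth, FROC analysis, patient-level ROC and
# bootstrap confidence intervals, and the cross-validation splitter.

#' Extract scored detection points from a probability map
#'
#' Detection candidates are the strict local maxima of the detection channel
#' over the 26-neighborhood with score >= `minScore`; maxima lying within
#' `minSeparationMm` (world distance) of a higher-scoring maximum are
#' greedily suppressed. Points are returned sorted by descending score.
#'
#' @param probMap a [ProbMap-class] (or plain (D, H, W) array plus
#'   `spacingMm`).
#' @param minScore minimum probability for a candidate (default 0.1).
#' @param minSeparationMm non-maximum-suppression radius in mm (default 5).
#' @param channel detection score channel: "p0" (lesion-anywhere, the
#'   default), "p1", or "max" (element-wise maximum of the two).
#' @param spacingMm spacing override when `probMap` is a plain array.
#' @return data.frame with columns z, y, x (1-based voxel coordinates),
#'   score, wz, wy, wx (world mm).
#' @export
extractDetections <- function(probMap, minScore = 0.1, minSeparationMm = 5,
                              channel = c("p0", "p1", "max"),
                              spacingMm = NULL) {
  channel <- match.arg(channel)
  if (is(probMap, "ProbMap")) {
    vals <- probMap@values
    spacing <- probMap@spacingMm
    k <- dim(vals)[1]
    vol <- switch(channel,
      p0 = array(vals[1, , , ], dim(vals)[-1]),
      p1 = {
        if (k < 2L) stop("map has no second channel", call. = FALSE)
        array(vals[2, , , ], dim(vals)[-1])
      },
      max = if (k == 1L) array(vals[1, , , ], dim(vals)[-1]) else
        array(pmax(vals[1, , , ], vals[2, , , ]), dim(vals)[-1]))
  } else {
    vol <- probMap
    spacing <- spacingMm
    if (is.null(spacing)) stop("spacingMm required for a plain array",
                               call. = FALSE)
  }
  lm <- .localMaxima26(as.numeric(vol), as.integer(dim(vol)), minScore)
  pts <- data.frame(z = lm$z, y = lm$y, x = lm$x, score = lm$score)
  pts <- pts[order(-pts$score, pts$z, pts$y, pts$x), , drop = FALSE]
  if (nrow(pts) > 1L && minSeparationMm > 0) {
    w <- .voxelToWorld(as.matrix(pts[, c("z", "y", "x")]), spacing)
    keep <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))[-1]) {
      prior <- which(keep[seq_len(i - 1L)])
      if (length(prior)) {
        dmin <- min(sqrt(rowSums((w[prior, , drop = FALSE] -
                                  matrix(w[i, ], length(prior), 3,
                                         byrow = TRUE))^2)))
        if (dmin < minSeparationMm) keep[i] <- FALSE
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  w <- .voxelToWorld(as.matrix(pts[, c("z", "y", "x")]), spacing)
  pts$wz <- w[, 1]; pts$wy <- w[, 2]; pts$wx <- w[, 3]
  rownames(pts) <- NULL
  pts
}

#' Adjudicate detection points against the ground-truth lesions
#'
#' A point is a true positive iff its Euclidean world-space distance to the
#' nearest lesion-mask voxel center is at most `radiusMm` (default 5 mm,
#' absorbing specimen/MRI registration mismatch); it is assigned to the
#' lesion containing that nearest voxel. A lesion counts as detected when at
#' least one TP point maps to it; extra TP points on the same lesion do not
#' become false positives. Adjudication is independent of point ordering.
#'
#' @param points detection data.frame from [extractDetections()].
#' @param case the [MpMRICase-class] holding lesion mask and table.
#' @param radiusMm TP distance threshold in mm.
#' @return A [DetectionSet-class].
#' @export
adjudicateDetections <- function(points, case, radiusMm = 5) {
  stopifnot(is(case, "MpMRICase"))
  spacing <- case@spacingMm
  if (length(spacing) != 3L || any(is.na(spacing)))
    stop("case spacing is missing", call. = FALSE)
  d <- dim(case@lesionMask)
  lab <- .labelComponents26(array(as.integer(case@lesionMask), d),
                            as.integer(d))
  ncomp <- if (any(case@lesionMask == 1)) max(lab) else 0L
  # map connected components to annotated lesion ids via nearest centroid
  compToId <- integer(ncomp)
  if (ncomp > 0L) {
    tabC <- as.matrix(case@lesionTable[, c("cz", "cy", "cx")])
    for (k in seq_len(ncomp)) {
      ck <- colMeans(which(lab == k, arr.ind = TRUE))
      compToId[k] <- case@lesionTable$lesionId[
        which.min(rowSums(sweep(tabC, 2, ck, `-`)^2))]
    }
  }
  n <- nrow(points)
  adjudication <- character(n)
  lesionId <- rep(NA_integer_, n)
  if (ncomp > 0L) {
    vox <- which(case@lesionMask == 1, arr.ind = TRUE)
    voxW <- .voxelToWorld(vox, spacing)
    voxComp <- lab[vox]
    for (i in seq_len(n)) {
      pw <- c(points$wz[i], points$wy[i], points$wx[i])
      d2 <- rowSums(sweep(voxW, 2, pw, `-`)^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= radiusMm) {
        adjudication[i] <- "TP"
        lesionId[i] <- compToId[voxComp[j]]
      } else adjudication[i] <- "FP"
    }
  } else if (n > 0L) {
    adjudication[] <- "FP"
  }
  pts <- points
  pts$adjudication <- if (n) adjudication else character(0)
  pts$lesionId <- if (n) lesionId else integer(0)
  ids <- case@lesionTable$lesionId
  best <- vapply(ids, function(id) {
    s <- pts$score[pts$adjudication == "TP" & pts$lesionId == id]
    if (length(s)) max(s) else NA_real_
  }, numeric(1))
  lesions <- data.frame(lesionId = ids, bestScore = best,
                        detected = !is.na(best))
  new("DetectionSet", caseId = case@caseId, points = pts, lesions = lesions)
}

#' FROC analysis over a set of cases
#'
#' Sweeps a score threshold over the union of all detection scores. At each
#' threshold the lesion-level sensitivity (detected lesions / all lesions)
#' and the mean number of FP points per patient are recorded. Sensitivity at
#' the standard operating points (0.5, 1, 1.5, 2, 2.5 FP/patient) follows
#' the step-function convention: the highest sensitivity among thresholds
#' whose mean FP rate does not exceed the operating point, so reported
#' numbers are reproducible bit for bit. Optional patient-resampling
#' bootstrap CIs.
#'
#' @param detSets list of [DetectionSet-class], one per case (cases without
#'   lesions contribute FPs only).
#' @param fpPerPatient operating points.
#' @param nBoot bootstrap replicates (0 disables CIs).
#' @param level CI level.
#' @param seed RNG seed for the bootstrap.
#' @return A [FROCResult-class].
#' @export
computeFROC <- function(detSets, fpPerPatient = c(0.5, 1, 1.5, 2, 2.5),
                        nBoot = 0L, level = 0.95, seed = 1L) {
  stopifnot(length(detSets) >= 1L)
  nLesions <- sum(vapply(detSets, function(s) nrow(s@lesions), integer(1)))
  if (nLesions == 0L)
    stop("no lesions in the evaluated set: sensitivity is undefined",
         call. = FALSE)
  core <- function(sets) {
    nCases <- length(sets)
    nles <- sum(vapply(sets, function(s) nrow(s@lesions), integer(1)))
    fpScores <- unlist(lapply(sets, function(s)
      s@points$score[s@points$adjudication == "FP"]))
    tpBest <- unlist(lapply(sets, function(s)
      s@lesions$bestScore[!is.na(s@lesions$bestScore)]))
    thr <- sort(unique(c(fpScores, tpBest)), decreasing = TRUE)
    if (!length(thr)) thr <- 1
    meanFP <- vapply(thr, function(t) sum(fpScores >= t) / nCases,
                     numeric(1))
    sens <- vapply(thr, function(t) sum(tpBest >= t) / max(nles, 1L),
                   numeric(1))
    curve <- data.frame(threshold = c(Inf, thr),
                        meanFP = c(0, meanFP),
                        sensitivity = c(0, sens))
    opSens <- vapply(fpPerPatient, function(f) {
      ok <- curve$meanFP <= f + 1e-12
      if (!any(ok)) 0 else max(curve$sensitivity[ok])
    }, numeric(1))
    list(curve = curve, opSens = opSens)
  }
  full <- core(detSets)
  op <- data.frame(fpPerPatient = fpPerPatient, sensitivity = full$opSens,
                   ciLo = NA_real_, ciHi = NA_real_)
  if (nBoot > 0L) {
    reps <- withr::with_seed(seed, {
      replicate(nBoot, {
        idx <- sample.int(length(detSets), replace = TRUE)
        sets <- detSets[idx]
        if (sum(vapply(sets, function(s) nrow(s@lesions), integer(1))) == 0L)
          rep(NA_real_, length(fpPerPatient))
        else core(sets)$opSens
      })
    })
    a <- (1 - level) / 2
    qs <- apply(matrix(reps, nrow = length(fpPerPatient)), 1, function(v)
      stats::quantile(v, c(a, 1 - a), na.rm = TRUE))
    op$ciLo <- qs[1, ]; op$ciHi <- qs[2, ]
  }
  new("FROCResult", curve = full$curve, operating = op,
      nCases = length(detSets), nLesions = as.integer(nLesions))
}

#' Mean FP/patient needed to reach a target sensitivity
#'
#' The smallest mean FP-per-patient on the FROC curve whose sensitivity is
#' at least `sensitivity`; `Inf` when the curve never reaches it.
#'
#' @param froc a [FROCResult-class].
#' @param sensitivity target lesion-level sensitivity.
#' @export
fpAtSensitivity <- function(froc, sensitivity = 0.8) {
  ok <- froc@curve$sensitivity >= sensitivity - 1e-12
  if (!any(ok)) Inf else min(froc@curve$meanFP[ok])
}

#' Patient-level score of a probability map
#'
#' The highest value of the detection channel (p0), used as the patient's
#' probability of harboring clinically significant cancer.
#'
#' @param probMap a [ProbMap-class] or plain array.
#' @export
patientScore <- function(probMap) {
  if (is(probMap, "ProbMap")) {
    v <- probMap@values
    return(max(v[1, , , ]))
  }
  max(probMap)
}

#' Area under the ROC curve
#'
#' Computed via the rank-based Mann-Whitney statistic (tie-aware): the
#' probability that a random positive scores above a random negative, with
#' ties counting one half.
#'
#' @param scores numeric predictions.
#' @param labels binary class labels (0/1 or logical).
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Percentile bootstrap confidence interval over patients
#'
#' Resamples the case list with replacement and returns the percentile
#' interval of `metricFn` over `nBoot` replicates. Replicates where the
#' metric is undefined (e.g. a single-class AUC resample) are dropped.
#'
#' @param metricFn function taking a list of cases and returning a scalar.
#' @param cases list (or vector) of per-patient objects.
#' @param nBoot replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return c(lo, hi).
#' @export
bootstrapCI <- function(metricFn, cases, nBoot = 1000L, level = 0.95,
                        seed = 1L) {
  vals <- withr::with_seed(seed, {
    replicate(nBoot, {
      idx <- sample.int(length(cases), replace = TRUE)
      tryCatch(metricFn(cases[idx]), error = function(e) NA_real_)
    })
  })
  a <- (1 - level) / 2
  q <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Random k-fold cross-validation splits
#'
#' Partitions the ids into k folds whose sizes differ by at most one,
#' reproducibly under the seed. 652 patients at k = 5 yield folds of
#' 131/131/130/130/130.
#'
#' @param caseIds vector of case identifiers.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment (1..k) named by case id.
#' @export
makeCVSplits <- function(caseIds, k = 5L, seed = 1L) {
  n <- length(caseIds)
  if (k > n) stop("k exceeds the number of cases", call. = FALSE)
  fold <- withr::with_seed(seed, {
    rep_len(seq_len(k), n)[sample.int(n)]
  })
  names(fold) <- as.character(caseIds)
  fold
}

#' Write detections to CSV
#'
#' Columns: case_id, z, y, x, score, adjudication.
#'
#' @param detSets list of [DetectionSet-class].
#' @param path output CSV path.
#' @export
writeDetectionsCSV <- function(detSets, path) {
  rows <- lapply(detSets, function(s) {
    if (!nrow(s@points)) return(NULL)
    data.frame(case_id = s@caseId, z = s@points$z, y = s@points$y,
               x = s@points$x, score = s@points$score,
               adjudication = s@points$adjudication)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(case_id = character(), z = integer(), y = integer(),
                      x = integer(), score = numeric(),
                      adjudication = character())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
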