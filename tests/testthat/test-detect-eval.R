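# analytic probability map: a sum of Gaussian bumps on a (D, H, W) grid
bumpMap <- function(d, centers, heights, sigmaVox = 2) {
  v <- array(0, d)
  idx <- which(v == 0, arr.ind = TRUE)
  for (i in seq_along(heights)) {
    c0 <- centers[[i]]
    r2 <- (idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2 + (idx[, 3] - c0[3])^2
    v[idx] <- v[idx] + heights[i] * exp(-r2 / (2 * sigmaVox^2))
  }
  pmin(v, 1)
}

test_that("a single smooth bump yields one detection at its peak", {
  v <- bumpMap(c(8L, 24L, 24L), list(c(4, 12, 12)), 0.9)
  pts <- extractDetections(probMap(v, c(3, 1, 1)))
  expect_identical(nrow(pts), 1L)
  expect_identical(unlist(pts[1, c("z", "y", "x")], use.names = FALSE),
                   c(4L, 12L, 12L))
  expect_equal(pts$score[1], max(v))
})

test_that("a constant map has no strict local maxima", {
  v <- array(0.7, c(4L, 8L, 8L))
  expect_identical(nrow(extractDetections(probMap(v, c(3, 1, 1)))), 0L)
})

test_that("well-separated bumps give one detection each", {
  v <- bumpMap(c(8L, 32L, 32L), list(c(4, 8, 8), c(4, 24, 24)), c(0.9, 0.6))
  pts <- extractDetections(probMap(v, c(3, 1, 1)), minSeparationMm = 5)
  expect_identical(nrow(pts), 2L)
  expect_true(all(diff(pts$score) < 0))   # sorted by descending score
  # pushing the separation radius above their distance suppresses the weaker
  ptsWide <- extractDetections(probMap(v, c(3, 1, 1)),
                               minSeparationMm = 50)
  expect_identical(nrow(ptsWide), 1L)
  expect_equal(ptsWide$score[1], max(v))
})

test_that("adjudication applies the 5 mm world-distance rule", {
  case <- boxCase(lesionVox = c(2L, 6L, 8L), spacing = c(3, 0.625, 0.625))
  mkpts <- function(vox) {
    w <- (vox - 1) * c(3, 0.625, 0.625)
    data.frame(z = vox[1], y = vox[2], x = vox[3], score = 0.9,
               wz = w[1], wy = w[2], wx = w[3])
  }
  # at the lesion voxel: distance 0 -> TP
  ds <- adjudicateDetections(mkpts(c(2L, 6L, 8L)), case)
  expect_identical(ds@points$adjudication, "TP")
  expect_true(ds@lesions$detected[1])
  # 16 in-plane voxels = 10 mm -> FP
  ds2 <- adjudicateDetections(mkpts(c(2L, 6L, 24L)), case)
  expect_identical(ds2@points$adjudication, "FP")
  expect_false(ds2@lesions$detected[1])
  # empty detection list: no TP, no FP, lesion undetected
  empty <- mkpts(c(2L, 6L, 8L))[0, ]
  ds3 <- adjudicateDetections(empty, case)
  expect_identical(nrow(ds3@points), 0L)
  expect_false(ds3@lesions$detected[1])
})

test_that("multiple TP points on one lesion never become FPs", {
  case <- boxCase(lesionVox = c(2L, 6L, 8L), spacing = c(3, 0.625, 0.625))
  w <- function(vox) (vox - 1) * c(3, 0.625, 0.625)
  pts <- data.frame(z = c(2L, 2L), y = c(6L, 6L), x = c(8L, 10L),
                    score = c(0.9, 0.7))
  ww <- rbind(w(c(2, 6, 8)), w(c(2, 6, 10)))
  pts$wz <- ww[, 1]; pts$wy <- ww[, 2]; pts$wx <- ww[, 3]
  ds <- adjudicateDetections(pts, case)
  expect_identical(ds@points$adjudication, c("TP", "TP"))
  expect_identical(sum(ds@lesions$detected), 1L)
  # ordering of the points does not change the verdicts
  ds2 <- adjudicateDetections(pts[2:1, ], case)
  expect_setequal(paste(ds2@points$x, ds2@points$adjudication),
                  paste(ds@points$x, ds@points$adjudication))
})

# assemble a DetectionSet directly, for controlled FROC inputs
mkDetSet <- function(id, tpScores, fpScores, nLesions = length(tpScores)) {
  n <- length(tpScores) + length(fpScores)
  pts <- data.frame(
    z = seq_len(n), y = rep(1L, n), x = rep(1L, n),
    score = c(tpScores, fpScores),
    wz = rep(0, n), wy = rep(0, n), wx = rep(0, n),
    adjudication = c(rep("TP", length(tpScores)),
                     rep("FP", length(fpScores))),
    lesionId = c(seq_along(tpScores),
                 rep(NA_integer_, length(fpScores))))
  lesions <- data.frame(
    lesionId = seq_len(nLesions),
    bestScore = c(tpScores, rep(NA_real_, nLesions - length(tpScores))),
    detected = c(rep(TRUE, length(tpScores)),
                 rep(FALSE, nLesions - length(tpScores))))
  new("DetectionSet", caseId = id, points = pts, lesions = lesions)
}

test_that("a perfect detector has sensitivity 1 at every operating point", {
  sets <- list(mkDetSet("a", 0.9, numeric(0)),
               mkDetSet("b", c(0.8, 0.7), numeric(0)))
  froc <- computeFROC(sets)
  expect_true(all(froc@operating$sensitivity == 1))
})

test_that("the 2-patient toy sweep reproduces the hand enumeration", {
  # A: one lesion hit at 0.9, an FP at 0.4; B: no lesion, an FP at 0.6
  sets <- list(mkDetSet("A", 0.9, 0.4),
               mkDetSet("B", numeric(0), 0.6, nLesions = 0L))
  froc <- computeFROC(sets)
  # hand enumeration over thresholds {0.9, 0.6, 0.4}:
  #   t=0.9: sens 1, meanFP 0;  t=0.6: sens 1, meanFP 0.5;
  #   t=0.4: sens 1, meanFP 1
  expect_equal(froc@curve$meanFP, c(0, 0, 0.5, 1))
  expect_equal(froc@curve$sensitivity, c(0, 1, 1, 1))
  expect_equal(sensitivityAt(froc, 0.5), 1.0)
  expect_equal(unname(froc@operating$sensitivity), rep(1, 5))
})

test_that("FROC sensitivity is monotone in the FP budget on random sets", {
  set.seed(77)
  for (rep in 1:20) {
    sets <- lapply(1:6, function(i) {
      nL <- sample(0:2, 1)
      nT <- if (nL > 0) sample(0:nL, 1) else 0
      mkDetSet(paste0("c", i), runif(nT), runif(sample(0:4, 1)),
               nLesions = nL)
    })
    if (sum(vapply(sets, function(s) nrow(s@lesions), integer(1))) == 0)
      next
    froc <- computeFROC(sets)
    s <- sensitivityAt(froc, c(0.5, 1, 1.5, 2, 2.5))
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("an all-negative set has undefined sensitivity", {
  sets <- list(mkDetSet("neg", numeric(0), 0.5, nLesions = 0L))
  expect_error(computeFROC(sets), "undefined")
})

test_that("the patient score is the maximum of the detection channel", {
  v <- array(0, c(1, 2, 4, 4))
  expect_equal(patientScore(new("ProbMap", values = v,
                                spacingMm = c(3, 1, 1))), 0)
  v[1, 1, 2, 3] <- 0.93
  pm <- new("ProbMap", values = v, spacingMm = c(3, 1, 1))
  expect_equal(patientScore(pm), 0.93)
  mirrored <- new("ProbMap", values = mirrorStack(v), spacingMm = c(3, 1, 1))
  expect_equal(patientScore(mirrored), patientScore(pm))
})

test_that("AUC matches brute-force pair enumeration", {
  bruteAUC <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  # swapping the middle pair misranks one positive-negative pair
  expect_equal(rocAUC(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)          # rounded to force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAUC(scores, labels), bruteAUC(scores, labels))
  }
  expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAUC(scores, labels), ref, tolerance = 1e-12)
})

test_that("labels independent of scores give AUC near 0.5", {
  set.seed(100)
  scores <- runif(4000)
  labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(rocAUC(scores, labels) - 0.5), 0.05)
})

test_that("the patient bootstrap brackets the point estimate", {
  set.seed(55)
  cases <- as.list(rnorm(80, mean = 2))
  metric <- function(cs) mean(unlist(cs))
  ci <- bootstrapCI(metric, cases, nBoot = 500, seed = 3L)
  est <- metric(cases)
  expect_lt(ci[1], est)
  expect_gt(ci[2], est)
  # reproducible under the seed
  expect_identical(ci, bootstrapCI(metric, cases, nBoot = 500, seed = 3L))
})

test_that("5-fold splits of 652 ids have sizes 131/131/130/130/130", {
  ids <- sprintf("case%03d", 1:652)
  fold <- makeCVSplits(ids, k = 5, seed = 42L)
  expect_identical(sort(as.integer(table(fold)), decreasing = TRUE),
                   c(131L, 131L, 130L, 130L, 130L))
  expect_setequal(names(fold), ids)
  expect_identical(fold, makeCVSplits(ids, k = 5, seed = 42L))
  expect_false(identical(fold, makeCVSplits(ids, k = 5, seed = 43L)))
  expect_error(makeCVSplits(ids[1:3], k = 5), "exceeds")
})

test_that("detections round-trip to CSV", {
  sets <- list(mkDetSet("A", 0.9, 0.4), mkDetSet("B", numeric(0), 0.6, 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDetectionsCSV(sets, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 3L)
  expect_setequal(unique(df$case_id), c("A", "B"))
})
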