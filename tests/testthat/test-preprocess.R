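# a hand-built case whose TZ centroid can be placed at an arbitrary angle
# from the prostate centroid, to exercise the alignment rotation
angledCase <- function(angleDeg) {
  D <- 2L; H <- 64L; W <- 64L
  z <- array(0, c(D, H, W))
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  pros <- (g$y - cy)^2 / 24^2 + (g$x - cx)^2 / 24^2 <= 1
  th <- angleDeg * pi / 180
  ty <- cy + 10 * cos(th); tx <- cx + 10 * sin(th)
  tz <- (g$y - ty)^2 / 8^2 + (g$x - tx)^2 / 8^2 <= 1
  prosM <- matrix(0, H, W); prosM[cbind(g$y, g$x)[pros, ]] <- 1
  tzM <- matrix(0, H, W); tzM[cbind(g$y, g$x)[tz, ]] <- 1
  pzM <- prosM * (1 - tzM)
  mk <- function(m) { a <- z; for (i in 1:D) a[i, , ] <- m; a }
  img <- mk(prosM * 50 + tzM * 30) + 10
  new("MpMRICase", t2w = img, adc = img * 10, highb = img / 2,
      tzMask = mk(tzM), pzMask = mk(pzM), lesionMask = z,
      lesionTable = data.frame(lesionId = integer(), zone = character(),
                               cz = numeric(), cy = numeric(),
                               cx = numeric(), radiusMm = numeric()),
      spacingMm = c(3, 1, 1), caseId = "angled")
}

tzOffsetAngle <- function(case) {
  pros <- (tzMask(case) + pzMask(case) > 0) + 0
  pc <- SymZonal:::.inPlaneCentroid(pros)
  tc <- SymZonal:::.inPlaneCentroid(tzMask(case))
  atan2(tc[2] - pc[2], tc[1] - pc[1])
}

test_that("already-aligned cases pass through unchanged", {
  case <- angledCase(0)
  out <- alignCenterAxis(case)
  expect_equal(attr(out, "rotationAngle"), 0)
  expect_identical(out@t2w, case@t2w)
  expect_identical(out@tzMask, case@tzMask)
})

test_that("rotation brings the prostate-TZ centroid line to vertical", {
  for (deg in c(35, -60, 90)) {
    case <- angledCase(deg)
    before <- tzOffsetAngle(case)
    expect_equal(before, deg * pi / 180, tolerance = 0.05)
    out <- alignCenterAxis(case)
    expect_equal(attr(out, "rotationAngle"), before, tolerance = 1e-9)
    after <- tzOffsetAngle(out)
    # residual in-plane offset of the line below one voxel over a 10-voxel arm
    expect_lt(abs(10 * sin(after)), 1)
  }
})

test_that("nearest-neighbor rotation preserves mask volume within 2%", {
  case <- angledCase(40)
  out <- alignCenterAxis(case)
  for (m in c("tzMask", "pzMask")) {
    n0 <- sum(slot(case, m)); n1 <- sum(slot(out, m))
    expect_lt(abs(n1 - n0) / n0, 0.02)
  }
})

test_that("all channels and masks receive the identical transform", {
  case <- angledCase(25)
  out <- alignCenterAxis(case)
  angle <- attr(out, "rotationAngle")
  # every image channel equals the shared rotation applied directly, and
  # every mask the shared nearest-neighbor rotation
  for (s in c("t2w", "adc", "highb"))
    expect_identical(slot(out, s),
                     SymZonal:::.rotateInPlane(slot(case, s), -angle,
                                               "linear"))
  expect_identical(out@tzMask,
                   SymZonal:::.rotateInPlane(case@tzMask, -angle, "nearest"))
})

test_that("empty masks are rejected", {
  case <- angledCase(10)
  case@tzMask[] <- 0
  case@pzMask[(case@tzMask + case@pzMask) > 0] <- 1
  expect_error(alignCenterAxis(case), "TZ")
})

test_that("center crop keeps the central index window", {
  D <- 2L
  v <- array(seq_len(D * 320 * 320), c(D, 320, 320))
  case <- new("MpMRICase", t2w = v, adc = v, highb = v,
              tzMask = array(0, dim(v)), pzMask = array(0, dim(v)),
              lesionMask = array(0, dim(v)),
              lesionTable = data.frame(lesionId = integer(),
                                       zone = character(), cz = numeric(),
                                       cy = numeric(), cx = numeric(),
                                       radiusMm = numeric()),
              spacingMm = c(3, 0.625, 0.625), caseId = "crop")
  out <- centerCrop(case, c(128L, 128L))
  expect_identical(dim(out@t2w), c(D, 128L, 128L))
  # 320 -> 128 retains 1-based indices 97..224 on each in-plane axis
  expect_identical(out@t2w, v[, 97:224, 97:224, drop = FALSE])
  # crop at input size is the identity
  same <- centerCrop(case, c(320L, 320L))
  expect_identical(same@t2w, case@t2w)
  expect_error(centerCrop(case, c(512L, 512L)), "exceeds")
})

test_that("a centered lesion survives the crop intact", {
  case <- smallCase(seed = 30L, nPZ = 1L)
  out <- centerCrop(case, c(24L, 24L))
  expect_identical(sum(out@lesionMask), sum(case@lesionMask))
})

test_that("normalization maps channels to [0,1] as specified", {
  d <- c(2L, 4L, 4L)
  t2 <- array(100, d); t2[1, 1, 1] <- 600; t2[1, 1, 2] <- 350
  hb <- array(runif(prod(d), 10, 90), d)
  ad <- array(1500, d); ad[1, 1, 1] <- 3500
  case <- new("MpMRICase", t2w = t2, adc = ad, highb = hb,
              tzMask = array(0, d), pzMask = array(0, d),
              lesionMask = array(0, d),
              lesionTable = data.frame(lesionId = integer(),
                                       zone = character(), cz = numeric(),
                                       cy = numeric(), cx = numeric(),
                                       radiusMm = numeric()),
              spacingMm = c(3, 1, 1), caseId = "norm")
  out <- normalizeCase(case, preprocessConfig(adcClipValue = 3000))
  expect_equal(out@t2w[1, 1, 2], 0.5)          # 350 between 100 and 600
  expect_equal(out@adc[1, 1, 1], 1.0)          # clipped then scaled
  expect_equal(out@adc[2, 1, 1], 0.5)          # 1500 / 3000
  for (s in c("t2w", "adc", "highb"))
    expect_true(all(slot(out, s) >= 0 & slot(out, s) <= 1))
  # min-max channels are idempotent
  out2 <- normalizeCase(out, preprocessConfig(adcClipValue = 3000))
  expect_equal(out2@t2w, out@t2w, tolerance = 1e-12)
  expect_equal(out2@highb, out@highb, tolerance = 1e-12)
  # degenerate constant channel
  flat <- case; flat@t2w[] <- 7
  expect_error(normalizeCase(flat), "constant")
})

test_that("the full chain runs and records provenance", {
  case <- smallCase(seed = 31L)
  sidecar <- withr::local_tempfile(fileext = ".json")
  out <- preprocessCase(case, preprocessConfig(cropSize = c(32L, 32L),
                                               rotate = TRUE),
                        sidecar = sidecar)
  expect_true(all(out@t2w >= 0 & out@t2w <= 1))
  prov <- jsonlite::read_json(sidecar)
  expect_identical(prov$case_id, caseId(case))
  expect_true(is.numeric(prov$rotation_angle_rad))
})
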