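# Independent scalar-loop oracle for the constrained focal cross-entropy:
# one voxel at a time, straight from the per-voxel definition. Kept free of
# any code shared with the vectorized implementation.
oracleZonal <- function(P, M, gamma, eps = 1e-7) {
  d <- dim(P)
  tot <- 0
  for (z in seq_len(d[2])) for (y in seq_len(d[3])) for (x in seq_len(d[4])) {
    p0 <- P[1, z, y, x]; p1 <- P[2, z, y, x]
    m0 <- M[1, z, y, x]; m1 <- M[2, z, y, x]
    q0 <- if (m0 == 1) p0 else max(p0, p1)
    q1 <- if (m1 == 1) min(p0, p1) else p1
    q0 <- min(max(q0, eps), 1 - eps)
    q1 <- min(max(q1, eps), 1 - eps)
    for (k in 1:2) {
      q <- if (k == 1) q0 else q1
      m <- if (k == 1) m0 else m1
      tot <- tot - m * (1 - q)^gamma * log(q) -
        (1 - m) * q^gamma * log(1 - q)
    }
  }
  tot
}

randomPair <- function(d = c(2L, 4L, 8L, 8L)) {
  P <- array(runif(prod(d)), d)
  m0 <- rbinom(prod(d[-1]), 1, 0.3)
  m1 <- m0 * rbinom(prod(d[-1]), 1, 0.5)   # (0,1) never generated
  M <- array(0, d)
  M[1, , , ] <- m0
  M[2, , , ] <- m1
  list(P = P, M = M)
}

test_that("probability constraints implement the max/min rules", {
  expect_equal(constrainProbs(c(0.3, 0.6), c(0, 0)), c(0.6, 0.6))
  expect_equal(constrainProbs(c(0.2, 0.8), c(1, 1)), c(0.2, 0.2))
  expect_equal(constrainProbs(c(0.9, 0.1), c(1, 0)), c(0.9, 0.1))
  expect_error(constrainProbs(c(0.5, 0.5), c(0, 1)), "undefined")
})

test_that("single-voxel losses match hand-evaluated values", {
  # m=(0,0), p=(0.3,0.6): both channels constrained to 0.6
  expect_equal(modifiedCE(c(0.3, 0.6), c(0, 0)), 2 * -log(0.4),
               tolerance = 1e-5)
  expect_equal(round(modifiedCE(c(0.3, 0.6), c(0, 0)), 5), 1.83258)
  # m=(1,0), p=(0.8,0.3): constraints inactive
  expect_equal(modifiedCE(c(0.8, 0.3), c(1, 0)), -log(0.8) - log(0.7),
               tolerance = 1e-5)
  expect_equal(round(modifiedCE(c(0.8, 0.3), c(1, 0)), 5), 0.57982)
  # perfect prediction is zero up to the eps clamp
  expect_lt(modifiedCE(c(1, 1), c(1, 1)), 1e-6)
  # focal form, gamma = 2
  expect_equal(zonalLoss(c(0.5, 0.5), c(1, 1), lossConfig(gamma = 2)),
               2 * 0.25 * -log(0.5), tolerance = 1e-5)
  expect_equal(round(zonalLoss(c(0.5, 0.5), c(1, 1), lossConfig(gamma = 2)),
                     5), 0.34657)
})

test_that("zonal loss at gamma 0 reduces exactly to the modified CE", {
  set.seed(11)
  for (i in 1:10) {
    rp <- randomPair()
    expect_identical(zonalLoss(rp$P, rp$M, lossConfig(gamma = 0)),
                     modifiedCE(rp$P, rp$M))
  }
})

test_that("binary focal loss matches hand values and reduces to BCE", {
  expect_lt(focalLossBinary(1, 1), 1e-6)
  expect_lt(focalLossBinary(0, 0), 1e-6)
  expect_equal(focalLossBinary(0.5, 1, lossConfig(gamma = 2)),
               0.25 * -log(0.5), tolerance = 1e-5)
  expect_equal(round(focalLossBinary(0.5, 1, lossConfig(gamma = 2)), 5),
               0.17329)
  set.seed(3)
  p <- array(runif(64), c(4, 4, 4))
  m <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  bce <- sum(-m * log(p) - (1 - m) * log(1 - p))
  expect_equal(focalLossBinary(p, m, lossConfig(gamma = 0)), bce,
               tolerance = 1e-9)
})

test_that("vectorized loss equals the scalar-loop oracle on random instances", {
  set.seed(2024)
  for (i in 1:100) {
    rp <- randomPair()
    gamma <- sample(c(0, 1, 2), 1)
    expect_equal(zonalLoss(rp$P, rp$M, lossConfig(gamma = gamma)),
                 oracleZonal(rp$P, rp$M, gamma), tolerance = 1e-6)
  }
})

test_that("for m=(0,0) the loss strictly increases in p1 beyond p0", {
  for (gamma in c(0, 2)) {
    for (p0 in c(0.2, 0.5, 0.7)) {
      grid <- seq(p0 + 0.02, 0.98, by = 0.02)
      losses <- vapply(grid, function(p1)
        zonalLoss(c(p0, p1), c(0, 0), lossConfig(gamma = gamma)),
        numeric(1))
      expect_true(all(diff(losses) > 0))
    }
  }
})

test_that("for m=(1,1) the loss is non-increasing in p1 below p0", {
  for (gamma in c(0, 2)) {
    p0 <- 0.8
    grid <- seq(0.05, p0, by = 0.05)
    losses <- vapply(grid, function(p1)
      zonalLoss(c(p0, p1), c(1, 1), lossConfig(gamma = gamma)), numeric(1))
    expect_true(all(diff(losses) <= 1e-12))
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(99)
  cfg <- lossConfig(gamma = 2, reduction = "sum")
  for (i in 1:20) {
    rp <- randomPair(c(2L, 2L, 3L, 3L))
    # keep away from the max/min tie points where the subgradient jumps
    ties <- abs(rp$P[1, , , ] - rp$P[2, , , ]) < 1e-3
    if (any(ties)) next
    g <- SymZonal:::.zonalLossGrad(rp$P, rp$M, cfg)
    idx <- sample(length(rp$P), 5)
    for (j in idx) {
      h <- 1e-6
      Pp <- rp$P; Pp[j] <- Pp[j] + h
      Pm <- rp$P; Pm[j] <- Pm[j] - h
      num <- (zonalLoss(Pp, rp$M, cfg) - zonalLoss(Pm, rp$M, cfg)) / (2 * h)
      expect_equal(g$grad[j], num, tolerance = 1e-4)
    }
  }
})

test_that("the loss is invariant to voxel ordering", {
  set.seed(5)
  rp <- randomPair()
  perm <- sample(prod(dim(rp$P)[-1]))
  permute <- function(a) {
    m <- matrix(a, nrow = 2)[, perm]
    array(m, dim(a))
  }
  expect_equal(zonalLoss(rp$P, rp$M, lossConfig(gamma = 2)),
               zonalLoss(permute(rp$P), permute(rp$M),
                         lossConfig(gamma = 2)),
               tolerance = 1e-10)
})

test_that("shape mismatches and bad configs are rejected", {
  expect_error(zonalLoss(array(0.5, c(2, 2, 2, 2)),
                         array(0, c(2, 2, 2, 3)), lossConfig()), "shapes")
  expect_error(lossConfig(gamma = -1))
  expect_error(lossConfig(eps = 0.5))
  expect_error(focalLossBinary(array(0.5, c(2, 2, 2)),
                               array(0, c(2, 2, 3))), "shapes")
})
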