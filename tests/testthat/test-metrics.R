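# Independent brute-force reference implementations (kept deliberately
# different in style from the package code: explicit double loops).

bruteAngularAccuracy <- function(pred, gt) {
  tot <- 0; n <- 0
  for (i in seq_along(pred)) {
    d <- pred[i] - gt[i]
    d <- atan2(sin(d), cos(d))
    tot <- tot + abs(d); n <- n + 1
  }
  1 - (tot / n) / pi
}

bruteMatch <- function(pred, gt, r) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) {
    hit <- FALSE
    for (j in seq_len(nrow(gt)))
      if (sqrt(sum((pred[i, ] - gt[j, ])^2)) <= r) hit <- TRUE
    if (hit) tp <- tp + 1 else fp <- fp + 1
  }
  for (j in seq_len(nrow(gt))) {
    hit <- FALSE
    for (i in seq_len(nrow(pred)))
      if (sqrt(sum((pred[i, ] - gt[j, ])^2)) <= r) hit <- TRUE
    if (!hit) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

bruteAHD <- function(X, Y, diag) {
  if (nrow(X) == 0 && nrow(Y) == 0) return(0)
  if (nrow(X) == 0 || nrow(Y) == 0) return(diag)
  dmat <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    dmat[i, j] <- sqrt(sum((X[i, ] - Y[j, ])^2))
  mean(apply(dmat, 1, min)) / 2 + mean(apply(dmat, 2, min)) / 2
}

randPts <- function(n, side = 8) matrix(runif(2 * n, 0, side), ncol = 2)

test_that("angular accuracy matches brute force on random 8x8 instances", {
  set.seed(11)
  for (rep in 1:20) {
    pred <- matrix(runif(64, -pi, pi), 8, 8)
    gt <- matrix(runif(64, -pi, pi), 8, 8)
    expect_equal(angularAccuracy(pred, gt)$mean,
                 bruteAngularAccuracy(pred, gt), tolerance = 1e-6)
  }
})

test_that("PS matching counts match brute force", {
  set.seed(12)
  for (rep in 1:50) {
    pred <- randPts(sample(0:6, 1))
    gt <- randPts(sample(0:6, 1))
    r <- runif(1, 0.5, 4)
    b <- bruteMatch(pred, gt, r)
    psP <- rotormap:::newPSSet(
      data.frame(t = rep(1L, nrow(pred)), x = pred[, 1], y = pred[, 2],
                 chirality = rep(NA_integer_, nrow(pred))),
      c(9L, 9L), 1L)
    psG <- rotormap:::newPSSet(
      data.frame(t = rep(1L, nrow(gt)), x = gt[, 1], y = gt[, 2],
                 chirality = rep(NA_integer_, nrow(gt))),
      c(9L, 9L), 1L)
    m <- matchPS(psP, psG, rMatch = r)
    expect_equal(c(tp = m$tp, fp = m$fp, fn = m$fn), b)
  }
})

test_that("average Hausdorff distance matches brute force incl. empty sets", {
  set.seed(13)
  diag <- sqrt(128)
  for (rep in 1:50) {
    X <- randPts(sample(0:5, 1))
    Y <- randPts(sample(0:5, 1))
    expect_equal(ahd(X, Y, diag), bruteAHD(X, Y, diag), tolerance = 1e-6)
  }
  expect_equal(ahd(randPts(0), randPts(0), diag), 0)
  expect_equal(ahd(randPts(3), randPts(0), diag), diag)
})

test_that("MAHD averages per-frame AHD", {
  set.seed(14)
  gtl <- list(randPts(3), randPts(0), randPts(2))
  prl <- list(randPts(2), randPts(1), randPts(2))
  diag <- sqrt(2 * 8^2)
  want <- mean(c(bruteAHD(gtl[[1]], prl[[1]], diag),
                 bruteAHD(gtl[[2]], prl[[2]], diag),
                 bruteAHD(gtl[[3]], prl[[3]], diag)))
  expect_equal(mahd(gtl, prl, dims = c(8, 8)), want, tolerance = 1e-6)
})

test_that("count MAE and F-score behave on edge cases", {
  expect_equal(countMAE(c(1, 2, 3), c(1, 4, 1)), 4 / 3)
  expect_error(countMAE(1:3, 1:4), "length")
  fs <- fScore(list(tp = 0, fp = 0, fn = 0))
  expect_true(is.na(fs$f))
  fs2 <- fScore(list(tp = 0, fp = 3, fn = 2))
  expect_equal(fs2$f, 0)
  fs3 <- fScore(list(tp = 8, fp = 2, fn = 2))
  expect_equal(fs3$precision, 0.8)
  expect_equal(fs3$recall, 0.8)
  expect_equal(fs3$f, 0.8, tolerance = 1e-12)
})

test_that("identical point sets give perfect scores", {
  ph <- plantedVortex(20L, 9.5, 9.5)
  ps <- detectPS(ph)
  rep <- evaluatePS(ps, ps)
  expect_equal(rep$f, 1)
  expect_equal(rep$mahd, 0)
  expect_equal(rep$mae, 0)
})
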