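# Brute-force loss references (independent implementations).

bruteMSE <- function(pred, target) mean((pred - target)^2)

bruteCE <- function(pred, target) {
  d <- dim(pred)
  tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in 1:2)
    tot <- tot - target[i, j, c] * log(pred[i, j, c] + 1e-12)
  tot / (d[1] * d[2])
}

bruteWHD <- function(p, pts, alpha = -3) {
  H <- nrow(p); W <- ncol(p); N <- H * W
  dmax <- sqrt(H^2 + W^2)
  eps <- 1e-6
  if (nrow(pts) == 0) return(dmax * sum(p) / N)
  t1 <- 0
  for (i in 1:H) for (j in 1:W) {
    x <- j - 1; y <- i - 1
    dm <- Inf
    for (k in seq_len(nrow(pts)))
      dm <- min(dm, sqrt((x - pts[k, 1])^2 + (y - pts[k, 2])^2))
    t1 <- t1 + p[i, j] * dm
  }
  t1 <- t1 / (sum(p) + eps)
  t2 <- 0
  for (k in seq_len(nrow(pts))) {
    acc <- 0
    for (i in 1:H) for (j in 1:W) {
      x <- j - 1; y <- i - 1
      dij <- sqrt((x - pts[k, 1])^2 + (y - pts[k, 2])^2)
      z <- p[i, j] * dij + (1 - p[i, j]) * dmax + eps
      acc <- acc + z^alpha / N
    }
    t2 <- t2 + acc^(1 / alpha)
  }
  t1 + t2 / nrow(pts)
}

test_that("losses match brute force on random 8x8 instances to 1e-6", {
  set.seed(21)
  for (rep in 1:10) {
    a <- array(runif(8 * 8 * 2, -1, 1), c(8, 8, 2))
    b <- array(runif(8 * 8 * 2, -1, 1), c(8, 8, 2))
    expect_equal(phaseLoss(a, b), bruteMSE(a, b), tolerance = 1e-6)

    logits <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2, 1))
    pr <- rotormap:::softmaxC(logits)
    dim(pr) <- c(8, 8, 2)
    hot <- matrix(runif(64) < 0.2, 8, 8)
    tg <- array(0, c(8, 8, 2)); tg[, , 2] <- hot; tg[, , 1] <- 1 - hot
    expect_equal(classmapLoss(pr, tg), bruteCE(pr, tg), tolerance = 1e-6)

    p <- matrix(runif(64), 8, 8)
    pts <- matrix(runif(2 * sample(0:3, 1), 0, 8), ncol = 2)
    expect_equal(weightedHausdorffLoss(p, pts), bruteWHD(p, pts),
                 tolerance = 1e-6)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(22)
  # weighted Hausdorff
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  pts <- matrix(runif(4, 0, 6), 2, 2)
  g <- rotormap:::weightedHausdorffGrad(p, pts)$grad
  for (idx in sample(36, 6)) {
    eps <- 1e-6
    pp <- p; pp[idx] <- pp[idx] + eps
    pm <- p; pm[idx] <- pm[idx] - eps
    num <- (weightedHausdorffLoss(pp, pts) - weightedHausdorffLoss(pm, pts)) /
      (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-4)
  }
  # empty ground truth
  g0 <- rotormap:::weightedHausdorffGrad(p, matrix(0, 0, 2))
  expect_equal(g0$loss, sqrt(72) * sum(p) / 36, tolerance = 1e-12)
})

test_that("full-model parameter gradients match finite differences", {
  set.seed(23)
  ns <- asNamespace("rotormap")
  for (variant in c("M1", "M2")) {
    net <- buildModel(variant, inputFrames = 2L, side = 8L,
                      encoderWidths = c(2L, 2L, 3L), latentWidth = 4L,
                      convsPerStage = 1L, seed = 3L)
    X <- array(stats::rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    th <- array(runif(8 * 8 * 2, -pi, pi), c(8, 8, 2))
    target <- array(0, c(8, 8, 2, 2))
    target[, , 1, ] <- cos(th); target[, , 2, ] <- sin(th)
    lossAt <- function(params) {
      net@params <- params
      fw <- ns$netForward(net, X, train = TRUE)
      ns$headLossGrad(net, fw, target, NULL)$loss
    }
    fw <- ns$netForward(net, X, train = TRUE)
    hl <- ns$headLossGrad(net, fw, target, NULL)
    grads <- ns$netBackward(net, fw, hl$dLogits)
    for (k in sample(names(grads), 6)) {
      j <- sample(length(net@params[[k]]), 1)
      eps <- 1e-5
      pp <- net@params; pp[[k]][j] <- pp[[k]][j] + eps
      pm <- net@params; pm[[k]][j] <- pm[[k]][j] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      ana <- grads[[k]][j]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-2)
    }
  }
})

test_that("training overfits a tiny problem (loss decreases)", {
  ph <- syntheticSpiral(16L, nT = 12L)
  X <- array(0, c(16, 16, 2, 10))
  targ <- array(0, c(16, 16, 2, 10))
  for (i in 1:10) {
    X[, , 1, i] <- cos(ph[, , i]); X[, , 2, i] <- cos(ph[, , i + 1])
    targ[, , , i] <- trigEncode(ph[, , i + 1])
  }
  ds <- new("RotorDataset", inputs = X, targets = list(phase = targ),
            masks = array(TRUE, c(16, 16, 10)),
            info = data.frame(episode = "e", t0 = 1:10, targetFrame = 2:11),
            spec = sampleSpec(nFrames = 2L, targetKind = "phase"),
            meta = list())
  net <- buildModel("M1", inputFrames = 2L, side = 16L,
                    encoderWidths = c(4L, 6L, 8L), latentWidth = 12L,
                    convsPerStage = 1L, seed = 2L)
  net <- trainModel(net, ds, epochs = 15L, batchSize = 5L, lr = 2e-3,
                    valFraction = 0.1, seed = 1L, verbose = FALSE)
  h <- net@state$history
  expect_equal(nrow(h), 15L)
  expect_lt(h$train[15], 0.5 * h$train[1])
})

test_that("head/variant wiring is enforced", {
  net <- buildModel("M1A", side = 16L, encoderWidths = c(2L, 2L, 2L),
                    latentWidth = 2L, convsPerStage = 1L)
  ds <- new("RotorDataset",
            inputs = array(0, c(16, 16, 5, 4)),
            targets = list(phase = array(0, c(16, 16, 2, 4))),
            masks = array(TRUE, c(16, 16, 4)),
            info = data.frame(episode = "e", t0 = 1:4, targetFrame = 1:4),
            spec = sampleSpec(targetKind = "phase"), meta = list())
  expect_error(trainModel(net, ds), "target kind")
  expect_error(predictPhase(net, array(0, c(16, 16, 5))), "phase-head")
  expect_error(buildModel("M9"), "variant")
  expect_error(buildModel("M1", side = 30L), "divisible")
})

test_that("softmax head yields per-pixel distributions; sigmoid in (0,1)", {
  ns <- asNamespace("rotormap")
  netA <- buildModel("M1A", inputFrames = 2L, side = 8L,
                     encoderWidths = c(2L, 2L, 2L), latentWidth = 3L,
                     convsPerStage = 1L, seed = 5L)
  X <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  fa <- ns$netForward(netA, X)
  expect_equal(max(abs(fa$out[, , 1, ] + fa$out[, , 2, ] - 1)), 0,
               tolerance = 1e-12)
  netB <- buildModel("M1B", inputFrames = 2L, side = 8L,
                     encoderWidths = c(2L, 2L, 2L), latentWidth = 3L,
                     convsPerStage = 1L, seed = 5L)
  fb <- ns$netForward(netB, X)
  expect_true(all(fb$out > 0 & fb$out < 1))
})
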