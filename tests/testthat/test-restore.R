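# gentle enough that the local Kuramoto order of the clean field stays
# above the fixed 0.9 outlier threshold (d = 5 x 3 kernel)
planeWavePhase <- function(side = 24L, nT = 9L) {
  ph <- array(0, c(side, side, nT))
  for (t in seq_len(nT))
    ph[, , t] <- wrapPhase(matrix(rep((0:(side - 1)) * 0.15, each = side),
                                  side, side) - 0.2 * t)
  ph
}

test_that("Kuramoto order parameter is 1 on coherent fields", {
  ph <- array(0.7, c(12, 12, 5))
  r <- kuramotoOrder(ph)
  expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)
})

test_that("outlier removal flags incoherent pixels and nothing else", {
  ph <- planeWavePhase()
  # corrupt one pixel across the temporal kernel extent
  ph[12, 12, 4:6] <- wrapPhase(ph[12, 12, 4:6] + pi)
  out <- removeOutliers(ph, d = 5, dtFrames = 3, rThreshold = 0.9)
  expect_true(is.na(phases(out)[12, 12, 5]))
  # far away from the corruption nothing is removed
  expect_false(anyNA(phases(out)[1:6, 1:6, ]))
  # threshold 0 is the identity
  id <- removeOutliers(ph, rThreshold = 0)
  expect_equal(phases(id), ph)
})

test_that("inpainting reconstructs a plane wave from holes", {
  ph <- planeWavePhase()
  holes <- ph
  set.seed(5)
  miss <- array(runif(length(ph)) < 0.3, dim(ph))
  holes[miss] <- NaN
  filled <- inpaintPhase(holes, d = 5, dtFrames = 3)
  expect_false(anyNA(phases(filled)))
  err <- abs(wrapPhase(phases(filled)[miss] - ph[miss]))
  expect_lt(mean(err), 0.25)
})

test_that("fixed-iteration inpainting warns when pixels stay unfilled", {
  ph <- planeWavePhase()
  ph[5:20, 5:20, ] <- NaN  # big hole
  expect_warning(inpaintPhase(ph, d = 5, iterations = 1), "inpaint")
})

test_that("smoothing is circular (no averaging across the wrap)", {
  # field hovering around the discontinuity at +-pi
  ph <- array(wrapPhase(pi + stats::rnorm(12 * 12 * 5, 0, 0.05)),
              c(12, 12, 5))
  sm <- smoothPhase(ph, d = 5, dtFrames = 3)
  # a linear average would land near 0; the circular one stays near +-pi
  expect_gt(mean(abs(phases(sm))), 3)
})

test_that("smoothing rejects movies with missing values", {
  ph <- planeWavePhase()
  ph[3, 3, 3] <- NaN
  expect_error(smoothPhase(ph), "inpaint")
})

test_that("restoration presets run and custom identity is the identity", {
  ph <- planeWavePhase()
  noisy <- wrapPhase(ph + array(stats::rnorm(length(ph), 0, 0.3), dim(ph)))
  for (preset in c("noisy", "lowres")) {
    rec <- restorePipeline(noisy, preset = preset)
    expect_false(anyNA(phases(rec)))
    errRec <- mean(abs(wrapPhase(phases(rec) - ph)))
    errRaw <- mean(abs(wrapPhase(noisy - ph)))
    expect_lt(errRec, errRaw)  # restoration must help
  }
  id <- restorePipeline(ph, preset = "custom")
  expect_equal(phases(id), ph)
})
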