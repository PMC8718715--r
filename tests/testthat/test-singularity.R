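test_that("a planted vortex is detected at the right place with chirality", {
  for (q in c(-1L, 1L)) {
    ph <- plantedVortex(20L, cx = 9.5, cy = 9.5, q = q)
    ps <- detectPS(ph)
    pts <- psPoints(ps)
    expect_equal(nrow(pts), 1L)
    expect_equal(pts$x, 9.5, tolerance = 0.51)
    expect_equal(pts$y, 9.5, tolerance = 0.51)
    expect_equal(pts$chirality, q)
  }
})

test_that("topological charge is conserved on 1,000 planted vortex fields", {
  set.seed(7)
  side <- 16L
  for (i in 1:1000) {
    nv <- sample(0:3, 1)
    ph <- matrix(runif(1, -pi, pi), side, side)
    qs <- integer(0)
    if (nv > 0) {
      for (v in seq_len(nv)) {
        q <- sample(c(-1L, 1L), 1)
        ph <- wrapPhase(ph + plantedVortex(side,
                                           cx = runif(1, 3, side - 4),
                                           cy = runif(1, 3, side - 4), q = q))
        qs <- c(qs, q)
      }
    }
    pts <- psPoints(detectPS(ph))
    # net charge of all detections equals the planted net charge
    expect_equal(sum(pts$chirality), sum(qs))
  }
})

test_that("class-map encoding marks the 2x2 plaquette and decodes back", {
  ph <- plantedVortex(24L, cx = 10.5, cy = 7.5, q = 1L)
  ps <- detectPS(ph)
  img <- encodePSClassMap(ps, dims = c(24L, 24L))
  expect_equal(dim(img), c(24L, 24L, 2L))
  expect_equal(sum(img[, , 2]), 4)              # one 2x2 block
  expect_true(all(img[, , 1] + img[, , 2] == 1))  # one-hot
  dec <- decodePSMap(img[, , 2])
  expect_equal(nrow(psPoints(dec)), 1L)
  expect_equal(psPoints(dec)$x, 10.5, tolerance = 0.51)
  expect_equal(psPoints(dec)$y, 7.5, tolerance = 0.51)
})

test_that("probability maps are thresholded into PS detections", {
  prob <- matrix(0, 16, 16)
  prob[4:5, 8:9] <- 0.9      # rows 4:5 (y), cols 8:9 (x)
  prob[12, 2] <- 0.3         # below threshold
  ps <- psFromProbability(prob, threshold = 0.5)
  pts <- psPoints(ps)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$x, 7.5, tolerance = 0.51)   # 0-based x = col - 1
  expect_equal(pts$y, 3.5, tolerance = 0.51)
})

test_that("chirality assignment recovers the rotation sense", {
  ph <- plantedVortex(20L, cx = 9.5, cy = 9.5, q = -1L)
  ps <- psFromProbability(encodePSClassMap(detectPS(ph), c(20L, 20L))[, , 2])
  expect_true(is.na(psPoints(ps)$chirality))
  ps2 <- assignChirality(ps, ph)
  expect_equal(psPoints(ps2)$chirality, -1)
})

test_that("masked regions produce no detections", {
  ph <- plantedVortex(20L, cx = 9.5, cy = 9.5)
  mask <- matrix(TRUE, 20, 20)
  mask[6:14, 6:14] <- FALSE
  ps <- detectPS(ph, mask = mask)
  expect_equal(nrow(psPoints(ps)), 0L)
})
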