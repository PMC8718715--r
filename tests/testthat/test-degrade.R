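mkMovie <- function(side = 32L, nT = 60L, seed = 3L) {
  set.seed(seed)
  tt <- seq_len(nT)
  mov <- array(0, c(side, side, nT))
  for (i in seq_len(side)) for (j in seq_len(side))
    mov[i, j, ] <- 0.5 + 0.4 * sin(2 * pi * (tt + i + 2 * j) / 20)
  mov
}

test_that("additive noise is seeded, unclipped and sigma-faithful", {
  mov <- mkMovie()
  n1 <- addNoise(mov, sigma = 0.3, seed = 9L)
  n2 <- addNoise(mov, sigma = 0.3, seed = 9L)
  expect_identical(frames(n1), frames(n2))
  n3 <- addNoise(mov, sigma = 0.3, seed = 10L)
  expect_false(identical(frames(n1), frames(n3)))
  resid <- frames(n1) - mov
  expect_equal(stats::sd(resid), 0.3, tolerance = 0.01)
  expect_gt(max(frames(n1)), 1)  # no clipping
})

test_that("noise respects tissue masks (outside stays exactly zero)", {
  mov <- mkMovie(16L, 20L)
  mask <- matrix(TRUE, 16, 16); mask[1:4, ] <- FALSE
  mv <- applyMask(new("ExcitationMovie", frames = mov, mask = NULL,
                      meta = list()), mask)
  noisy <- addNoise(mv, 0.5, seed = 1L)
  expect_true(all(frames(noisy)[1:4, , ] == 0))
})

test_that("sparsification keeps a xi-per-axis pixel lattice", {
  mov <- mkMovie(24L, 10L)
  sp <- sparsify(mov, xi = 0.25)
  valid <- movieMeta(sp)$valid
  expect_equal(mean(valid), 0.25^2, tolerance = 0.02)
  # unobserved pixels zeroed, observed untouched
  expect_true(all(frames(sp)[rep(!valid, 10)] == 0))
  expect_equal(frames(sp)[rep(valid, 10)], mov[rep(valid, 10)])
  expect_error(sparsify(mov, xi = 0.9), "xi")
})

test_that("low-resolution degradation block-averages", {
  mov <- mkMovie(32L, 4L)
  lr <- lowresMovie(mov, size = 8L)
  fr <- frames(lr)
  expect_equal(dim(fr), dim(mov))
  expect_equal(fr[1, 1, 1], mean(mov[1:4, 1:4, 1]), tolerance = 1e-12)
  # constant within each 4x4 block
  expect_equal(max(abs(fr[1:4, 1:4, 1] - fr[1, 1, 1])), 0)
})

test_that("electrode layouts have the advertised geometry", {
  for (nm in c("grid8x8-large", "grid8x8-small")) {
    lay <- electrodeLayout(nm, dims = c(128L, 128L))
    expect_equal(nrow(lay@centers), 64L)
  }
  star <- electrodeLayout("star", dims = c(128L, 128L))
  expect_gt(nrow(star@centers), 10)
  m <- rotormap:::layoutMask(electrodeLayout("grid8x8-large", c(128L, 128L)),
                             c(128L, 128L))
  expect_true(mean(m) < 1 && mean(m) > 0)
})

test_that("layout application records the observation mask", {
  mov <- mkMovie(32L, 10L)
  lay <- electrodeLayout("grid8x8-small", dims = c(32L, 32L))
  obs <- applyLayout(mov, lay, sigma = 0.2, seed = 4L)
  valid <- movieMeta(obs)$valid
  expect_true(all(frames(obs)[rep(!valid, 10)] == 0))
  expect_gt(stats::sd(frames(obs)[rep(valid, 10)] - mov[rep(valid, 10)]), 0.1)
})

test_that("random tissue masks are seeded, bounded and 4-connected", {
  for (s in 1:5) {
    m <- randomTissueMask(c(48L, 48L), seed = s)
    expect_identical(m, randomTissueMask(c(48L, 48L), seed = s))
    cov <- mean(m)
    expect_gte(cov, 0.3)
    expect_lte(cov, 0.95)
    # 4-connectivity: label with EBImage (4-connected) and expect one blob
    expect_equal(max(EBImage::bwlabel(m + 0)), 1)
  }
})
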