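test_that("wrapPhase maps onto [-pi, pi) and is idempotent", {
  x <- seq(-20, 20, by = 0.37)
  w <- wrapPhase(x)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(wrapPhase(w), w)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
})

test_that("analytic-signal phase of a sinusoid advances linearly", {
  tt <- 0:599
  x <- cos(2 * pi * tt / 50)
  ph <- hilbertPhase(x)
  dphi <- wrapPhase(diff(ph))
  inner <- dphi[50:500]
  expect_equal(mean(inner), 2 * pi / 50, tolerance = 1e-3)
  expect_lt(stats::sd(inner), 1e-2)
})

test_that("constant traces are rejected (vector) or marked missing (movie)", {
  expect_error(hilbertPhase(rep(1, 100)), "constant")
  mov <- array(0, c(4, 4, 100))
  mov[1, 1, ] <- sin(seq_len(100) / 5)
  ph <- hilbertPhase(mov)
  expect_true(all(is.na(phases(ph)[2, 2, ])))
  expect_false(anyNA(phases(ph)[1, 1, ]))
})

test_that("delay-embedding phase tracks a sinusoid cycle", {
  tt <- 0:999
  x <- sin(2 * pi * tt / 80)
  expect_equal(autoEmbedDelay(x), 20, tolerance = 2)
  ph <- delayEmbeddingPhase(x)
  good <- ph[100:900]
  # one full cycle per period: mean wrapped increment = 2 pi / 80
  expect_equal(mean(wrapPhase(diff(good))), 2 * pi / 80, tolerance = 0.01)
})

test_that("linear interpolation phase anchors upstrokes at -pi", {
  tt <- 0:479
  x <- 0.5 + 0.5 * sin(2 * pi * tt / 60)
  ph <- linearInterpPhase(x, upstrokeThreshold = 0.5)
  ups <- which(diff(ph) < -pi)  # wrap instants
  expect_gt(length(ups), 2)
  expect_error(linearInterpPhase(rep(0.1, 100)), "upstroke")
})

test_that("trigonometric encode/decode round-trips below 1e-6 rad", {
  set.seed(1)
  ph <- matrix(runif(400, -pi, pi - 1e-9), 20, 20)
  enc <- trigEncode(ph)
  dec <- trigDecode(enc)
  expect_lt(max(abs(wrapPhase(dec - ph))), 1e-6)
  # magnitude invariance
  dec2 <- trigDecode(enc * 0.37)
  expect_lt(max(abs(wrapPhase(dec2 - ph))), 1e-6)
  expect_true(is.nan(trigDecode(array(0, c(1, 1, 2)))[1, 1]))
})

test_that("sliding-window normalization maps traces into [0, 1]", {
  set.seed(2)
  mov <- array(rnorm(8 * 8 * 300, 5, 2), c(8, 8, 300))
  for (i in 1:8) for (j in 1:8)
    mov[i, j, ] <- mov[i, j, ] + 3 * sin(2 * pi * (1:300) / 40 + i + j)
  nm <- slidingWindowNormalize(mov, window = 100)
  fr <- frames(nm)
  expect_gte(min(fr), 0)
  expect_lte(max(fr), 1)
  # every pixel uses its full local range
  expect_gt(mean(apply(fr, c(1, 2), max)), 0.99)
})
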