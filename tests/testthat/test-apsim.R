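test_that("configuration validity catches bad parameters", {
  expect_error(simulationConfig(dt = 0.5), "stab|dt")
  expect_error(simulationConfig(stencil = 7L), "stencil")
  expect_error(simulationConfig(gridSize = c(0L, 0L)), "gridSize")
  expect_s4_class(simulationConfig(), "SimulationConfig")
})

test_that("stimulation events must fit the integration window", {
  cfg <- simulationConfig(nSnapshots = 100L)  # window [200, 500] too late
  expect_error(simulateEpisode(cfg), "window")
})

test_that("simulation is deterministic and seed-sensitive", {
  cfg <- simulationConfig(gridSize = c(60L, 60L), nSnapshots = 40L,
                          transientTime = 20, s2Time = 15,
                          stimWindow = c(18, 22), seed = 4L)
  m1 <- simulateEpisode(cfg)
  m2 <- simulateEpisode(cfg)
  expect_identical(frames(m1), frames(m2))
  cfg@seed <- 5L
  m3 <- simulateEpisode(cfg)
  expect_false(identical(frames(m1), frames(m3)))
  expect_equal(dim(frames(m1)), c(60L, 60L, 40L))
})

test_that("simulateEpisode does not disturb the caller RNG stream", {
  cfg <- simulationConfig(gridSize = c(40L, 40L), nSnapshots = 5L,
                          transientTime = 1, s2Time = 0.8,
                          nRandomStims = 0L, seed = 4L)
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulateEpisode(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a planar S1 wave propagates and stays bounded", {
  cfg <- simulationConfig(gridSize = c(80L, 80L), nSnapshots = 30L,
                          nRandomStims = 0L)
  st <- newSimState(cfg)
  st <- stimulate(st, x = 0, y = 40, radius = 4, amplitude = 1)
  v0 <- st$V
  expect_gt(max(v0), 0.9)
  st <- apStep(st, cfg, nSteps = 400L)
  expect_true(all(is.finite(st$V)))
  expect_true(max(st$V) <= 1.5 && min(st$V) >= -0.5)
  # the excited region must have moved/expanded away from the stimulus site
  expect_gt(sum(st$V > 0.5), sum(v0 > 0.5))
})

test_that("quiescent tissue stays quiescent (no spontaneous activity)", {
  cfg <- simulationConfig(gridSize = c(30L, 30L), nSnapshots = 3L)
  st <- newSimState(cfg)
  st <- apStep(st, cfg, nSteps = 200L)
  expect_equal(max(abs(st$V)), 0, tolerance = 1e-12)
})
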