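# Shared, lazily computed fixtures. Everything is generated in code and
# memoized for the session so expensive artifacts (simulations, trained
# models) are built once and reused across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Default-configuration episode used by several acceptance criteria.
refEpisode <- function(nSnapshots = 2500L, seed = 1L) {
  fixture(sprintf("episode_%d_%d", nSnapshots, seed),
          simulateEpisode(simulationConfig(nSnapshots = nSnapshots,
                                           seed = seed)))
}

# The long reference episode: the dominant period is measured at the native
# 200x200 resolution (single-pixel traces, first 2,500 snapshots) before the
# raw 1.6 GB array is dropped; only the 128x128 resized movie (0.65 GB) and
# the scalar period are memoized.
refLong <- function() {
  fixture("refLong", {
    ep <- simulateEpisode(simulationConfig(nSnapshots = 5000L, seed = 1L))
    per <- dominantPeriod(ep@frames[, , 1:2500])
    list(movie = resizeMovie(ep, 128L), period2500 = per)
  })
}

# Shorter episodes for training; 700 snapshots keeps the default random
# stimulation window inside the integration horizon.
trainEpisode <- function(seed) {
  fixture(sprintf("train_%d", seed),
          simulateEpisode(simulationConfig(nSnapshots = 700L, seed = seed)))
}

# A synthetic rigidly rotating spiral phase movie (analytic, no simulation):
# phase(x, y, t) = theta(x, y) - omega t, one PS at the center.
syntheticSpiral <- function(side = 32L, nT = 20L, omega = 2 * pi / 10) {
  cx <- (side - 1) / 2 + 0.25
  cy <- (side - 1) / 2 + 0.25
  xs <- matrix(rep(0:(side - 1), each = side), side, side)  # x = column
  ys <- matrix(rep(0:(side - 1), side), side, side)         # y = row
  th <- atan2(ys - cy, xs - cx)
  ph <- array(0, c(side, side, nT))
  for (t in seq_len(nT)) ph[, , t] <- wrapPhase(th - omega * (t - 1))
  ph
}

# Planted vortex field: phase = q * atan2(y - cy, x - cx) (+ background).
plantedVortex <- function(side, cx, cy, q = 1L, bg = 0) {
  xs <- matrix(rep(0:(side - 1), each = side), side, side)
  ys <- matrix(rep(0:(side - 1), side), side, side)
  wrapPhase(q * atan2(ys - cy, xs - cx) + bg)
}

# Reduced-scale training setup shared by the training-based acceptance
# criteria: two training episodes, one held-out test episode, 32x32.
trainTestDatasets <- function(targetKind, degradation) {
  key <- sprintf("ds_%s_%s_%s", targetKind, degradation$type %||% "none",
                 degradation$sigma %||% 0)
  fixture(key, {
    spec <- sampleSpec(nFrames = 5L, targetKind = targetKind)
    train <- buildDataset(list(a = trainEpisode(11L), b = trainEpisode(12L)),
                          spec = spec, degradation = degradation,
                          side = 32L, frameStep = 2L, seed = 2L)
    test <- buildDataset(list(c = trainEpisode(13L)), spec = spec,
                         degradation = degradation, side = 32L,
                         frameStep = 8L, seed = 3L)
    list(train = train, test = test)
  })
}

# Staged learning-rate schedule (8-epoch stages): 2e-3 x3, 1e-3 x2, then
# 5e-4. Settled on small-scale calibration runs before the acceptance
# measurements were fixed.
trainedNet <- function(variant, targetKind, degradation, epochs) {
  key <- sprintf("net_%s_%s_%s", variant, degradation$type %||% "none",
                 degradation$sigma %||% 0)
  fixture(key, {
    ds <- trainTestDatasets(targetKind, degradation)
    net <- buildModel(variant, inputFrames = 5L, side = 32L,
                      encoderWidths = c(8L, 16L, 32L), latentWidth = 64L,
                      convsPerStage = 2L, seed = 1L)
    lrs <- c(2e-3, 2e-3, 2e-3, 1e-3, 1e-3, 5e-4)
    done <- 0L; stage <- 0L
    while (done < epochs) {
      stage <- stage + 1L
      n <- min(8L, epochs - done)
      net <- trainModel(net, ds$train, epochs = n, batchSize = 32L,
                        lr = lrs[min(stage, length(lrs))], seed = stage,
                        verbose = FALSE)
      done <- done + n
    }
    net
  })
}

decodePhaseTargets <- function(targ) {
  d <- dim(targ)
  out <- array(0, c(d[1], d[2], d[4]))
  for (i in seq_len(d[4])) out[, , i] <- trigDecode(targ[, , , i])
  out
}
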