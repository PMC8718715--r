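#' @include AllGenerics.R
NULL

#' Create a simulation configuration
#'
#' Returns a \linkS4class{SimulationConfig} with defaults calibrated so that
#' the resulting spiral-wave chaos has a dominant rotation period of about 100
#' stored snapshots and is self-sustained over thousands of snapshots: the
#' standard reaction parameter set (a=0.09, k=8.2, eps0=0.01, mu1=0.07,
#' mu2=0.3, D=1), dt=0.05, dx=0.9, an isotropic 9-point Laplacian, snapshots
#' every 10th Euler step, and an S1/S2 cross-field initiation protocol plus
#' seeded random point stimuli (see the package vignette for the calibration
#' rationale).
#'
#' @param gridSize integer(2) rows, columns.
#' @param a,k,eps0,mu1,mu2,D reaction/diffusion parameters.
#' @param dt,dx Euler step and grid spacing.
#' @param stencil 5 or 9 point Laplacian.
#' @param snapshotStride store every n-th step.
#' @param nSnapshots number of stored frames.
#' @param transientTime time units discarded before recording.
#' @param s1Width plane-wave stimulus width in pixels (0 disables S1+S2).
#' @param s2Time time of the cross-field stimulus.
#' @param s2Rows,s2Cols 1-based inclusive pixel ranges of the S2 quadrant;
#'   defaults scale with the grid (lower half rows, left 60% of columns).
#' @param nRandomStims number of seeded random point stimuli.
#' @param stimWindow numeric(2) time window for random stimuli.
#' @param stimRadius,stimAmplitude point stimulus geometry.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nSnapshots = 10L)
#' cfg
#' @export
simulationConfig <- function(gridSize = c(200L, 200L), a = 0.09, k = 8.2,
                             eps0 = 0.01, mu1 = 0.07, mu2 = 0.3, D = 1.0,
                             dt = 0.05, dx = 0.9, stencil = 9L,
                             snapshotStride = 10L, nSnapshots = 500L,
                             transientTime = 180, s1Width = 8L, s2Time = 116,
                             s2Rows = NULL, s2Cols = NULL, nRandomStims = 2L,
                             stimWindow = c(200, 500), stimRadius = 5,
                             stimAmplitude = 1, seed = 1L) {
  gridSize <- as.integer(gridSize)
  if (is.null(s2Rows)) s2Rows <- c(floor(gridSize[1] / 2) + 1, gridSize[1])
  if (is.null(s2Cols)) s2Cols <- c(1, round(0.6 * gridSize[2]))
  new("SimulationConfig", gridSize = gridSize, a = a, k = k, eps0 = eps0,
      mu1 = mu1, mu2 = mu2, D = D, dt = dt, dx = dx,
      stencil = as.integer(stencil), snapshotStride = as.integer(snapshotStride),
      nSnapshots = as.integer(nSnapshots), transientTime = transientTime,
      s1Width = as.integer(s1Width), s2Time = s2Time, s2Rows = s2Rows,
      s2Cols = s2Cols, nRandomStims = as.integer(nRandomStims),
      stimWindow = stimWindow, stimRadius = stimRadius,
      stimAmplitude = stimAmplitude, seed = as.integer(seed))
}

#' Create a fresh simulation state
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with matrices \code{V} and \code{r} (all zero, the resting
#'   fixed point of the dynamics) and step counter \code{t}.
#' @export
newSimState <- function(config) {
  H <- config@gridSize[1]; W <- config@gridSize[2]
  list(V = matrix(0, H, W), r = matrix(0, H, W), t = 0L)
}

#' Advance a simulation state by Euler steps
#'
#' @param state list(V, r, t) as returned by \code{\link{newSimState}}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param nSteps number of Euler steps.
#' @return the advanced state; the input is not modified.
#' @examples
#' cfg <- simulationConfig(gridSize = c(32L, 32L))
#' st <- newSimState(cfg)
#' st <- apStep(st, cfg, 10L)   # zero state is a fixed point
#' stopifnot(all(st$V == 0))
#' @export
apStep <- function(state, config, nSteps = 1L) {
  res <- ap_integrate(state$V, state$r, matrix(0, 0, 6),
                      config@a, config@k, config@eps0, config@mu1, config@mu2,
                      config@D, config@dt, config@dx, config@stencil,
                      as.integer(nSteps), 0L, 1L, 0L)
  list(V = res$V, r = res$r, t = state$t + as.integer(nSteps))
}

#' Apply a point stimulus to a simulation state
#'
#' Raises V to at least \code{amplitude} within a disk; the refractory field
#' is unchanged.
#'
#' @param state list(V, r, t).
#' @param x,y 0-based pixel coordinates of the disk centre.
#' @param radius disk radius in pixels (> 0).
#' @param amplitude excitation value.
#' @return the stimulated state.
#' @export
stimulate <- function(state, x, y, radius, amplitude = 1) {
  if (radius <= 0) stop("radius must be > 0")
  H <- nrow(state$V); W <- ncol(state$V)
  if (x < 0 || x >= W || y < 0 || y >= H) stop("(x, y) outside the grid")
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rows <- matrix(0:(H - 1), H, W)
  inside <- (cols - x)^2 + (rows - y)^2 <= radius^2
  state$V[inside] <- pmax(state$V[inside], amplitude)
  state
}

# Build the event matrix (step, type, p1..p4) for ap_integrate.
# Types: 0 disk stimulus (x, y, radius, amplitude); 1 column band
# (col0, col1, amplitude, -); 2 rectangle (row0, row1, col0, col1), amp 1.
buildEvents <- function(config) {
  ev <- NULL
  if (config@s1Width > 0L) {
    ev <- rbind(ev, c(0, 1, 0, config@s1Width - 1, 1, 0))
    s2step <- round(config@s2Time / config@dt)
    ev <- rbind(ev, c(s2step, 2, config@s2Rows[1] - 1, config@s2Rows[2] - 1,
                      config@s2Cols[1] - 1, config@s2Cols[2] - 1))
  }
  if (config@nRandomStims > 0L) {
    H <- config@gridSize[1]; W <- config@gridSize[2]
    times <- sort(stats::runif(config@nRandomStims, config@stimWindow[1],
                               config@stimWindow[2]))
    margin <- ceiling(config@stimRadius) + 10
    sx <- sample.int(W - 2 * margin, config@nRandomStims, replace = TRUE) +
      margin - 1
    sy <- sample.int(H - 2 * margin, config@nRandomStims, replace = TRUE) +
      margin - 1
    ev <- rbind(ev, cbind(round(times / config@dt), 0, sx, sy,
                          config@stimRadius, config@stimAmplitude))
  }
  if (is.null(ev)) ev <- matrix(0, 0, 6)
  ev[order(ev[, 1]), , drop = FALSE]
}

#' Simulate an excitation movie
#'
#' Integrates the Aliev-Panfilov model from the resting state, initiates
#' spiral-wave chaos by the configured S1/S2 + random stimulation protocol,
#' discards the transient, and records \code{nSnapshots} frames, one every
#' \code{snapshotStride}-th Euler step. Deterministic for a fixed
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return an \linkS4class{ExcitationMovie} with provenance in \code{meta}.
#' @examples
#' cfg <- simulationConfig(gridSize = c(48L, 48L), s1Width = 0L,
#'                         nRandomStims = 0L, transientTime = 0,
#'                         nSnapshots = 5L)
#' mov <- simulateEpisode(cfg)  # no stimuli: stays at rest
#' stopifnot(all(frames(mov) == 0))
#' @export
simulateEpisode <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  oldseed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(config@seed)
  events <- buildEvents(config)
  transSteps <- as.integer(round(config@transientTime / config@dt))
  stride <- config@snapshotStride
  nSteps <- transSteps + (config@nSnapshots - 1L) * stride + 1L
  if (nrow(events) && max(events[, 1]) >= nSteps)
    stop("stimulation events fall outside the integration window")
  H <- config@gridSize[1]; W <- config@gridSize[2]
  res <- ap_integrate(matrix(0, H, W), matrix(0, H, W), events,
                      config@a, config@k, config@eps0, config@mu1, config@mu2,
                      config@D, config@dt, config@dx, config@stencil,
                      nSteps, transSteps, stride, config@nSnapshots)
  if (res$n_recorded != config@nSnapshots)
    stop("internal error: recorded ", res$n_recorded, " of ",
         config@nSnapshots, " snapshots")
  fr <- res$frames
  dim(fr) <- c(H, W, config@nSnapshots)
  new("ExcitationMovie", frames = fr, mask = NULL,
      meta = list(kind = "simulation", seed = config@seed, config = config))
}
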