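#' @include rotormap-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for the excitable-media simulator
#'
#' Holds all reaction, integration and stimulation-protocol parameters of the
#' two-variable Aliev-Panfilov reaction-diffusion model
#' \deqn{\partial V/\partial t = D\nabla^2 V - kV(V-a)(V-1) - Vr}
#' \deqn{\partial r/\partial t = \epsilon(V,r)(kV(a+1-V) - r),\quad
#'   \epsilon(V,r) = \epsilon_0 + \mu_1 r/(V+\mu_2)}
#' integrated with explicit Euler steps on a regular grid with no-flux
#' boundaries. Spiral-wave chaos is initiated by an S1 plane wave, an S2
#' cross-field stimulus into the refractory tail, and a seeded number of
#' random point stimuli; an initial transient is discarded before snapshots
#' are recorded every \code{snapshotStride}-th step.
#'
#' @slot gridSize integer(2), rows and columns (default 200 x 200).
#' @slot a,k,eps0,mu1,mu2 numeric reaction parameters (defaults 0.09, 8.2,
#'   0.01, 0.07, 0.3).
#' @slot D numeric diffusion constant (default 1.0).
#' @slot dt numeric Euler step (default 0.05).
#' @slot dx numeric grid spacing (default 0.9).
#' @slot stencil integer, 5- or 9-point Laplacian (default 9, isotropic).
#' @slot snapshotStride integer, store every n-th step (default 10).
#' @slot nSnapshots integer, number of stored frames.
#' @slot transientTime numeric, time units discarded before recording.
#' @slot s1Width integer, width in pixels of the initial plane-wave stimulus
#'   column band (0 disables S1/S2 initiation).
#' @slot s2Time numeric, time of the cross-field S2 stimulus.
#' @slot s2Rows,s2Cols numeric(2), row/column pixel range (1-based, inclusive)
#'   of the S2 quadrant.
#' @slot nRandomStims integer, number of seeded random point stimuli.
#' @slot stimWindow numeric(2), time window for the random stimuli.
#' @slot stimRadius,stimAmplitude numeric, point-stimulus geometry.
#' @slot seed integer RNG seed (stimulus placement).
#' @export
setClass("SimulationConfig",
  representation(
    gridSize = "integer", a = "numeric", k = "numeric", eps0 = "numeric",
    mu1 = "numeric", mu2 = "numeric", D = "numeric", dt = "numeric",
    dx = "numeric", stencil = "integer", snapshotStride = "integer",
    nSnapshots = "integer", transientTime = "numeric", s1Width = "integer",
    s2Time = "numeric", s2Rows = "numeric", s2Cols = "numeric",
    nRandomStims = "integer", stimWindow = "numeric", stimRadius = "numeric",
    stimAmplitude = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(a = object@a, k = object@k, eps0 = object@eps0, mu1 = object@mu1,
           mu2 = object@mu2, D = object@D, dt = object@dt, dx = object@dx)
  if (any(pos <= 0)) {
    msg <- c(msg, paste("parameters must be > 0:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (length(object@gridSize) != 2L || any(object@gridSize < 8L))
    msg <- c(msg, "gridSize must be two integers >= 8")
  if (!object@stencil %in% c(5L, 9L))
    msg <- c(msg, "stencil must be 5 or 9")
  if (object@snapshotStride < 1L)
    msg <- c(msg, "snapshotStride must be >= 1")
  if (object@nSnapshots < 1L)
    msg <- c(msg, "nSnapshots must be >= 1")
  # explicit-Euler stability bound for the diffusion term
  bound <- object@dx^2 / (4 * object@D)
  if (object@dt > bound)
    msg <- c(msg, sprintf("dt=%g violates the stability bound dx^2/(4D)=%g",
                          object@dt, bound))
  if (length(msg)) msg else TRUE
})

#' Excitation movie
#'
#' A stack of voltage-like scalar fields, stored as an H x W x T array
#' (row = y, column = x, frame = t). An optional binary tissue mask marks
#' valid pixels; masked-out pixels are exactly 0. The \code{meta} list holds
#' provenance (simulation config, seeds, degradations applied) including an
#' optional \code{meta$valid} observation mask from degradation operators.
#'
#' @slot frames numeric array H x W x T.
#' @slot mask logical matrix H x W, or NULL.
#' @slot meta list of provenance entries.
#' @export
setClass("ExcitationMovie",
  representation(frames = "array", mask = "matrixOrNULL", meta = "list")
)

setValidity("ExcitationMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), d[1:2]))
      return("mask dimensions must match frame dimensions")
    out <- !object@mask
    if (any(abs(object@frames[rep(out, d[3])]) > 0))
      return("masked-out pixels must be exactly 0")
  }
  TRUE
})

#' Phase movie
#'
#' Per-pixel instantaneous phase angles in [-pi, pi), stored as an
#' H x W x T array. Missing values (removed outliers, unobserved pixels,
#' outside-mask pixels) are NaN.
#'
#' @slot phases numeric array H x W x T; non-missing values in [-pi, pi).
#' @slot mask logical matrix H x W, or NULL.
#' @slot meta list of provenance entries.
#' @export
setClass("PhaseMovie",
  representation(phases = "array", mask = "matrixOrNULL", meta = "list")
)

setValidity("PhaseMovie", function(object) {
  d <- dim(object@phases)
  if (length(d) != 3L) return("phases must be an H x W x T array")
  v <- object@phases[!is.na(object@phases)]
  if (length(v) && (min(v) < -pi || max(v) >= pi + 1e-12))
    return("non-missing phases must lie in [-pi, pi)")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), d[1:2]))
      return("mask dimensions must match phase dimensions")
    out <- !object@mask
    if (any(!is.na(object@phases[rep(out, d[3])])))
      return("outside-mask pixels must be missing (NaN)")
  }
  TRUE
})

#' Phase singularity set
#'
#' Sub-pixel phase singularity (PS) locations across frames. Coordinates are
#' 0-based with x = column and y = row (origin top-left); detections from the
#' 2x2 line integral sit at plaquette centres (half-integer coordinates).
#' Chirality is +1 / -1 for the rotation sense, or NA when unknown (direct
#' network predictions carry no sign).
#'
#' @slot points data.frame with columns t (1-based frame), x, y, chirality.
#' @slot dims integer(2), image height and width.
#' @slot nFrames integer, number of frames the set refers to.
#' @export
setClass("PhaseSingularitySet",
  representation(points = "data.frame", dims = "integer", nFrames = "integer")
)

setValidity("PhaseSingularitySet", function(object) {
  p <- object@points
  need <- c("t", "x", "y", "chirality")
  if (!all(need %in% names(p)))
    return("points must have columns t, x, y, chirality")
  if (nrow(p)) {
    if (any(p$x < -0.5 | p$x > object@dims[2] - 0.5 |
            p$y < -0.5 | p$y > object@dims[1] - 0.5))
      return("PS coordinates outside image bounds")
    ch <- p$chirality[!is.na(p$chirality)]
    if (length(ch) && !all(ch %in% c(-1, 1)))
      return("chirality must be -1, +1 or NA")
    if (any(p$t < 1 | p$t > object@nFrames))
      return("frame indices out of range")
  }
  TRUE
})

#' Electrode layout
#'
#' A set of circular electrodes (centres in 0-based pixel coordinates,
#' common diameter) used to emulate sparse mapping-catheter observations.
#'
#' @slot centers numeric matrix n x 2, columns x and y.
#' @slot diameter numeric, electrode diameter in pixels.
#' @slot name character layout name.
#' @export
setClass("ElectrodeLayout",
  representation(centers = "matrix", diameter = "numeric", name = "character")
)

setValidity("ElectrodeLayout", function(object) {
  if (ncol(object@centers) != 2L) return("centers must be an n x 2 matrix")
  if (object@diameter <= 0) return("diameter must be > 0")
  TRUE
})

#' Sample specification for dataset assembly
#'
#' Describes how network samples are cut from a movie: \code{nFrames} input
#' frames sampled backwards from \eqn{t_0} at spacing \code{tau}
#' (\eqn{t_0, t_0-\tau, \ldots, t_0-(N_t-1)\tau}), with the target taken at
#' \eqn{t_0 + \Delta} (\code{futureOffset}).
#'
#' @slot nFrames integer N_t in 1..10.
#' @slot tau integer frame sampling distance >= 1.
#' @slot futureOffset integer Delta >= 0.
#' @slot targetKind character: "phase", "ps_classmap" or "ps_coords".
#' @export
setClass("SampleSpec",
  representation(nFrames = "integer", tau = "integer",
                 futureOffset = "integer", targetKind = "character")
)

setValidity("SampleSpec", function(object) {
  if (object@nFrames < 1L || object@nFrames > 10L)
    return("nFrames must be in 1..10")
  if (object@tau < 1L) return("tau must be >= 1")
  if (object@futureOffset < 0L) return("futureOffset must be >= 0")
  if (!object@targetKind %in% c("phase", "ps_classmap", "ps_coords"))
    return("targetKind must be phase, ps_classmap or ps_coords")
  TRUE
})

#' Convolutional network model
#'
#' A compact encoder-decoder network for image-to-image phase or phase
#' singularity prediction. Five variants are provided: \code{M1} (frames
#' stacked as channels, trigonometric phase output), \code{M2} (per-frame
#' shared encoder with a convolutional LSTM latent), \code{M3} (M1 plus long
#' skip connections), \code{M1A} (two-class PS class-map output) and
#' \code{M1B} (single-channel PS probability trained with the weighted
#' Hausdorff loss).
#'
#' @slot variant character, one of M1, M2, M3, M1A, M1B.
#' @slot spec list: architecture hyperparameters (inputFrames, side,
#'   encoderWidths, latentWidth, convsPerStage, head, ...).
#' @slot params list of parameter arrays (convolution weights, biases,
#'   batch-norm scales/shifts).
#' @slot state list of non-trained state (batch-norm running moments,
#'   optimizer state, training history).
#' @export
setClass("RotorNet",
  representation(variant = "character", spec = "list", params = "list",
                 state = "list")
)

setValidity("RotorNet", function(object) {
  if (!object@variant %in% c("M1", "M2", "M3", "M1A", "M1B"))
    return("variant must be one of M1, M2, M3, M1A, M1B")
  TRUE
})

#' Training / evaluation dataset
#'
#' Samples assembled from one or more movies: degraded input frame stacks
#' paired with clean ground-truth targets. Episode provenance is kept so
#' train/test splits can be enforced to be episode-disjoint.
#'
#' @slot inputs numeric array H x W x N_t x N (degraded input frames).
#' @slot targets list: per-kind target arrays/lists (see
#'   \code{\link{buildDataset}}).
#' @slot masks logical array H x W x N or NULL-like empty list element.
#' @slot info data.frame with one row per sample: episode, t0, targetIndex.
#' @slot spec the \linkS4class{SampleSpec} used.
#' @slot meta list of provenance entries (degradation spec, seeds).
#' @export
setClass("RotorDataset",
  representation(inputs = "array", targets = "list", masks = "ANY",
                 info = "data.frame", spec = "SampleSpec", meta = "list")
)
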