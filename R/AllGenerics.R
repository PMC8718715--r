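#' @include AllClasses.R
NULL

#' Extract the frame stack of a movie
#'
#' @param x an \linkS4class{ExcitationMovie}.
#' @return numeric array H x W x T.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "ExcitationMovie", function(x) x@frames)

#' Extract the phase stack of a phase movie
#'
#' @param x a \linkS4class{PhaseMovie}.
#' @return numeric array H x W x T with NaN for missing values.
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname phases
#' @export
setMethod("phases", "PhaseMovie", function(x) x@phases)

#' Extract the tissue mask of a movie
#'
#' @param x an \linkS4class{ExcitationMovie} or \linkS4class{PhaseMovie}.
#' @return logical H x W matrix or NULL.
#' @export
setGeneric("movieMask", function(x) standardGeneric("movieMask"))

#' @rdname movieMask
#' @export
setMethod("movieMask", "ExcitationMovie", function(x) x@mask)

#' @rdname movieMask
#' @export
setMethod("movieMask", "PhaseMovie", function(x) x@mask)

#' Extract the provenance metadata of an object
#'
#' @param x an \linkS4class{ExcitationMovie}, \linkS4class{PhaseMovie} or
#'   \linkS4class{RotorDataset}.
#' @return a list.
#' @export
setGeneric("movieMeta", function(x) standardGeneric("movieMeta"))

#' @rdname movieMeta
#' @export
setMethod("movieMeta", "ExcitationMovie", function(x) x@meta)

#' @rdname movieMeta
#' @export
setMethod("movieMeta", "PhaseMovie", function(x) x@meta)

#' @rdname movieMeta
#' @export
setMethod("movieMeta", "RotorDataset", function(x) x@meta)

#' Extract phase singularity points
#'
#' @param x a \linkS4class{PhaseSingularitySet}.
#' @return data.frame with columns t, x, y, chirality.
#' @export
setGeneric("psPoints", function(x) standardGeneric("psPoints"))

#' @rdname psPoints
#' @export
setMethod("psPoints", "PhaseSingularitySet", function(x) x@points)

#' Number of frames
#'
#' @param x a movie-like object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "ExcitationMovie", function(x) dim(x@frames)[3L])

#' @rdname nFrames
#' @export
setMethod("nFrames", "PhaseMovie", function(x) dim(x@phases)[3L])

#' @rdname nFrames
#' @export
setMethod("nFrames", "PhaseSingularitySet", function(x) x@nFrames)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %dx%d grid, dt=%g, dx=%g, %d-point stencil\n",
    object@gridSize[1], object@gridSize[2], object@dt, object@dx,
    object@stencil))
  cat(sprintf("  reaction: a=%g k=%g eps0=%g mu1=%g mu2=%g D=%g\n",
              object@a, object@k, object@eps0, object@mu1, object@mu2,
              object@D))
  cat(sprintf(
    "  %d snapshots every %d steps after transient %g; seed %d\n",
    object@nSnapshots, object@snapshotStride, object@transientTime,
    object@seed))
  cat(sprintf("  protocol: S1 width %d, S2 at t=%g, %d random stimuli\n",
              object@s1Width, object@s2Time, object@nRandomStims))
  invisible(NULL)
})

setMethod("show", "ExcitationMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ExcitationMovie: %d x %d pixels, %d frames%s\n",
              d[1], d[2], d[3],
              if (is.null(object@mask)) "" else ", masked"))
  cat(sprintf("  value range [%.3g, %.3g]\n",
              min(object@frames), max(object@frames)))
  invisible(NULL)
})

setMethod("show", "PhaseMovie", function(object) {
  d <- dim(object@phases)
  nmiss <- sum(is.na(object@phases))
  cat(sprintf("PhaseMovie: %d x %d pixels, %d frames, %.1f%% missing\n",
              d[1], d[2], d[3], 100 * nmiss / length(object@phases)))
  invisible(NULL)
})

setMethod("show", "PhaseSingularitySet", function(object) {
  cat(sprintf(
    "PhaseSingularitySet: %d detections in %d frames (%d x %d image)\n",
    nrow(object@points), object@nFrames, object@dims[1], object@dims[2]))
  if (nrow(object@points)) {
    cat(sprintf("  mean %.2f per frame; chirality +1: %d, -1: %d, NA: %d\n",
                nrow(object@points) / object@nFrames,
                sum(object@points$chirality == 1, na.rm = TRUE),
                sum(object@points$chirality == -1, na.rm = TRUE),
                sum(is.na(object@points$chirality))))
  }
  invisible(NULL)
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout '%s': %d electrodes, diameter %g px\n",
              object@name, nrow(object@centers), object@diameter))
  invisible(NULL)
})

setMethod("show", "SampleSpec", function(object) {
  cat(sprintf(
    "SampleSpec: N_t=%d, tau=%d, future offset=%d, target '%s'\n",
    object@nFrames, object@tau, object@futureOffset, object@targetKind))
  invisible(NULL)
})

setMethod("show", "RotorNet", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("RotorNet %s: %d input frame(s), %d x %d, %d parameters\n",
              object@variant, object@spec$inputFrames, object@spec$side,
              object@spec$side, np))
  cat(sprintf("  encoder widths %s, latent %d, head %s\n",
              paste(object@spec$encoderWidths, collapse = "/"),
              object@spec$latentWidth, object@spec$head))
  if (!is.null(object@state$history) && nrow(object@state$history))
    cat(sprintf("  trained %d epochs, final val loss %.4g\n",
                nrow(object@state$history),
                utils::tail(object@state$history$val, 1)))
  invisible(NULL)
})

setMethod("show", "RotorDataset", function(object) {
  d <- dim(object@inputs)
  cat(sprintf(
    "RotorDataset: %d samples of %d x %d x %d, target '%s'\n",
    d[4], d[1], d[2], d[3], object@spec@targetKind))
  cat(sprintf("  episodes: %s\n",
              paste(sort(unique(object@info$episode)), collapse = ", ")))
  invisible(NULL)
})
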