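#' @include degrade.R
NULL

asPhaseArray <- function(phase) {
  mask <- NULL
  meta <- list()
  if (is(phase, "PhaseMovie")) {
    mask <- phase@mask
    meta <- phase@meta
    phase <- phase@phases
  }
  d <- dim(phase)
  if (length(d) == 2L) dim(phase) <- c(d, 1L)
  list(ph = phase, mask = mask, meta = meta)
}

maskVec <- function(mask) if (is.null(mask)) logical(0) else as.logical(mask)

#' Complex (phasor) encoding of a phase movie
#'
#' phi -> cos(phi) + i sin(phi) per pixel; missing values propagate. All
#' circular averaging in this module operates on these unit phasors, never on
#' raw angles.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @return complex array of unit modulus (NA where missing).
#' @export
complexEncode <- function(phase) {
  p <- asPhaseArray(phase)
  array(complex(real = cos(p$ph), imaginary = sin(p$ph)), dim(p$ph))
}

#' Kuramoto order parameter map
#'
#' For every pixel and frame, r(x, y; t) = |mean phasor| over a disk-shaped
#' spatio-temporal kernel of diameter \code{d} pixels and \code{dtFrames}
#' frames (centred, truncated at edges); 1 means perfect local phase
#' coherence. Missing values are excluded from the mean; all-missing kernels
#' give NA.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param d kernel disk diameter in pixels.
#' @param dtFrames temporal kernel extent (odd).
#' @return numeric array of r values in [0, 1].
#' @export
kuramotoOrder <- function(phase, d = 5, dtFrames = 3) {
  p <- asPhaseArray(phase)
  kuramoto_movie(cos(p$ph), sin(p$ph), maskVec(p$mask), d,
                 as.integer(dtFrames))
}

#' Remove incoherent phase values (outlier filter)
#'
#' Marks as missing every pixel whose local Kuramoto order parameter
#' (kernel d x dtFrames) falls below \code{rThreshold}; other values are
#' untouched. Idempotent at a fixed threshold only up to the coherence gain
#' of removal; with \code{rThreshold = 0} it is the identity.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param d,dtFrames kernel spec (defaults 5 pixels x 3 frames).
#' @param rThreshold coherence cutoff in (0, 1]; values with r < threshold
#'   are removed.
#' @return a \linkS4class{PhaseMovie} with outliers missing.
#' @export
removeOutliers <- function(phase, d = 5, dtFrames = 3, rThreshold = 0.9) {
  p <- asPhaseArray(phase)
  if (rThreshold > 0) {
    r <- kuramoto_movie(cos(p$ph), sin(p$ph), maskVec(p$mask), d,
                        as.integer(dtFrames))
    p$ph[!is.na(r) & r < rThreshold] <- NaN
  }
  new("PhaseMovie", phases = p$ph, mask = p$mask,
      meta = c(p$meta, list(outlierD = d, outlierThreshold = rThreshold)))
}

#' Inpaint missing phase values
#'
#' Iteratively fills missing values with the argument of the kernel-mean
#' phasor, where the kernel (disk d x dtFrames) holds at least
#' \code{minValidFraction} valid entries. Updates are Jacobi-style (newly
#' filled values become usable only in the next iteration), so the result is
#' sweep-order independent. Runs until filled when \code{iterations = Inf},
#' progressively relaxing \code{minValidFraction} if the fill stalls on very
#' sparse anchors; a fixed iteration count may leave pixels unfilled.
#' Unfilled pixels raise a warning.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param d,dtFrames kernel spec.
#' @param minValidFraction minimum valid fraction of in-image, in-mask kernel
#'   entries (default 0.3).
#' @param iterations iteration count, or Inf to fill completely.
#' @return a \linkS4class{PhaseMovie}.
#' @export
inpaintPhase <- function(phase, d = 5, dtFrames = 3, minValidFraction = 0.3,
                         iterations = Inf) {
  p <- asPhaseArray(phase)
  fillAll <- !is.finite(iterations)
  nIter <- if (fillAll) 1000L else as.integer(iterations)
  res <- inpaint_movie(cos(p$ph), sin(p$ph), maskVec(p$mask), d,
                       as.integer(dtFrames), minValidFraction, nIter, fillAll)
  iterTotal <- res$iterations
  mvf <- minValidFraction
  # fill-to-completion can stall when no remaining kernel reaches the valid
  # fraction (very sparse anchors); relax the requirement until any single
  # valid neighbour suffices, so fills propagate from whatever anchors exist
  while (fillAll && res$unfilled > 0 && mvf > 1e-9) {
    mvf <- mvf / 4
    res <- inpaint_movie(res$cos, res$sin, maskVec(p$mask), d,
                         as.integer(dtFrames), mvf, 1000L, TRUE)
    iterTotal <- iterTotal + res$iterations
  }
  out <- wrapPhase(atan2(res$sin, res$cos))
  out[is.na(res$cos)] <- NaN
  dim(out) <- dim(p$ph)
  if (res$unfilled > 0)
    warning(res$unfilled, " pixels could not be inpainted")
  new("PhaseMovie", phases = out, mask = p$mask,
      meta = c(p$meta, list(inpaintD = d, inpaintIterations = iterTotal,
                            unfilled = res$unfilled)))
}

#' Spatio-temporal phase smoothing
#'
#' Replaces every phase value by the argument of the mean phasor over the
#' disk d x dtFrames kernel. Requires a fully observed movie (run after
#' inpainting); missing values inside the mask are an error.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param d,dtFrames kernel spec (defaults 7 pixels x 3 frames).
#' @return a smoothed \linkS4class{PhaseMovie}.
#' @export
smoothPhase <- function(phase, d = 7, dtFrames = 3) {
  p <- asPhaseArray(phase)
  inside <- if (is.null(p$mask)) TRUE else rep(as.logical(p$mask), dim(p$ph)[3])
  if (any(is.na(p$ph) & inside))
    stop("smoothing requires a fully observed movie; inpaint first")
  res <- smooth_movie(cos(p$ph), sin(p$ph), maskVec(p$mask), d,
                      as.integer(dtFrames))
  out <- wrapPhase(atan2(res$sin, res$cos))
  out[is.na(res$cos)] <- NaN
  dim(out) <- dim(p$ph)
  new("PhaseMovie", phases = out, mask = p$mask,
      meta = c(p$meta, list(smoothD = d)))
}

#' Classical phase restoration pipeline
#'
#' Composes the outlier-removal, inpainting and smoothing stages per
#' observation regime:
#' \describe{
#'   \item{noisy}{outlier removal (d=5, r<0.9) -> inpaint to completion ->
#'     smooth (d=7).}
#'   \item{lowres}{smooth with d=11.}
#'   \item{grid-large, grid-small}{inpaint 7 iterations with d=11 (then to
#'     completion), smooth d=7.}
#'   \item{star}{inpaint 10 iterations with d=19 (then to completion),
#'     smooth d=7.}
#'   \item{sparse}{inpaint to completion, then outlier removal, re-inpaint,
#'     smooth (denoising after inpainting).}
#'   \item{custom}{stages controlled by the arguments; all disabled is the
#'     identity.}
#' }
#' All kernels use dtFrames = 3.
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param preset one of "noisy", "lowres", "grid-large", "grid-small",
#'   "star", "sparse", "custom".
#' @param outlierD,rThreshold custom-stage outlier kernel/threshold (NULL
#'   disables).
#' @param inpaintD,inpaintIterations custom-stage inpainting (NULL disables).
#' @param smoothD custom-stage smoothing diameter (NULL disables).
#' @param dtFrames temporal kernel extent.
#' @return restored \linkS4class{PhaseMovie}.
#' @export
restorePipeline <- function(phase,
                            preset = c("noisy", "lowres", "grid-large",
                                       "grid-small", "star", "sparse",
                                       "custom"),
                            outlierD = NULL, rThreshold = 0.9,
                            inpaintD = NULL, inpaintIterations = Inf,
                            smoothD = NULL, dtFrames = 3) {
  preset <- match.arg(preset)
  finishInpaint <- function(x, d) {
    if (any(is.na(phases(x)) &
            (if (is.null(x@mask)) TRUE else rep(x@mask, dim(phases(x))[3]))))
      inpaintPhase(x, d = d, dtFrames = dtFrames) else x
  }
  switch(preset,
    noisy = {
      x <- removeOutliers(phase, d = 5, dtFrames = dtFrames, rThreshold = 0.9)
      x <- finishInpaint(x, 5)
      smoothPhase(x, d = 7, dtFrames = dtFrames)
    },
    lowres = smoothPhase(phase, d = 11, dtFrames = dtFrames),
    `grid-large` = ,
    `grid-small` = {
      # the first pass is deliberately partial; completion follows below
      x <- suppressWarnings(
        inpaintPhase(phase, d = 11, dtFrames = dtFrames, iterations = 7))
      x <- finishInpaint(x, 11)
      smoothPhase(x, d = 7, dtFrames = dtFrames)
    },
    star = {
      x <- suppressWarnings(
        inpaintPhase(phase, d = 19, dtFrames = dtFrames, iterations = 10))
      x <- finishInpaint(x, 19)
      smoothPhase(x, d = 7, dtFrames = dtFrames)
    },
    sparse = {
      x <- inpaintPhase(phase, d = 5, dtFrames = dtFrames)
      x <- removeOutliers(x, d = 5, dtFrames = dtFrames, rThreshold = 0.9)
      x <- finishInpaint(x, 5)
      smoothPhase(x, d = 7, dtFrames = dtFrames)
    },
    custom = {
      x <- if (is(phase, "PhaseMovie")) phase else {
        p <- asPhaseArray(phase)
        new("PhaseMovie", phases = p$ph, mask = p$mask, meta = p$meta)
      }
      if (!is.null(outlierD))
        x <- removeOutliers(x, d = outlierD, dtFrames = dtFrames,
                            rThreshold = rThreshold)
      if (!is.null(inpaintD))
        x <- inpaintPhase(x, d = inpaintD, dtFrames = dtFrames,
                          iterations = inpaintIterations)
      if (!is.null(smoothD))
        x <- smoothPhase(x, d = smoothD, dtFrames = dtFrames)
      x
    })
}
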