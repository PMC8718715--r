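#' @include nets-model.R
NULL

#' Sample specification constructor
#'
#' @param nFrames number of input frames N_t (1..10).
#' @param tau input frame spacing (frames).
#' @param futureOffset target offset Delta beyond the last input frame.
#' @param targetKind "phase", "ps_classmap" or "ps_coords".
#' @return a \linkS4class{SampleSpec}.
#' @examples
#' sampleSpec(nFrames = 5, targetKind = "phase")
#' @export
sampleSpec <- function(nFrames = 5L, tau = 1L, futureOffset = 0L,
                       targetKind = "phase") {
  new("SampleSpec", nFrames = as.integer(nFrames), tau = as.integer(tau),
      futureOffset = as.integer(futureOffset), targetKind = targetKind)
}

#' Ground-truth phase and phase singularities for a movie
#'
#' For simulated (clean, fully observed) movies the reference phase is the
#' analytic-signal phase of the raw voltage traces and the reference phase
#' singularities are its topological-charge detections. For experimental-style
#' movies the traces are first sliding-window normalized, then phase-mapped
#' and passed through the classical restoration pipeline before detection.
#' Movies shorter than \code{minPeriods} dominant oscillation periods are
#' rejected, since the analytic-signal phase is unreliable there.
#'
#' @param movie an \linkS4class{ExcitationMovie} or H x W x T array.
#' @param kind "simulation" (clean) or "experimental" (normalize + restore).
#' @param preset restoration preset for kind "experimental" (see
#'   \code{\link{restorePipeline}}).
#' @param window sliding normalization window (frames) for "experimental".
#' @param minPeriods minimum movie length in dominant periods (default 2).
#' @return list with elements \code{phase} (\linkS4class{PhaseMovie}) and
#'   \code{ps} (\linkS4class{PhaseSingularitySet}).
#' @export
makeGroundTruth <- function(movie, kind = c("simulation", "experimental"),
                            preset = "noisy", window = 100L, minPeriods = 2) {
  kind <- match.arg(kind)
  movie <- asMovie(movie)
  nT <- dim(movie@frames)[3]
  per <- dominantPeriod(movie)
  # NA means no autocorrelation peak within T/2, i.e. under two periods
  if (is.na(per) || nT < minPeriods * per)
    stop("movie too short for reliable phase ground truth: ", nT,
         " frames < ", minPeriods, " x dominant period (",
         if (is.na(per)) "undetermined" else per, ")")
  if (kind == "simulation") {
    phase <- hilbertPhase(movie)
  } else {
    norm <- slidingWindowNormalize(movie, window = window)
    phase <- restorePipeline(hilbertPhase(norm), preset = preset)
  }
  list(phase = phase, ps = detectPS(phase))
}

#' Apply a named degradation to a movie
#'
#' Dispatch helper used by \code{\link{buildDataset}}; the degradation is a
#' list with a \code{type} field and type-specific parameters:
#' \describe{
#'   \item{none}{identity.}
#'   \item{noise}{\code{sigma}: additive Gaussian noise.}
#'   \item{lowres}{\code{size} coarse side, optional \code{sigma} noise
#'     applied before downsampling.}
#'   \item{layout}{\code{layout} (an \linkS4class{ElectrodeLayout} or a layout
#'     name), optional \code{sigma}.}
#'   \item{sparse}{\code{xi} observed-pixel fraction, optional \code{sigma}
#'     noise applied before sparsification.}
#' }
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param degradation degradation spec list.
#' @param seed noise seed.
#' @return degraded \linkS4class{ExcitationMovie}.
#' @export
degradeMovie <- function(movie, degradation = list(type = "none"), seed = 1L) {
  movie <- asMovie(movie)
  type <- degradation$type %||% "none"
  sg <- degradation$sigma %||% 0
  switch(type,
    none = movie,
    noise = addNoise(movie, sg, seed = seed),
    lowres = {
      m <- if (sg > 0) addNoise(movie, sg, seed = seed) else movie
      lowresMovie(m, degradation$size)
    },
    layout = {
      lay <- degradation$layout
      if (is.character(lay))
        lay <- electrodeLayout(lay, dims = dim(movie@frames)[1:2])
      applyLayout(movie, lay, sigma = sg, seed = seed)
    },
    sparse = {
      m <- if (sg > 0) addNoise(movie, sg, seed = seed) else movie
      sparsify(m, degradation$xi)
    },
    stop("unknown degradation type: ", type))
}

psCoordsAt <- function(ps, frame) {
  p <- ps@points[ps@points$t == frame, c("x", "y"), drop = FALSE]
  as.matrix(p)
}

#' Assemble a training/evaluation dataset from movies
#'
#' Each movie is one episode. Per episode the clean ground truth (phase and
#' phase singularities) is computed first, the movie is then degraded, and
#' samples are cut: inputs are the degraded frames at
#' \eqn{t_0, t_0 - \tau, \ldots}, oldest first; the clean target is taken at
#' \eqn{t_0 + \Delta}. Leading frames without full input history (and, for
#' the analytic-signal ground truth, nothing else) are dropped. Degradation
#' noise seeds are derived per episode from \code{seed}, so the dataset is
#' exactly reproducible.
#'
#' @param movies an \linkS4class{ExcitationMovie} or a (optionally named)
#'   list of them, one per episode.
#' @param spec a \linkS4class{SampleSpec}.
#' @param degradation degradation spec (see \code{\link{degradeMovie}}).
#' @param side optional resize target applied before everything else.
#' @param frameStep spacing between consecutive t0 values (default 1).
#' @param gtKind,gtPreset ground-truth mode (see
#'   \code{\link{makeGroundTruth}}).
#' @param trim frames discarded at each end of every episode before cutting
#'   samples (analytic-signal edge guard; default 20).
#' @param seed degradation seed.
#' @return a \linkS4class{RotorDataset}.
#' @export
buildDataset <- function(movies, spec = sampleSpec(),
                         degradation = list(type = "none"), side = NULL,
                         frameStep = 1L, gtKind = "simulation",
                         gtPreset = "noisy", trim = 20L, seed = 1L) {
  if (!is.list(movies)) movies <- list(movies)
  epNames <- names(movies) %||% paste0("episode", seq_along(movies))
  if (is.null(names(movies))) names(movies) <- epNames
  inputsL <- list(); targetsL <- list(); masksL <- list(); infoL <- list()
  hist <- (spec@nFrames - 1L) * spec@tau
  for (e in seq_along(movies)) {
    mv <- asMovie(movies[[e]])
    if (!is.null(side)) mv <- resizeMovie(mv, side)
    gt <- makeGroundTruth(mv, kind = gtKind, preset = gtPreset)
    deg <- degradeMovie(mv, degradation, seed = seed + e - 1L)
    fr <- deg@frames
    d <- dim(fr)
    t0s <- seq(trim + hist + 1L, d[3] - spec@futureOffset - trim,
               by = frameStep)
    if (!length(t0s))
      stop("episode ", epNames[e], " too short for the sample spec")
    ph <- phases(gt$phase)
    tissue <- mv@mask %||% matrix(TRUE, d[1], d[2])
    for (t0 in t0s) {
      tin <- t0 - seq(hist, 0L, by = -spec@tau)
      tt <- t0 + spec@futureOffset
      inputsL[[length(inputsL) + 1L]] <- fr[, , tin, drop = FALSE]
      targetsL[[length(targetsL) + 1L]] <- switch(spec@targetKind,
        phase = trigEncode(ph[, , tt]),
        ps_classmap = encodePSClassMap(gt$ps, dims = d[1:2], frame = tt),
        ps_coords = psCoordsAt(gt$ps, tt))
      masksL[[length(masksL) + 1L]] <- tissue & !is.na(ph[, , tt])
      infoL[[length(infoL) + 1L]] <-
        data.frame(episode = epNames[e], t0 = t0, targetFrame = tt)
    }
  }
  N <- length(inputsL)
  d <- dim(inputsL[[1]])
  inputs <- array(unlist(inputsL, use.names = FALSE),
                  c(d[1], d[2], spec@nFrames, N))
  targets <- if (spec@targetKind == "ps_coords") list(coords = targetsL)
    else {
      td <- dim(targetsL[[1]])
      arr <- array(unlist(targetsL, use.names = FALSE), c(td, N))
      stats::setNames(list(arr), spec@targetKind)
    }
  masks <- array(unlist(masksL, use.names = FALSE), c(d[1], d[2], N))
  new("RotorDataset", inputs = inputs, targets = targets, masks = masks,
      info = do.call(rbind, infoL), spec = spec,
      meta = list(degradation = degradation, seed = seed, side = side,
                  gtKind = gtKind, trim = trim, frameStep = frameStep))
}

subsetDataset <- function(dataset, idx) {
  targets <- dataset@targets
  if (dataset@spec@targetKind == "ps_coords") {
    targets[[1]] <- targets[[1]][idx]
  } else {
    targets[[1]] <- targets[[1]][, , , idx, drop = FALSE]
  }
  new("RotorDataset",
      inputs = dataset@inputs[, , , idx, drop = FALSE],
      targets = targets,
      masks = dataset@masks[, , idx, drop = FALSE],
      info = dataset@info[idx, , drop = FALSE],
      spec = dataset@spec, meta = dataset@meta)
}

#' Episode-disjoint train/test split
#'
#' Splits a dataset so that no episode contributes samples to both parts.
#' Requires at least two episodes; whole episodes are assigned to the test
#' part at random (seeded) until \code{testFraction} of episodes is reached.
#'
#' @param dataset a \linkS4class{RotorDataset}.
#' @param testFraction fraction of episodes held out (default 0.5).
#' @param seed assignment seed.
#' @return list with \code{train} and \code{test}
#'   \linkS4class{RotorDataset}s.
#' @export
splitDataset <- function(dataset, testFraction = 0.5, seed = 1L) {
  eps <- unique(dataset@info$episode)
  if (length(eps) < 2L)
    stop("episode-disjoint split requires at least 2 episodes")
  nTest <- max(1L, min(length(eps) - 1L, round(testFraction * length(eps))))
  testEps <- withSeed(seed, sample(eps, nTest))
  isTest <- dataset@info$episode %in% testEps
  list(train = subsetDataset(dataset, which(!isTest)),
       test = subsetDataset(dataset, which(isTest)))
}
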