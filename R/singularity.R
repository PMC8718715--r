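#' @include phasecore.R
NULL

newPSSet <- function(points, dims, nframes) {
  points <- as.data.frame(points)
  if (!nrow(points))
    points <- data.frame(t = integer(), x = numeric(), y = numeric(),
                         chirality = numeric())
  new("PhaseSingularitySet", points = points, dims = as.integer(dims),
      nFrames = as.integer(nframes))
}

#' Detect phase singularities by the 2x2 line integral
#'
#' For every 2x2 pixel plaquette, the four phase differences around the
#' closed loop are wrap-corrected to (-pi, pi] and summed; a sum of +/- 2 pi
#' marks a phase singularity at the plaquette centre, with the sign giving
#' the chirality. Plaquettes containing missing values or pixels outside the
#' mask are skipped.
#'
#' @param phase a \linkS4class{PhaseMovie}, or an H x W phase matrix, or an
#'   H x W x T array.
#' @param mask optional logical H x W matrix restricting detection.
#' @param tol tolerance on |sum| - 2 pi (the discrete sum is exactly 0 or
#'   +/- 2 pi up to rounding).
#' @return a \linkS4class{PhaseSingularitySet} with 0-based half-integer
#'   coordinates (x = column, y = row).
#' @examples
#' g <- expand.grid(y = 0:31, x = 0:31)
#' vortex <- matrix(atan2(g$y - 15.2, g$x - 16.1), 32, 32)
#' psPoints(detectPS(vortex))
#' @export
detectPS <- function(phase, mask = NULL, tol = 1e-6) {
  if (is(phase, "PhaseMovie")) {
    if (is.null(mask)) mask <- phase@mask
    phase <- phase@phases
  }
  d <- dim(phase)
  if (length(d) == 2L) dim(phase) <- c(d, 1L)
  d <- dim(phase)
  m <- if (is.null(mask)) logical(0) else as.logical(mask)
  res <- ps_detect(phase, m, tol)
  newPSSet(res, d[1:2], d[3])
}

#' Encode a PS set as a two-channel class map
#'
#' Builds the categorical target image for class-map PS prediction: the PS
#' channel is 1 on the four pixels surrounding each singularity (its 2x2
#' plaquette), the background channel is the complement, so the two channels
#' sum to one everywhere.
#'
#' @param ps a \linkS4class{PhaseSingularitySet} (single frame selected via
#'   \code{frame}).
#' @param dims integer(2) image height and width (default: from \code{ps}).
#' @param frame which frame of \code{ps} to encode.
#' @return numeric array H x W x 2 (background, PS).
#' @export
encodePSClassMap <- function(ps, dims = NULL, frame = 1L) {
  if (is.null(dims)) dims <- ps@dims
  H <- dims[1]; W <- dims[2]
  pts <- ps@points[ps@points$t == frame, , drop = FALSE]
  psch <- matrix(0, H, W)
  if (nrow(pts)) {
    if (any(pts$x < 0 | pts$x > W - 1 | pts$y < 0 | pts$y > H - 1))
      stop("PS coordinates out of bounds for the requested shape")
    for (i in seq_len(nrow(pts))) {
      rows <- unique(pmin(pmax(floor(pts$y[i]) + c(0L, 1L), 0L), H - 1L)) + 1L
      cols <- unique(pmin(pmax(floor(pts$x[i]) + c(0L, 1L), 0L), W - 1L)) + 1L
      psch[rows, cols] <- 1
    }
  }
  out <- array(0, c(H, W, 2L))
  out[, , 1] <- 1 - psch
  out[, , 2] <- psch
  out
}

#' Decode a binary PS prediction image
#'
#' Finds 8-connected components (pixels adjacent by edges or corners belong
#' to one object) and emits one PS per component at its centroid, optionally
#' intensity-weighted. Chirality is NA (binary detections carry no sign).
#'
#' @param img logical (or 0/1) H x W matrix.
#' @param frame frame index to record.
#' @param weights optional H x W intensity map for weighted centroids.
#' @return a \linkS4class{PhaseSingularitySet}.
#' @export
decodePSMap <- function(img, frame = 1L, weights = NULL) {
  img <- matrix(as.logical(img), nrow(img), ncol(img))
  lab <- label_components8(img)
  n <- max(lab)
  if (n == 0)
    return(newPSSet(NULL, dim(img), frame))
  xs <- ys <- numeric(n)
  cols <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  rows <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  w <- if (is.null(weights)) matrix(1, nrow(img), ncol(img)) else weights
  for (i in seq_len(n)) {
    sel <- lab == i
    ws <- w[sel]
    xs[i] <- sum(cols[sel] * ws) / sum(ws)
    ys[i] <- sum(rows[sel] * ws) / sum(ws)
  }
  newPSSet(data.frame(t = frame, x = xs, y = ys, chirality = NA_real_),
           dim(img), frame)
}

#' Phase singularities from a probability map
#'
#' Thresholds a per-pixel PS probability image and decodes the connected
#' components (\code{\link{decodePSMap}}), using the probabilities as
#' centroid weights when \code{weighted}.
#'
#' @param prob numeric H x W map in [0, 1], or H x W x T array.
#' @param threshold binarization level in (0, 1).
#' @param frame frame index recorded for matrix input.
#' @param weighted use intensity-weighted centroids.
#' @return a \linkS4class{PhaseSingularitySet}.
#' @export
psFromProbability <- function(prob, threshold = 0.5, frame = 1L,
                              weighted = TRUE) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be inside (0, 1)")
  if (min(prob, na.rm = TRUE) < 0 || max(prob, na.rm = TRUE) > 1)
    stop("probabilities must lie in [0, 1]")
  d <- dim(prob)
  if (length(d) == 3L) {
    sets <- lapply(seq_len(d[3]), function(t) {
      psFromProbability(prob[, , t], threshold, t, weighted)@points
    })
    return(newPSSet(do.call(rbind, sets), d[1:2], d[3]))
  }
  bin <- prob >= threshold
  bin[is.na(bin)] <- FALSE
  decodePSMap(bin, frame, weights = if (weighted) prob else NULL)
}

#' Assign chirality to decoded PS from a phase map
#'
#' Re-derives the rotation sense of signless detections from the winding of
#' an accompanying phase map around each detection (majority sign of nearby
#' plaquette charges).
#'
#' @param ps a \linkS4class{PhaseSingularitySet} (single-frame entries get
#'   the matching frame of \code{phase}).
#' @param phase H x W matrix or H x W x T array of phases.
#' @param radius search radius in pixels around each detection.
#' @return the PS set with chirality filled in where determinable.
#' @export
assignChirality <- function(ps, phase, radius = 2) {
  d <- dim(phase)
  if (length(d) == 2L) dim(phase) <- c(d, 1L)
  ref <- detectPS(phase)
  pts <- ps@points
  rp <- ref@points
  for (i in seq_len(nrow(pts))) {
    cand <- rp[rp$t == pts$t[i], , drop = FALSE]
    if (!nrow(cand)) next
    dd <- sqrt((cand$x - pts$x[i])^2 + (cand$y - pts$y[i])^2)
    near <- which(dd <= radius)
    if (length(near))
      pts$chirality[i] <- sign(sum(cand$chirality[near]) + 0.5 * 0)
  }
  pts$chirality[pts$chirality == 0] <- NA_real_
  newPSSet(pts, ps@dims, ps@nFrames)
}
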