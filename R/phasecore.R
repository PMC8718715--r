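#' @include apsim.R
NULL

#' Wrap angles onto [-pi, pi)
#'
#' @param phi numeric vector/array of angles in radians.
#' @return angles wrapped onto the half-open interval [-pi, pi).
#' @examples
#' wrapPhase(c(-pi, pi, 3 * pi / 2))
#' @export
wrapPhase <- function(phi) ((phi + pi) %% (2 * pi)) - pi

# Analytic-signal phase of the columns of a T x P matrix (mean-subtracted),
# via the FFT construction of the analytic signal.
analyticPhaseMatrix <- function(x) {
  n <- nrow(x)
  x <- sweep(x, 2L, colMeans(x))
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  wrapPhase(Arg(z))
}

#' Hilbert-transform instantaneous phase
#'
#' Computes the instantaneous phase as the argument of the analytic signal of
#' the mean-subtracted excitation trace, pixel-wise for movies. The analytic
#' signal is built by the standard FFT construction (positive frequencies
#' doubled, negative zeroed).
#'
#' @param x numeric vector (a single pixel trace), or an
#'   \linkS4class{ExcitationMovie}, or an H x W x T array.
#' @param chunk number of pixels transformed per FFT block (memory control).
#' @return for a vector input, a phase vector in [-pi, pi); for movie input,
#'   a \linkS4class{PhaseMovie}. Constant pixel traces are an error for
#'   vector input and are marked missing for movie input.
#' @examples
#' t <- 0:999
#' ph <- hilbertPhase(sin(2 * pi * t / 100))
#' # phase advances 2*pi per 100 frames
#' mean(diff(ph[100:900]) %% (2 * pi)) * 100 / (2 * pi)
#' @export
hilbertPhase <- function(x, chunk = 4096L) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) < 4L) stop("trace too short")
    if (max(x) - min(x) <= 0) stop("degenerate (constant) trace")
    return(drop(analyticPhaseMatrix(matrix(x, ncol = 1))))
  }
  mask <- NULL
  meta <- list()
  if (is(x, "ExcitationMovie")) {
    mask <- x@mask
    meta <- x@meta
    x <- x@frames
  }
  d <- dim(x)
  if (length(d) != 3L) stop("expected an H x W x T array or ExcitationMovie")
  P <- d[1] * d[2]
  m <- matrix(x, nrow = P, ncol = d[3])
  out <- matrix(NaN, P, d[3])
  rng <- matrixStats_range(m)
  live <- rng[, 2] - rng[, 1] > 0
  if (!is.null(mask)) live <- live & as.vector(mask)
  idx <- which(live)
  for (s in seq(1L, length(idx), by = chunk)) {
    ii <- idx[s:min(s + chunk - 1L, length(idx))]
    out[ii, ] <- t(analyticPhaseMatrix(t(m[ii, , drop = FALSE])))
  }
  dim(out) <- d
  new("PhaseMovie", phases = out, mask = mask,
      meta = c(meta, list(phaseMethod = "hilbert")))
}

# per-row min/max without extra dependencies
matrixStats_range <- function(m) {
  cbind(do.call(pmin, as.data.frame(m)), do.call(pmax, as.data.frame(m)))
}

#' Automatic embedding delay
#'
#' Chooses the delay-embedding lag as roughly a quarter of the average cycle
#' length: the first zero crossing of the autocorrelation of the
#' mean-subtracted trace.
#'
#' @param x numeric trace.
#' @return integer lag >= 1.
#' @export
autoEmbedDelay <- function(x) {
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = length(x) %/% 2, plot = FALSE)$acf
  z <- which(ac <= 0)
  if (!length(z)) stop("no zero crossing in the autocorrelation")
  max(1L, z[1] - 1L)
}

#' Delay-embedding phase
#'
#' Phase by time-delay embedding: phi(t) = arctan2(V*(t), V*(t + tau)) on the
#' mean-centred trace V*. The last tau samples have no future partner and are
#' marked missing.
#'
#' @param x numeric vector, \linkS4class{ExcitationMovie}, or H x W x T array.
#' @param tauEmbed integer delay in frames; NULL selects about a quarter cycle
#'   via \code{\link{autoEmbedDelay}} (movie input pools a central-pixel
#'   trace).
#' @return phase vector or \linkS4class{PhaseMovie}, as for
#'   \code{\link{hilbertPhase}}.
#' @export
delayEmbeddingPhase <- function(x, tauEmbed = NULL) {
  traceFun <- function(v, tau) {
    v <- v - mean(v)
    n <- length(v)
    out <- rep(NaN, n)
    out[1:(n - tau)] <- atan2(v[1:(n - tau)], v[(tau + 1):n])
    wrapPhase(out)
  }
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(tauEmbed)) tauEmbed <- autoEmbedDelay(x)
    tauEmbed <- as.integer(tauEmbed)
    if (tauEmbed < 1L) stop("tauEmbed must be >= 1")
    if (tauEmbed >= length(x)) stop("tauEmbed must be smaller than the trace")
    return(traceFun(x, tauEmbed))
  }
  mask <- NULL
  meta <- list()
  if (is(x, "ExcitationMovie")) {
    mask <- x@mask
    meta <- x@meta
    x <- x@frames
  }
  d <- dim(x)
  if (is.null(tauEmbed))
    tauEmbed <- autoEmbedDelay(x[ceiling(d[1] / 2), ceiling(d[2] / 2), ])
  tauEmbed <- as.integer(tauEmbed)
  if (tauEmbed >= d[3]) stop("tauEmbed must be smaller than the movie length")
  P <- d[1] * d[2]
  m <- matrix(x, P, d[3])
  mc <- m - rowMeans(m)
  n <- d[3]
  out <- matrix(NaN, P, n)
  out[, 1:(n - tauEmbed)] <-
    atan2(mc[, 1:(n - tauEmbed), drop = FALSE],
          mc[, (tauEmbed + 1):n, drop = FALSE])
  out <- wrapPhase(out)
  if (!is.null(mask)) out[!as.vector(mask), ] <- NaN
  dim(out) <- d
  new("PhaseMovie", phases = out, mask = mask,
      meta = c(meta, list(phaseMethod = "delay-embedding",
                          tauEmbed = tauEmbed)))
}

#' Linear upstroke-interpolated phase
#'
#' Detects upstrokes (upward crossings of a threshold) and assigns phase as a
#' piecewise-linear ramp from -pi at one upstroke to pi at the next. Samples
#' before the first and after the last upstroke are missing.
#'
#' @param x numeric trace.
#' @param upstrokeThreshold crossing level (default 0.5).
#' @return phase vector in [-pi, pi) with NaN outside the covered cycles.
#' @export
linearInterpPhase <- function(x, upstrokeThreshold = 0.5) {
  n <- length(x)
  up <- which(x[-n] < upstrokeThreshold & x[-1] >= upstrokeThreshold) + 1L
  if (length(up) < 2L)
    stop("insufficient cycles: fewer than 2 upstrokes detected")
  out <- rep(NaN, n)
  for (i in seq_len(length(up) - 1L)) {
    j <- up[i]:up[i + 1]
    out[j] <- -pi + 2 * pi * (j - up[i]) / (up[i + 1] - up[i])
  }
  wrapPhase(out)
}

#' Sliding-window min-max normalization
#'
#' Per pixel and frame, rescales the excitation by the running minimum and
#' maximum over a centred temporal window (truncated at the movie edges) so
#' values land in [0, 1]. Pixels whose window is constant map to 0 and are
#' flagged in \code{meta$flagged}.
#'
#' @param movie an \linkS4class{ExcitationMovie} or H x W x T array.
#' @param window window length in frames (>= 2; typically one cycle).
#' @return an \linkS4class{ExcitationMovie} in [0, 1].
#' @export
slidingWindowNormalize <- function(movie, window = 100L) {
  if (window < 2L) stop("window must be >= 2")
  mask <- NULL
  meta <- list()
  if (is(movie, "ExcitationMovie")) {
    mask <- movie@mask
    meta <- movie@meta
    movie <- movie@frames
  }
  res <- sliding_window_minmax(movie, as.integer(window))
  fr <- res$frames
  if (!is.null(mask)) fr[rep(!mask, dim(fr)[3])] <- 0
  new("ExcitationMovie", frames = fr, mask = mask,
      meta = c(meta, list(normalized = TRUE, window = as.integer(window),
                          flagged = res$flagged)))
}

#' Trigonometric phase encoding
#'
#' Maps phase angles onto the unit circle, phi -> (cos phi, sin phi), the
#' regression target of the phase-predicting networks.
#'
#' @param phase numeric array of angles (any shape); NaN propagates.
#' @return array of dimension c(dim(phase), 2) with cosine and sine channels.
#' @examples
#' e <- trigEncode(matrix(c(0, pi / 2), 1, 2))
#' e[1, 1, ]  # (1, 0)
#' @export
trigEncode <- function(phase) {
  d <- dim(phase)
  if (is.null(d)) d <- length(phase)
  out <- c(cos(phase), sin(phase))
  dim(out) <- c(d, 2L)
  out
}

#' Trigonometric phase decoding
#'
#' Inverse of \code{\link{trigEncode}}: phi = arctan2(s, c). Magnitude
#' invariant, so unnormalized network outputs decode directly. The undefined
#' point (0, 0) decodes to NaN.
#'
#' @param enc array whose last dimension has extent 2 (cosine, sine).
#' @return array of angles in [-pi, pi) with the last dimension dropped.
#' @export
trigDecode <- function(enc) {
  d <- dim(enc)
  if (is.null(d) || d[length(d)] != 2L)
    stop("enc must have a trailing dimension of extent 2")
  n <- prod(d[-length(d)])
  cc <- enc[seq_len(n)]
  ss <- enc[n + seq_len(n)]
  phi <- atan2(ss, cc)
  phi[cc == 0 & ss == 0] <- NaN
  phi <- wrapPhase(phi)
  if (length(d) > 2L) dim(phi) <- d[-length(d)]
  else if (length(d) == 2L) phi <- as.vector(phi)
  phi
}
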