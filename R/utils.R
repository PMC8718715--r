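#' @include restore.R
NULL

#' Dominant oscillation period of a movie
#'
#' Estimates the dominant rotational period (in frames) of spiral-wave
#' activity from single-pixel voltage traces: the autocorrelation of each
#' sampled mean-subtracted trace is pooled and the first positive-lag maximum
#' beyond the initial decay is returned.
#'
#' @param movie \linkS4class{ExcitationMovie} or H x W x T array.
#' @param nPixels number of evenly spread pixels to pool.
#' @param minLag smallest admissible period in frames.
#' @return numeric period estimate in frames, or NA when no autocorrelation
#'   peak exists within half the movie length (period undetermined).
#' @examples
#' tt <- seq_len(600)
#' mov <- array(rep(sin(2 * pi * tt / 100), each = 16), c(4, 4, 600))
#' dominantPeriod(mov)
#' @export
dominantPeriod <- function(movie, nPixels = 64L, minLag = 10L) {
  if (is(movie, "ExcitationMovie")) movie <- movie@frames
  d <- dim(movie)
  P <- d[1] * d[2]
  m <- matrix(movie, P, d[3])
  live <- which(apply(m, 1, function(v) max(v) - min(v)) > 0)
  if (!length(live)) stop("movie has no non-constant pixels")
  sel <- live[unique(round(seq(1, length(live),
                               length.out = min(nPixels, length(live)))))]
  maxLag <- d[3] %/% 2
  pooled <- numeric(maxLag + 1)
  for (i in sel) {
    v <- m[i, ] - mean(m[i, ])
    pooled <- pooled + stats::acf(v, lag.max = maxLag, plot = FALSE,
                                  demean = FALSE)$acf[, 1, 1]
  }
  pooled <- pooled / length(sel)
  lo <- as.integer(minLag)
  seg <- pooled[(lo + 1):(maxLag + 1)]
  # first local maximum after the zero-lag decay that is an actual peak
  cand <- which(diff(sign(diff(seg))) == -2) + 1L
  if (!length(cand)) return(NA_real_)
  peak <- cand[seg[cand] >= 0.5 * max(seg[cand])][1]
  as.numeric(peak + lo - 1L)
}

#' Resize a movie
#'
#' Bilinear (with antialiasing filter) frame-by-frame resizing, used to bring
#' simulated movies to the network input resolution.
#'
#' @param movie \linkS4class{ExcitationMovie}, \linkS4class{PhaseMovie} (via
#'   phasor channels) or array.
#' @param side target square side in pixels.
#' @return resized object of the same class.
#' @export
resizeMovie <- function(movie, side) {
  resizeArr <- function(a) {
    d <- dim(a)
    out <- array(0, c(side, side, d[3]))
    for (t in seq_len(d[3]))
      out[, , t] <- EBImage::resize(a[, , t], w = side, h = side,
                                    antialias = TRUE)
    out
  }
  if (is(movie, "ExcitationMovie")) {
    mask <- movie@mask
    if (!is.null(mask))
      mask <- EBImage::resize(mask + 0, w = side, h = side) >= 0.5
    fr <- resizeArr(movie@frames)
    if (!is.null(mask)) fr[rep(!mask, dim(fr)[3])] <- 0
    return(new("ExcitationMovie", frames = fr, mask = mask,
               meta = c(movie@meta, list(resizedTo = side))))
  }
  if (is(movie, "PhaseMovie")) {
    # resize on the phasor channels to respect circularity
    cc <- resizeArr(cos(movie@phases))
    ss <- resizeArr(sin(movie@phases))
    ph <- wrapPhase(atan2(ss, cc))
    mask <- movie@mask
    if (!is.null(mask)) {
      mask <- EBImage::resize(mask + 0, w = side, h = side) >= 0.5
      ph[rep(!mask, dim(ph)[3])] <- NaN
    }
    return(new("PhaseMovie", phases = ph, mask = mask,
               meta = c(movie@meta, list(resizedTo = side))))
  }
  resizeArr(movie)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
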