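#' @include metrics.R
NULL

asMovie <- function(x) {
  if (is(x, "ExcitationMovie")) return(x)
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  new("ExcitationMovie", frames = x, mask = NULL, meta = list())
}

withSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Add Gaussian white noise to a movie
#'
#' Adds i.i.d. N(0, sigma^2) noise to every pixel of every frame,
#' independently in space and time. Values are not clipped, so the noisy
#' movie can leave [0, 1]. Identical seeds give identical realizations.
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param sigma noise standard deviation (>= 0) in excitation units.
#' @param seed integer RNG seed.
#' @return a noisy \linkS4class{ExcitationMovie}.
#' @export
addNoise <- function(movie, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  movie <- asMovie(movie)
  if (sigma == 0) return(movie)
  fr <- movie@frames
  fr <- fr + withSeed(seed, array(stats::rnorm(length(fr), 0, sigma), dim(fr)))
  mask <- movie@mask
  if (!is.null(mask)) fr[rep(!mask, dim(fr)[3])] <- 0
  new("ExcitationMovie", frames = fr, mask = mask,
      meta = c(movie@meta, list(noiseSigma = sigma, noiseSeed = seed)))
}

#' Sparsify a movie to every n-th pixel
#'
#' Emulates electrode-like subsampling: keeps pixels whose row and column are
#' multiples of the stride n = round(1 / xi) (0-based), sets all others to 0.
#' xi names the per-axis fraction of retained pixels, so xi = 0.125 keeps a
#' 16 x 16 subgrid of a 128 x 128 image. The observation mask of kept pixels
#' is attached as \code{meta$valid}.
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param xi per-axis sparsity fraction; 1/xi must be within 1e-6 of an
#'   integer (admissible values 1, 1/2, 1/3, ...).
#' @return sparsified \linkS4class{ExcitationMovie}.
#' @export
sparsify <- function(movie, xi) {
  if (xi <= 0 || xi > 1) stop("xi must be in (0, 1]")
  n <- round(1 / xi)
  if (abs(1 / xi - n) > 0.05 * n)
    stop("xi must correspond to an integer stride; admissible values are ",
         "1, 0.5, 0.33, 0.25, 0.2, 0.17, 0.125, ... (1/n)")
  movie <- asMovie(movie)
  d <- dim(movie@frames)
  valid <- matrix(FALSE, d[1], d[2])
  valid[seq(1, d[1], by = n), seq(1, d[2], by = n)] <- TRUE
  fr <- movie@frames
  fr[rep(!valid, d[3])] <- 0
  new("ExcitationMovie", frames = fr, mask = movie@mask,
      meta = c(movie@meta, list(xi = xi, stride = n, valid = valid)))
}

#' Low-resolution degradation
#'
#' Block-averages each frame down to size x size pixels and replicates
#' (nearest-neighbour) back to the original resolution, emulating a
#' low-resolution sensor.
#'
#' @param movie \linkS4class{ExcitationMovie} or array; frame side must be
#'   divisible by \code{size}.
#' @param size target low resolution (pixels per side).
#' @return degraded \linkS4class{ExcitationMovie}.
#' @export
lowresMovie <- function(movie, size) {
  movie <- asMovie(movie)
  d <- dim(movie@frames)
  if (d[1] %% size || d[2] %% size)
    stop("frame dimensions must be divisible by size")
  by <- d[1] %/% size; bx <- d[2] %/% size
  fr <- movie@frames
  # block mean via dimension folding, then nearest replication
  dim(fr) <- c(by, size, bx, size, d[3])
  small <- apply(fr, c(2, 4, 5), mean)
  up <- small[rep(seq_len(size), each = by), rep(seq_len(size), each = bx), ,
              drop = FALSE]
  dim(up) <- d
  new("ExcitationMovie", frames = up, mask = movie@mask,
      meta = c(movie@meta, list(lowresSize = size)))
}

#' Construct an electrode layout
#'
#' Built-in layouts for a dims[1] x dims[2] image: the 8 x 8 grids of round
#' electrodes with 16-pixel spacing and diameters 15 ("grid8x8-large") or 11
#' ("grid8x8-small"), and a parametric star of concentric rings
#' ("star"). Custom layouts pass explicit centres.
#'
#' @param name one of "grid8x8-large", "grid8x8-small", "star", "custom".
#' @param dims integer(2) image height and width (default 128 x 128).
#' @param centers n x 2 matrix (x, y) for custom layouts.
#' @param diameter electrode diameter for custom/star layouts.
#' @param rings,perRing star geometry: number of rings and electrodes on the
#'   outermost ring.
#' @return an \linkS4class{ElectrodeLayout}.
#' @export
electrodeLayout <- function(name = c("grid8x8-large", "grid8x8-small", "star",
                                     "custom"),
                            dims = c(128L, 128L), centers = NULL,
                            diameter = NULL, rings = 5L, perRing = 12L) {
  name <- match.arg(name)
  H <- dims[1]; W <- dims[2]
  if (name %in% c("grid8x8-large", "grid8x8-small")) {
    spacing <- 16
    off <- (c(W, H) - 7 * spacing) / 2
    g <- expand.grid(x = off[1] + spacing * 0:7, y = off[2] + spacing * 0:7)
    centers <- as.matrix(g)
    diameter <- if (name == "grid8x8-large") 15 else 11
  } else if (name == "star") {
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    rmax <- 0.45 * min(H, W)
    pts <- matrix(c(cx, cy), 1, 2)
    for (i in seq_len(rings)) {
      rad <- rmax * i / rings
      nseg <- max(4L, round(perRing * i / rings))
      th <- 2 * pi * (seq_len(nseg) - 1) / nseg + (i %% 2) * pi / nseg
      pts <- rbind(pts, cbind(cx + rad * cos(th), cy + rad * sin(th)))
    }
    centers <- pts
    if (is.null(diameter)) diameter <- 9
  } else {
    if (is.null(centers) || is.null(diameter))
      stop("custom layouts need centers and diameter")
    centers <- as.matrix(centers)
  }
  colnames(centers) <- c("x", "y")
  new("ElectrodeLayout", centers = centers, diameter = diameter, name = name)
}

layoutMask <- function(layout, dims) {
  H <- dims[1]; W <- dims[2]
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rows <- matrix(0:(H - 1), H, W)
  m <- matrix(FALSE, H, W)
  r2 <- (layout@diameter / 2)^2
  for (i in seq_len(nrow(layout@centers))) {
    m <- m | ((cols - layout@centers[i, 1])^2 +
                (rows - layout@centers[i, 2])^2 <= r2)
  }
  m
}

#' Apply an electrode layout to a movie
#'
#' Retains the signal (plus optional additive Gaussian noise) inside the
#' electrode disks and zeroes everything else. The kept-pixel mask is
#' attached as \code{meta$valid}.
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param layout an \linkS4class{ElectrodeLayout}.
#' @param sigma noise added to the retained pixels (before zeroing).
#' @param seed RNG seed for the noise.
#' @return degraded \linkS4class{ExcitationMovie}.
#' @export
applyLayout <- function(movie, layout, sigma = 0, seed = 1L) {
  movie <- asMovie(movie)
  d <- dim(movie@frames)
  valid <- layoutMask(layout, d[1:2])
  if (sigma > 0) movie <- addNoise(movie, sigma, seed)
  fr <- movie@frames
  fr[rep(!valid, d[3])] <- 0
  new("ExcitationMovie", frames = fr, mask = movie@mask,
      meta = c(movie@meta, list(layout = layout@name, valid = valid)))
}

#' Apply a tissue mask to a movie
#'
#' Sets pixels outside the mask to exactly 0 and attaches the mask.
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param mask logical H x W matrix.
#' @return masked \linkS4class{ExcitationMovie}.
#' @export
applyMask <- function(movie, mask) {
  movie <- asMovie(movie)
  d <- dim(movie@frames)
  if (!identical(dim(mask), d[1:2])) stop("mask shape mismatch")
  mask <- matrix(as.logical(mask), d[1], d[2])
  fr <- movie@frames
  fr[rep(!mask, d[3])] <- 0
  new("ExcitationMovie", frames = fr, mask = mask, meta = movie@meta)
}

#' Random tissue-shaped mask
#'
#' Generates a smooth, connected blob covering 40-90% of the frame,
#' emulating the irregular heart silhouettes of experimental recordings; used
#' for mask augmentation during training. The blob is star-shaped about its
#' centre (radius varies smoothly with angle), hence always a single
#' 4-connected component. Seeded and reproducible.
#'
#' @param dims integer(2) height, width.
#' @param seed RNG seed.
#' @return logical H x W matrix.
#' @export
randomTissueMask <- function(dims, seed = 1L) {
  H <- dims[1]; W <- dims[2]
  withSeed(seed, {
    target <- stats::runif(1, 0.4, 0.9)
    cx <- (W - 1) / 2 + stats::runif(1, -0.08, 0.08) * W
    cy <- (H - 1) / 2 + stats::runif(1, -0.08, 0.08) * H
    nh <- 4L
    amp <- stats::runif(nh, 0, 0.25) / seq_len(nh)
    ph <- stats::runif(nh, 0, 2 * pi)
    cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
    rows <- matrix(0:(H - 1), H, W)
    theta <- atan2(rows - cy, cols - cx)
    rr <- sqrt((cols - cx)^2 + (rows - cy)^2)
    shape <- matrix(1, H, W)
    for (j in seq_len(nh))
      shape <- shape + amp[j] * cos((j + 1) * theta + ph[j])
    # binary search the base radius for the target coverage
    lo <- 1; hi <- max(H, W)
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      cov <- mean(rr <= mid * shape)
      if (cov < target) lo <- mid else hi <- mid
    }
    rr <= ((lo + hi) / 2) * shape
  })
}
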