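#' @include io.R
NULL

# ---- elementary layer math (arrays are H x W x C x B, column-major) --------

dims4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) d <- c(d, 1L)
  d
}

as4 <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# batch-norm forward over (H, W, B) per channel
bnForward <- function(x, gamma, beta, state, name, train, momentum = 0.1,
                      eps = 1e-5) {
  d <- dims4(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*B) x C
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    rmKey <- paste0(name, ".rm"); rvKey <- paste0(name, ".rv")
    state[[rmKey]] <- (1 - momentum) * (state[[rmKey]] %||% 0) + momentum * mu
    state[[rvKey]] <- (1 - momentum) * (state[[rvKey]] %||% 1) + momentum * va
  } else {
    mu <- state[[paste0(name, ".rm")]] %||% numeric(d[3])
    va <- state[[paste0(name, ".rv")]] %||% rep(1, d[3])
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- array(y, c(d[1], d[2], d[4], d[3]))
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       state = state)
}

bnBackward <- function(dy, gamma, cache) {
  d <- cache$d
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  n <- nrow(dym)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  mean1 <- colMeans(dxhat)
  mean2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2, mean1) - sweep(xhat, 2, mean2, "*"),
              2, cache$invstd, "*")
  dx <- aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over the channel dimension (2-channel case used by M1A)
softmaxC <- function(x) {
  d <- dims4(x)
  m <- pmax(x[, , 1, , drop = FALSE], x[, , 2, , drop = FALSE])
  e1 <- exp(x[, , 1, , drop = FALSE] - m)
  e2 <- exp(x[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  out <- x
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adamStep <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(grads)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- losses ----------------------------------------------------------------

#' Mean-squared-error phase loss
#'
#' Loss of the phase-predicting networks: mean of the squared differences of
#' the trigonometric channels over in-mask pixels (and both channels).
#'
#' @param pred,target arrays H x W x 2 (x B) of (cos, sin) channels.
#' @param mask optional logical H x W (x B) of valid pixels.
#' @return scalar loss.
#' @examples
#' p <- array(0, c(4, 4, 2)); t <- p; t[, , 1] <- 1
#' phaseLoss(p, t)  # 0.5
#' @export
phaseLoss <- function(pred, target, mask = NULL) {
  phaseLossGrad(pred, target, mask)$loss
}

phaseLossGrad <- function(pred, target, mask = NULL) {
  pred <- as4(pred); target <- as4(target)
  d <- dims4(pred)
  w <- array(1, d)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) == d[1] * d[2]) {
      w <- array(rep(mask, d[3] * d[4]), d)
    } else if (length(mask) == d[1] * d[2] * d[4]) {
      w <- aperm(array(rep(array(mask, c(d[1], d[2], d[4])), d[3]),
                       c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else stop("mask shape mismatch")
  }
  n <- sum(w)
  if (n == 0) stop("empty mask")
  diff <- (pred - target) * w
  list(loss = sum(diff^2) / n, grad = 2 * diff / n)
}

#' Categorical cross-entropy class-map loss
#'
#' Mean per-pixel cross-entropy between a predicted two-channel per-pixel
#' distribution and a one-hot class-map target.
#'
#' @param pred array H x W x 2 (x B) of per-pixel probabilities (channels sum
#'   to 1).
#' @param target one-hot array of the same shape.
#' @return scalar loss.
#' @examples
#' t <- array(c(1, 0), c(1, 1, 2))
#' classmapLoss(array(c(0.5, 0.5), c(1, 1, 2)), t)  # log(2)
#' @export
classmapLoss <- function(pred, target) {
  pred <- as4(pred); target <- as4(target)
  s <- pred[, , 1, , drop = FALSE] + pred[, , 2, , drop = FALSE]
  if (max(abs(s - 1)) > 1e-5) stop("pred channels must sum to 1 per pixel")
  eps <- 1e-12
  d <- dims4(pred)
  -sum(target * log(pred + eps)) / (d[1] * d[2] * d[4])
}

#' Weighted Hausdorff distance loss
#'
#' Differentiable point-localization loss between a per-pixel probability map
#' and a set of ground-truth points: the probability-weighted mean distance
#' from predicted mass to the nearest true point, plus for every true point a
#' generalized (power \code{alpha}) mean over pixels of
#' \eqn{p_i d(x_i, y) + (1 - p_i) d_{max}}. With \code{alpha = -3} the second
#' term approximates a soft minimum. Pixel coordinates are 0-based
#' (x = column, y = row); \eqn{d_{max}} is the image diagonal. For an empty
#' ground-truth set the point terms are skipped and the total predicted mass
#' is penalized (d_max * sum(p) / n_pixels).
#'
#' @param pred numeric H x W probability map in [0, 1].
#' @param gtPoints n x 2 matrix of (x, y) ground-truth coordinates (possibly
#'   0 rows).
#' @param alpha generalized-mean exponent (nonzero; default -3).
#' @return scalar loss.
#' @export
weightedHausdorffLoss <- function(pred, gtPoints, alpha = -3) {
  weightedHausdorffGrad(pred, gtPoints, alpha)$loss
}

weightedHausdorffGrad <- function(pred, gtPoints, alpha = -3) {
  if (alpha == 0) stop("alpha must be nonzero")
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
    stop("pred must lie in [0, 1]")
  H <- nrow(pred); W <- ncol(pred)
  N <- H * W
  dmax <- sqrt(H^2 + W^2)
  gtPoints <- as.matrix(gtPoints)
  p <- as.vector(pred)
  eps <- 1e-6
  if (nrow(gtPoints) == 0) {
    loss <- dmax * sum(p) / N
    g <- matrix(dmax / N, H, W)
    return(list(loss = loss, grad = g))
  }
  D <- sqrt(grid_point_dist2(H, W, gtPoints))  # N x n
  S <- sum(p) + eps
  mind <- apply(D, 1, min)
  term1 <- sum(p * mind) / S
  g1 <- (mind - term1) / S
  Z <- p * D + (1 - p) * dmax + eps   # N x n
  za <- Z^alpha
  Ma <- (colMeans(za))^(1 / alpha)    # per gt point
  term2 <- mean(Ma)
  # d term2 / d z_ij = (1/n) * Ma_j^(1-alpha) * z_ij^(alpha-1) / N
  n <- nrow(gtPoints)
  coef <- sweep(Z^(alpha - 1), 2, Ma^(1 - alpha), "*") / (N * n)
  g2 <- rowSums(coef * (D - dmax))
  list(loss = term1 + term2, grad = matrix(g1 + g2, H, W))
}
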