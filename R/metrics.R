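#' @include singularity.R
NULL

#' Minimum absolute circular difference
#'
#' @param a,b angle arrays (radians).
#' @return array of |delta phi| in [0, pi].
#' @export
circularDiff <- function(a, b) {
  d <- abs(wrapPhase(a - b))
  # wrapPhase maps to [-pi, pi); |.| of -pi is pi, the antipodal distance
  d
}

#' Angular accuracy of a phase prediction
#'
#' Computes 1 - <|delta phi|> / pi, where |delta phi| is the minimum absolute
#' circular difference per pixel, averaged over all in-mask, non-missing
#' pixels of all frames; the standard deviation is over the same pooled pixel
#' population.
#'
#' @param pred,gt phase arrays (same shape) or \linkS4class{PhaseMovie}s.
#' @param mask optional logical mask (per-pixel H x W, or full shape).
#' @return list(mean, sd, n) of the accuracy.
#' @examples
#' angularAccuracy(matrix(0, 4, 4), matrix(pi / 2, 4, 4))$mean  # 0.75
#' @export
angularAccuracy <- function(pred, gt, mask = NULL) {
  if (is(pred, "PhaseMovie")) pred <- pred@phases
  if (is(gt, "PhaseMovie")) gt <- gt@phases
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
  keep <- !(is.na(pred) | is.na(gt))
  if (!is.null(mask)) {
    if (length(mask) == length(pred)) keep <- keep & as.logical(mask)
    else {
      d <- dim(pred)
      keep <- keep & rep(as.logical(mask), if (length(d) == 3L) d[3] else 1L)
    }
  }
  if (!any(keep)) stop("empty mask: no pixels to compare")
  err <- circularDiff(pred[keep], gt[keep])
  acc <- 1 - err / pi
  list(mean = mean(acc), sd = stats::sd(acc), n = length(acc))
}

framePoints <- function(ps, t) {
  p <- ps@points[ps@points$t == t, c("x", "y"), drop = FALSE]
  as.matrix(p)
}

matchCounts <- function(predM, gtM, rMatch) {
  np <- nrow(predM); ng <- nrow(gtM)
  if (np == 0 && ng == 0) return(c(tp = 0, fp = 0, fn = 0))
  if (np == 0) return(c(tp = 0, fp = 0, fn = ng))
  if (ng == 0) return(c(tp = 0, fp = np, fn = 0))
  d2 <- outer(predM[, 1], gtM[, 1], "-")^2 + outer(predM[, 2], gtM[, 2], "-")^2
  near <- d2 <= rMatch^2
  # counting rule: a prediction within r of any ground truth is a true
  # positive (counted per prediction); a ground truth with no prediction
  # within r is a false negative (counted per ground truth)
  tp <- sum(rowSums(near) > 0)
  fp <- np - tp
  fn <- sum(colSums(near) == 0)
  c(tp = tp, fp = fp, fn = fn)
}

#' Match predicted and ground-truth phase singularities
#'
#' Frame-by-frame counting with matching radius \code{rMatch}: every
#' prediction within \code{rMatch} pixels of any ground-truth PS is a true
#' positive, other predictions are false positives, and every ground-truth PS
#' with no prediction within \code{rMatch} is a false negative. Note that two
#' predictions near one ground-truth PS both count as true positives, so
#' tp + fn may exceed the ground-truth count in that (rare) case.
#'
#' @param pred,gt \linkS4class{PhaseSingularitySet}s over the same frames.
#' @param rMatch matching radius in pixels (3 for simulated data, 6 for
#'   experimental-resolution data).
#' @return list(tp, fp, fn, rMatch, perFrame data.frame).
#' @export
matchPS <- function(pred, gt, rMatch = 3) {
  nT <- max(gt@nFrames, pred@nFrames)
  per <- t(vapply(seq_len(nT), function(t) {
    matchCounts(framePoints(pred, t), framePoints(gt, t), rMatch)
  }, c(tp = 0, fp = 0, fn = 0)))
  tot <- colSums(per)
  list(tp = unname(tot["tp"]), fp = unname(tot["fp"]), fn = unname(tot["fn"]),
       rMatch = rMatch,
       perFrame = data.frame(t = seq_len(nT), tp = per[, "tp"],
                             fp = per[, "fp"], fn = per[, "fn"]))
}

#' Precision, recall and F-score of a PS match
#'
#' @param match result of \code{\link{matchPS}} (or any list with tp, fp, fn).
#' @return list(precision, recall, f); entries are NA when undefined
#'   (no predictions / no ground truth), and 0 when tp = 0 with nonzero
#'   fp and fn.
#' @export
fScore <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (tp + fp + fn == 0) NA_real_ else 0
  list(precision = precision, recall = recall, f = f)
}

#' Mean absolute error of per-frame PS counts
#'
#' @param gtCounts,predCounts equal-length numeric vectors of per-frame PS
#'   counts.
#' @return mean |predicted - true|.
#' @export
countMAE <- function(gtCounts, predCounts) {
  if (length(gtCounts) != length(predCounts)) stop("length mismatch")
  mean(abs(predCounts - gtCounts))
}

#' Average Hausdorff distance between two point sets
#'
#' d_AHD(X, Y) = (mean_x min_y d(x,y) + mean_y min_x d(x,y)) / 2.
#' If exactly one set is empty the distance is the image diagonal; if both
#' are empty it is 0 (a perfect empty prediction is not penalized).
#'
#' @param X,Y numeric matrices n x 2 (columns x, y), possibly 0-row.
#' @param imageDiagonal diagonal length sqrt(W^2 + H^2) used for the
#'   one-empty-set convention.
#' @return nonnegative scalar.
#' @export
ahd <- function(X, Y, imageDiagonal) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nx <- nrow(X); ny <- nrow(Y)
  if (nx == 0 && ny == 0) return(0)
  if (nx == 0 || ny == 0) return(imageDiagonal)
  d <- sqrt(outer(X[, 1], Y[, 1], "-")^2 + outer(X[, 2], Y[, 2], "-")^2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Mean average Hausdorff distance over frames
#'
#' @param gt,pred \linkS4class{PhaseSingularitySet}s, or equal-length lists
#'   of n x 2 point matrices.
#' @param dims integer(2) image height and width (for the diagonal); taken
#'   from the PS sets when omitted.
#' @return mean of the per-frame \code{\link{ahd}} values.
#' @export
mahd <- function(gt, pred, dims = NULL) {
  if (is(gt, "PhaseSingularitySet")) {
    if (is.null(dims)) dims <- gt@dims
    nT <- max(gt@nFrames, pred@nFrames)
    gtl <- lapply(seq_len(nT), function(t) framePoints(gt, t))
    prl <- lapply(seq_len(nT), function(t) framePoints(pred, t))
  } else {
    gtl <- gt; prl <- pred
    if (length(gtl) != length(prl)) stop("length mismatch")
    if (is.null(dims)) stop("dims required for list input")
  }
  diag <- sqrt(sum(as.numeric(dims)^2))
  mean(vapply(seq_along(gtl), function(i) ahd(gtl[[i]], prl[[i]], diag),
              numeric(1)))
}

#' Full PS evaluation report
#'
#' Convenience wrapper computing the matched precision/recall/F-score, the
#' per-frame count MAE and the mean average Hausdorff distance between two PS
#' sets.
#'
#' @param pred,gt \linkS4class{PhaseSingularitySet}s.
#' @param rMatch matching radius in pixels.
#' @return list(precision, recall, f, mae, mahd, tp, fp, fn, nFrames).
#' @export
evaluatePS <- function(pred, gt, rMatch = 3) {
  m <- matchPS(pred, gt, rMatch)
  fs <- fScore(m)
  nT <- max(gt@nFrames, pred@nFrames)
  gtc <- tabulate(gt@points$t, nT)
  prc <- tabulate(pred@points$t, nT)
  list(precision = fs$precision, recall = fs$recall, f = fs$f,
       mae = countMAE(gtc, prc), mahd = mahd(gt, pred),
       tp = m$tp, fp = m$fp, fn = m$fn, nFrames = nT)
}
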