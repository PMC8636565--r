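# Trajectory preparation: convert raw nuclear-NFkB time courses into the
# scaled, 1-second-interpolated model input.
#
# Replicate 1: control and siIkBa fold changes are rescaled TOGETHER to
# span 2-100 (one affine map from the pooled range).  Replicate 2: the
# affine map is anchored on the control series alone and applied to both
# conditions, because replicate 2's maximum activity appears at late
# siIkBa time points rather than at the control first peak; the anchored
# siIkBa series may therefore exceed 100.

#' Subtract a basal (assay background) signal
#'
#' @param tc an \linkS4class{NfkbTimeCourse}.
#' @param basal background constant, strictly below the series minimum.
#' @return the time course with \code{basal} subtracted from every value.
#' @export
subtractBasal <- function(tc, basal) {
  stopifnot(is(tc, "NfkbTimeCourse"))
  if (basal >= min(tc@values))
    stop("basal must be strictly below the series minimum")
  tc@values <- tc@values - basal
  validObject(tc)
  tc
}

#' Fold change of a time course relative to t = 0
#'
#' @param tc an \linkS4class{NfkbTimeCourse} with a strictly positive
#'   value at t = 0.
#' @return the time course divided by its t = 0 value.
#' @export
foldChange <- function(tc) {
  stopifnot(is(tc, "NfkbTimeCourse"))
  v0 <- tc@values[tc@times == 0]
  if (length(v0) != 1 || v0 <= 0) stop("value at t = 0 must be positive")
  tc@values <- tc@values / v0
  tc
}

affineRescale <- function(x, from, lo, hi) {
  if (diff(from) <= 0) stop("cannot rescale a constant series (zero range)")
  if (hi <= lo) stop("hi must exceed lo")
  lo + (hi - lo) * (x - from[1]) / (from[2] - from[1])
}

#' Jointly rescale control and siIkBa fold changes to span lo-hi
#'
#' One affine map is computed from the pooled minimum and maximum of both
#' series and applied to both, so the pooled output spans exactly
#' \code{[lo, hi]}.  This is the replicate-1 rule.
#'
#' @param ctrl,si \linkS4class{NfkbTimeCourse} fold changes.
#' @param lo,hi target range (default 2-100).
#' @return list with rescaled \code{ctrl} and \code{si}.
#' @export
rescaleJoint <- function(ctrl, si, lo = 2, hi = 100) {
  stopifnot(is(ctrl, "NfkbTimeCourse"), is(si, "NfkbTimeCourse"))
  pooled <- range(c(ctrl@values, si@values))
  ctrl@values <- affineRescale(ctrl@values, pooled, lo, hi)
  si@values <- affineRescale(si@values, pooled, lo, hi)
  list(ctrl = ctrl, si = si)
}

#' Rescale with the affine map anchored on the control series
#'
#' The map sending the CONTROL min/max to \code{[lo, hi]} is applied to
#' both conditions; the siIkBa output may exceed \code{hi}.  This is the
#' replicate-2 rule (its maximum activity appears late in siIkBa, so the
#' control first peak is pinned to \code{hi} instead).
#'
#' @inheritParams rescaleJoint
#' @return list with rescaled \code{ctrl} and \code{si}.
#' @export
rescaleAnchored <- function(ctrl, si, lo = 2, hi = 100) {
  stopifnot(is(ctrl, "NfkbTimeCourse"), is(si, "NfkbTimeCourse"))
  anchor <- range(ctrl@values)
  ctrl@values <- affineRescale(ctrl@values, anchor, lo, hi)
  si@values <- affineRescale(si@values, anchor, lo, hi)
  list(ctrl = ctrl, si = si)
}

#' Interpolate a time course to a 1-second input grid
#'
#' Monotone cubic Hermite (pchip) interpolation of the scaled fold change
#' at 1-second resolution over [0, tEndS]; knot values are reproduced
#' exactly and the interpolant does not overshoot adjacent knots.  For
#' t < 0 the grid holds the t = 0 value (pre-stimulus steady state), so
#' delayed lookups never fall off-grid.
#'
#' @param tc an \linkS4class{NfkbTimeCourse} covering at least 0-180 min.
#' @param tStartS grid start in seconds (default -14400 = -(180 + 60) min,
#'   enough for the -60 min window plus the maximal 7200 s delay).
#' @param tEndS grid end in seconds (default 10800 = 180 min).
#' @return an \linkS4class{NfkbInputGrid}.
#' @export
interpolateSeconds <- function(tc, tStartS = -14400, tEndS = 10800) {
  stopifnot(is(tc, "NfkbTimeCourse"))
  if (tStartS > -3600 - 7200)
    stop("tStartS must be <= -10800 so delayed lookups never fall off-grid")
  if (tEndS < 10800) stop("tEndS must be >= 10800 (180 min)")
  xs <- minToSec(tc@times)
  if (min(xs) > 0 || max(xs) < tEndS)
    stop("time course must cover the full [0, tEndS] window")
  tPos <- seq(0, tEndS)
  vPos <- pracma::pchip(xs, tc@values, tPos)
  values <- c(rep(vPos[1], -tStartS), vPos)
  nfkbInputGrid(values, tStartS = tStartS, tEndS = tEndS,
                scaleLo = min(tc@values), scaleHi = max(tc@values))
}

#' Full input preparation for one biological replicate
#'
#' Basal subtraction, fold change, replicate-specific 2-100 rescaling
#' (joint for replicate 1, control-anchored for replicate 2) and 1-second
#' pchip interpolation, for the control and siIkBa series of one
#' replicate.
#'
#' @param ctrl,si raw \linkS4class{NfkbTimeCourse} objects of one
#'   replicate.
#' @param replicate 1 (joint rescaling) or 2 (anchored rescaling);
#'   defaults to the replicate tag of \code{ctrl}.
#' @param basal assay background constant (default 0).
#' @param lo,hi scaling range (default 2-100).
#' @param tStartS,tEndS grid window in seconds.
#' @return list with \code{ctrl} and \code{si} \linkS4class{NfkbInputGrid}s.
#' @export
prepareInputs <- function(ctrl, si, replicate = ctrl@replicate, basal = 0,
                          lo = 2, hi = 100, tStartS = -14400, tEndS = 10800) {
  if (basal != 0) {
    ctrl <- subtractBasal(ctrl, basal)
    si <- subtractBasal(si, basal)
  }
  fc <- list(ctrl = foldChange(ctrl), si = foldChange(si))
  scaled <- if (replicate == 1)
    rescaleJoint(fc$ctrl, fc$si, lo, hi)
  else
    rescaleAnchored(fc$ctrl, fc$si, lo, hi)
  list(ctrl = interpolateSeconds(scaled$ctrl, tStartS, tEndS),
       si = interpolateSeconds(scaled$si, tStartS, tEndS))
}
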