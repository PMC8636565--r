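#' Sampled nuclear-NFkB (or expression) time course
#'
#' An ordered series of (time, value) pairs tagged with the experimental
#' condition and the biological replicate.  Times are minutes with the
#' first sample at stimulation (t = 0); values are non-negative signal
#' units (raw immunofluorescence intensity, fold change, or the rescaled
#' model input, depending on the processing stage).
#'
#' @slot times numeric, strictly ascending sampling times in minutes,
#'   starting at 0.
#' @slot values numeric, non-negative signal values, same length as
#'   \code{times}.
#' @slot condition either \code{"ctrl"} or \code{"siIkBa"}.
#' @slot replicate integer, biological replicate (1 or 2).
#' @exportClass NfkbTimeCourse
setClass("NfkbTimeCourse",
  slots = c(
    times = "numeric",
    values = "numeric",
    condition = "character",
    replicate = "integer"
  )
)

setValidity("NfkbTimeCourse", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 2)
    msg <- c(msg, "at least two time points are required")
  if (length(object@times) >= 2 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly ascending")
  if (length(object@times) >= 1 && object@times[1] != 0)
    msg <- c(msg, "times must start at 0")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(object@condition) != 1 ||
      !object@condition %in% c("ctrl", "siIkBa"))
    msg <- c(msg, "condition must be 'ctrl' or 'siIkBa'")
  if (length(object@replicate) != 1 || !object@replicate %in% c(1L, 2L))
    msg <- c(msg, "replicate must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an NfkbTimeCourse
#'
#' @param times sampling times in minutes, strictly ascending, starting at 0.
#' @param values non-negative signal values.
#' @param condition \code{"ctrl"} or \code{"siIkBa"}.
#' @param replicate biological replicate, 1 or 2.
#' @return an \linkS4class{NfkbTimeCourse}.
#' @examples
#' nfkbTimeCourse(c(0, 15, 30), c(1, 4, 8), "ctrl", 1)
#' @export
nfkbTimeCourse <- function(times, values, condition = "ctrl", replicate = 1L) {
  new("NfkbTimeCourse", times = as.numeric(times), values = as.numeric(values),
      condition = condition, replicate = as.integer(replicate))
}

#' Model input: NFkB fold change on a 1-second grid
#'
#' The scaled fold-change trajectory interpolated to 1-second resolution,
#' covering a pre-stimulus window so that delayed lookups
#' \eqn{NFkB(t - \tau)} never fall off-grid.  For \eqn{t < 0} the grid
#' holds the \eqn{t = 0} value (pre-stimulus steady state).
#'
#' @slot tStartS first grid time in seconds (at most -3600 - tau_max).
#' @slot tEndS last grid time in seconds (at least 10800).
#' @slot values fold-change values on the 1-second grid,
#'   \code{tEndS - tStartS + 1} of them.
#' @slot scaleLo,scaleHi the fold-units range the scaled data were mapped
#'   to (2 and 100 for the standard preparation).
#' @exportClass NfkbInputGrid
setClass("NfkbInputGrid",
  slots = c(
    tStartS = "numeric",
    tEndS = "numeric",
    values = "numeric",
    scaleLo = "numeric",
    scaleHi = "numeric"
  )
)

setValidity("NfkbInputGrid", function(object) {
  msg <- character()
  n <- object@tEndS - object@tStartS + 1
  if (length(object@values) != n)
    msg <- c(msg, "values must have tEndS - tStartS + 1 entries (1-s grid)")
  if (object@tStartS > -3600)
    msg <- c(msg, "tStartS must be <= -3600 (pre-stimulus window)")
  if (object@tEndS < 10800)
    msg <- c(msg, "tEndS must be >= 10800 (simulation window)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  i0 <- -object@tStartS + 1
  if (length(object@values) >= i0 && i0 >= 1 &&
      any(object@values[seq_len(i0 - 1)] != object@values[i0]))
    msg <- c(msg, "values for t < 0 must equal the value at t = 0")
  if (length(msg)) msg else TRUE
})

#' Construct an NfkbInputGrid
#'
#' @param values fold-change values on the 1-second grid.
#' @param tStartS,tEndS grid window in seconds.
#' @param scaleLo,scaleHi the fold-units scaling range recorded with the grid.
#' @return an \linkS4class{NfkbInputGrid}.
#' @export
nfkbInputGrid <- function(values, tStartS = -14400, tEndS = 10800,
                          scaleLo = min(values), scaleHi = max(values)) {
  new("NfkbInputGrid", tStartS = tStartS, tEndS = tEndS,
      values = as.numeric(values), scaleLo = scaleLo, scaleHi = scaleHi)
}

#' Per-model parameter set
#'
#' Houses the free parameters of one transcription model together with its
#' fixed constants and the bound constraints used during optimization.
#'
#' @slot modelName one of \code{"simple"}, \code{"iffl"}, \code{"cycle3"},
#'   \code{"v4"}.
#' @slot free named numeric vector of free parameter values.
#' @slot fixed named numeric vector of fixed constants.
#' @slot bounds 2 x p matrix with rows \code{lo}, \code{hi}.
#' @exportClass GrmParamSet
setClass("GrmParamSet",
  slots = c(
    modelName = "character",
    free = "numeric",
    fixed = "numeric",
    bounds = "matrix"
  )
)

setValidity("GrmParamSet", function(object) {
  msg <- character()
  if (!object@modelName %in% grmModelNames())
    return(sprintf("unknown model '%s'", object@modelName))
  def <- grmModelDef(object@modelName)
  if (!identical(sort(names(object@free)), sort(def$free)))
    msg <- c(msg, sprintf("free parameters must be exactly {%s}",
                          paste(def$free, collapse = ", ")))
  else {
    b <- object@bounds
    if (!identical(rownames(b), c("lo", "hi")) ||
        !all(def$free %in% colnames(b)))
      msg <- c(msg, "bounds must be a 2 x p matrix with rows lo, hi")
    else {
      v <- object@free[colnames(b)]
      bad <- v <= b["lo", ] | v >= b["hi", ]
      if (any(bad))
        msg <- c(msg, sprintf("parameter(s) outside bounds: %s",
                              paste(colnames(b)[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a forward simulation of one transcription model
#'
#' @slot modelName the simulated model.
#' @slot evalTimes evaluation times in minutes.
#' @slot mrna mRNA abundance (arbitrary concentration units) at
#'   \code{evalTimes}.
#' @slot tf competitor-TF abundance (iffl / v4 only; length 0 otherwise).
#' @slot states matrix with columns \code{C}, \code{O}, \code{A}: closed /
#'   open / active promoter-state fractions (cycle3 / v4 only; 0 rows
#'   otherwise).
#' @slot foldChange mRNA fold change relative to t = 0 (filled by
#'   \code{\link{simFoldChange}}; length 0 before that).
#' @slot mfi,auc max-fold induction and area under the fold-change curve
#'   over 0-180 min (NA before \code{simFoldChange}).
#' @exportClass GrmSimResult
setClass("GrmSimResult",
  slots = c(
    modelName = "character",
    evalTimes = "numeric",
    mrna = "numeric",
    tf = "numeric",
    states = "matrix",
    foldChange = "numeric",
    mfi = "numeric",
    auc = "numeric"
  )
)

setValidity("GrmSimResult", function(object) {
  msg <- character()
  if (length(object@mrna) != length(object@evalTimes))
    msg <- c(msg, "mrna must match evalTimes in length")
  if (any(object@mrna < -1e-9))
    msg <- c(msg, "mRNA must be non-negative (within solver tolerance)")
  if (nrow(object@states) > 0) {
    if (any(object@states < -1e-9) || any(object@states > 1 + 1e-9))
      msg <- c(msg, "promoter-state fractions must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "NfkbTimeCourse", function(object) {
  cat(sprintf("NfkbTimeCourse: %s, replicate %d, %d points over %g-%g min\n",
              object@condition, object@replicate, length(object@times),
              min(object@times), max(object@times)))
  cat(sprintf("  values: %s\n",
              paste(signif(head(object@values, 6), 4), collapse = ", ")))
})

setMethod("show", "NfkbInputGrid", function(object) {
  cat(sprintf(
    "NfkbInputGrid: 1-s grid over [%g, %g] s, range [%.4g, %.4g] (scale %g-%g)\n",
    object@tStartS, object@tEndS, min(object@values), max(object@values),
    object@scaleLo, object@scaleHi))
})

setMethod("show", "GrmParamSet", function(object) {
  cat(sprintf("GrmParamSet for model '%s'\n", object@modelName))
  cat("  free: ", paste(sprintf("%s=%.4g", names(object@free), object@free),
                        collapse = ", "), "\n")
  cat("  fixed:", paste(sprintf("%s=%.4g", names(object@fixed), object@fixed),
                        collapse = ", "), "\n")
})

setMethod("show", "GrmSimResult", function(object) {
  cat(sprintf("GrmSimResult (%s): %d evaluation times over %g-%g min\n",
              object@modelName, length(object@evalTimes),
              min(object@evalTimes), max(object@evalTimes)))
  if (length(object@foldChange))
    cat(sprintf("  MFI %.3g, AUC %.4g fold*min\n", object@mfi, object@auc))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' @describeIn nfkbTimeCourse sampling times (minutes).
#' @param x an object.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @describeIn nfkbTimeCourse signal values.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @export
setMethod("timePoints", "NfkbTimeCourse", function(x) x@times)
#' @export
setMethod("signalValues", "NfkbTimeCourse", function(x) x@values)

#' Model name of a parameter set or simulation result
#' @param x a \linkS4class{GrmParamSet} or \linkS4class{GrmSimResult}.
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @export
setMethod("modelName", "GrmParamSet", function(x) x@modelName)
#' @export
setMethod("modelName", "GrmSimResult", function(x) x@modelName)

#' Free parameters of a parameter set
#' @param x a \linkS4class{GrmParamSet}.
#' @export
setGeneric("freeParams", function(x) standardGeneric("freeParams"))
#' @export
setMethod("freeParams", "GrmParamSet", function(x) x@free)

#' Fixed constants of a parameter set
#' @param x a \linkS4class{GrmParamSet}.
#' @export
setGeneric("fixedParams", function(x) standardGeneric("fixedParams"))
#' @export
setMethod("fixedParams", "GrmParamSet", function(x) x@fixed)

#' Bound constraints of a parameter set
#' @param x a \linkS4class{GrmParamSet}.
#' @export
setGeneric("paramBounds", function(x) standardGeneric("paramBounds"))
#' @export
setMethod("paramBounds", "GrmParamSet", function(x) x@bounds)

#' Evaluation times (minutes) of a simulation result
#' @param x a \linkS4class{GrmSimResult}.
#' @export
setGeneric("evalTimes", function(x) standardGeneric("evalTimes"))
#' @export
setMethod("evalTimes", "GrmSimResult", function(x) x@evalTimes)

#' mRNA abundance of a simulation result
#' @param x a \linkS4class{GrmSimResult}.
#' @export
setGeneric("mrnaValues", function(x) standardGeneric("mrnaValues"))
#' @export
setMethod("mrnaValues", "GrmSimResult", function(x) x@mrna)

#' Promoter-state fractions (C, O, A) of a simulation result
#' @param x a \linkS4class{GrmSimResult}.
#' @export
setGeneric("promoterStates", function(x) standardGeneric("promoterStates"))
#' @export
setMethod("promoterStates", "GrmSimResult", function(x) x@states)

#' Competitor-TF abundance of a simulation result
#' @param x a \linkS4class{GrmSimResult}.
#' @export
setGeneric("tfValues", function(x) standardGeneric("tfValues"))
#' @export
setMethod("tfValues", "GrmSimResult", function(x) x@tf)

#' Fold-change values of a simulation result
#' @param x a \linkS4class{GrmSimResult}.
#' @export
setGeneric("foldChangeValues", function(x) standardGeneric("foldChangeValues"))
#' @export
setMethod("foldChangeValues", "GrmSimResult", function(x) x@foldChange)

#' Values of an input grid
#' @param x an \linkS4class{NfkbInputGrid}.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @export
setMethod("gridValues", "NfkbInputGrid", function(x) x@values)

#' Grid times in seconds
#' @param x an \linkS4class{NfkbInputGrid}.
#' @export
setGeneric("gridTimes", function(x) standardGeneric("gridTimes"))
#' @export
setMethod("gridTimes", "NfkbInputGrid", function(x) seq(x@tStartS, x@tEndS))
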