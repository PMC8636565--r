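# Model registry: free parameters, fixed constants, global bound constraints.
#
# Units: rate constants are s^-1, delays tau are seconds, the regulation
# strength constants K_D multiply the (dimensionless) scaled NFkB fold
# change inside Hill terms (K x)^h / ((K x)^h + 1).
#
# Fixed constants: the competitor (p50) branch uses k_degTF = 8.022537e-6
# s^-1 (a ~24 h mRNA half-life), K_DTF = 100 and tau_TF = 7200 s (the 2 h
# p50 processing delay); the promoter cycle fixes the backward rates at
# 1% of the forward rates, k_-3 = 1 and K_D3 = 0.5.  k_syn is fixed at 1
# throughout (only fold changes are fitted).

.grmRegistry <- local({
  kdeg <- c(2e-5, 2e-3)
  kd <- c(0.001, 1000)
  tau <- c(0, 7200)
  k1 <- c(6e-5, 6e-3)
  mk <- function(lo, hi) c(lo = lo, hi = hi)
  boundsMat <- function(...) {
    b <- cbind(...)
    rownames(b) <- c("lo", "hi")
    b
  }
  list(
    simple = list(
      id = 1L,
      free = c("k_deg", "K_D", "tau"),
      logScale = c(k_deg = TRUE, K_D = TRUE, tau = FALSE),
      bounds = boundsMat(k_deg = kdeg, K_D = kd, tau = tau),
      fixed = c(h = 1, k_syn = 1)
    ),
    iffl = list(
      id = 2L,
      free = c("k_deg", "K_D1", "K_D2", "tau"),
      logScale = c(k_deg = TRUE, K_D1 = TRUE, K_D2 = TRUE, tau = FALSE),
      bounds = boundsMat(k_deg = kdeg, K_D1 = kd, K_D2 = kd, tau = tau),
      fixed = c(h = 2, h_TF = 1, k_degTF = 8.022537e-6, K_DTF = 100,
                tau_TF = 7200, k_syn = 1)
    ),
    cycle3 = list(
      id = 3L,
      free = c("k_1", "k_2", "k_deg", "K_D1", "K_D2", "tau"),
      logScale = c(k_1 = TRUE, k_2 = TRUE, k_deg = TRUE, K_D1 = TRUE,
                   K_D2 = TRUE, tau = FALSE),
      bounds = boundsMat(k_1 = k1, k_2 = c(0.007, 69.31), k_deg = kdeg,
                         K_D1 = kd, K_D2 = kd, tau = tau),
      fixed = c(k_m3 = 1, K_D3 = 0.5, k_syn = 1)
    ),
    v4 = list(
      id = 4L,
      free = c("k_deg", "k_1", "k_2", "K_D1", "K_D2", "K_DTF2", "tau"),
      logScale = c(k_deg = TRUE, k_1 = TRUE, k_2 = TRUE, K_D1 = TRUE,
                   K_D2 = TRUE, K_DTF2 = TRUE, tau = FALSE),
      bounds = boundsMat(k_deg = kdeg, k_1 = k1, k_2 = c(0.007, 69.315),
                         K_D1 = kd, K_D2 = kd, K_DTF2 = kd, tau = tau),
      fixed = c(h = 2, h_TF = 1, k_degTF = 8.022537e-6, K_DTF = 100,
                tau_TF = 7200, k_m3 = 1, K_D3 = 0.5, k_syn = 1)
    )
  )
})

#' Names of the available transcription models
#' @return character vector \code{c("simple", "iffl", "cycle3", "v4")}.
#' @export
grmModelNames <- function() names(.grmRegistry)

#' Model definition: free parameters, fixed constants, global bounds
#'
#' @param model model name.
#' @return a list with elements \code{id}, \code{free}, \code{logScale},
#'   \code{bounds} (2 x p matrix, rows \code{lo}/\code{hi}) and
#'   \code{fixed}.
#' @export
grmModelDef <- function(model) {
  if (!model %in% names(.grmRegistry))
    stop(sprintf("unknown model '%s'", model))
  .grmRegistry[[model]]
}

#' Construct a parameter set for one transcription model
#'
#' @param model model name (\code{grmModelNames()}).
#' @param free named numeric vector of free parameter values; must lie
#'   strictly inside the model's global bounds.
#' @param bounds optional 2 x p bounds matrix (defaults to the model's
#'   global bounds).
#' @return a \linkS4class{GrmParamSet}.
#' @examples
#' grmParamSet("simple", c(k_deg = 5e-4, K_D = 0.1, tau = 600))
#' @export
grmParamSet <- function(model, free, bounds = NULL) {
  def <- grmModelDef(model)
  free <- unlist(free)
  if (is.null(bounds)) bounds <- def$bounds
  new("GrmParamSet", modelName = model, free = free[def$free],
      fixed = def$fixed, bounds = bounds)
}

# pack free + fixed parameters into the C++ layout
packParams <- function(params) {
  f <- params@free
  x <- params@fixed
  switch(params@modelName,
    simple = c(x["k_syn"], f["k_deg"], f["K_D"], x["h"], f["tau"]),
    iffl = c(x["k_syn"], f["k_deg"], f["K_D1"], f["K_D2"], x["h"], f["tau"],
             x["k_degTF"], x["K_DTF"], x["h_TF"], x["tau_TF"]),
    cycle3 = c(x["k_syn"], f["k_deg"], f["k_1"], f["k_2"],
               0.01 * f["k_1"], 0.01 * f["k_2"], x["k_m3"],
               f["K_D1"], f["K_D2"], x["K_D3"], f["tau"]),
    v4 = c(x["k_syn"], f["k_deg"], f["k_1"], f["k_2"],
           0.01 * f["k_1"], 0.01 * f["k_2"], x["k_m3"],
           f["K_D1"], f["K_D2"], x["K_D3"], f["K_DTF2"], x["h"], f["tau"],
           x["k_degTF"], x["K_DTF"], x["h_TF"], x["tau_TF"]),
    stop("unknown model"))
}

# default integration step: the simple/IFFL systems are non-stiff (rates
# <= 2e-3 s^-1) and use RK4 at 12 s (half-steps land on integer grid
# seconds); the promoter-cycle systems are integrated implicitly at 24 s.
# Both agree with a dense-output reference solver to <1e-4 relative on
# the standard input.
defaultDt <- function(model) if (model %in% c("simple", "iffl")) 12 else 24

#' Hill activation function
#'
#' \eqn{(K x)^h / ((K x)^h + 1)}: the fraction of time the promoter (or
#' the competitor-TF gene) is activated at regulator abundance \code{x}
#' with regulation strength \code{K} and Hill exponent \code{h}.
#'
#' @param x regulator abundance (non-negative).
#' @param K regulation strength constant (positive).
#' @param h Hill exponent (positive).
#' @return activation in [0, 1); vectorized over \code{x}.
#' @examples
#' hillActivation(3, K = 1, h = 2)  # 9/10
#' @export
hillActivation <- function(x, K, h) {
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0")
  if (K <= 0 || h <= 0) stop("K and h must be positive")
  z <- (K * x)^h
  z / (z + 1)
}

#' Delayed input lookup on an input grid
#'
#' Returns the grid value at \code{tS - tauS}, with \code{t - tau} rounded
#' to the nearest grid second.  Lookups before t = 0 return the t = 0
#' value (the pre-stimulus hold rule); lookups before the grid start are
#' an error.
#'
#' @param grid an \linkS4class{NfkbInputGrid}.
#' @param tS time in seconds.
#' @param tauS delay in seconds (non-negative).
#' @return fold-change value(s); vectorized over \code{tS}.
#' @export
delayedValue <- function(grid, tS, tauS) {
  t <- round(tS - tauS)
  if (any(t < grid@tStartS))
    stop("delayed lookup before the grid start")
  idx <- pmin(t, grid@tEndS) - grid@tStartS + 1
  grid@values[idx]
}

#' Steady state of a transcription model under constant input
#'
#' Solves the model's equilibrium under a constant NFkB input \code{n0}:
#' closed forms for the mRNA and competitor-TF levels, and a bracketed
#' root solve on the active-state fraction for the promoter-cycle models.
#'
#' @param params a \linkS4class{GrmParamSet}.
#' @param n0 constant input in fold units (> 0); by convention the scaled
#'   grid value at t = 0.
#' @return a named list with \code{mrna}, and where applicable \code{tf}
#'   and \code{states} (named C, O, A).
#' @examples
#' ps <- grmParamSet("simple", c(k_deg = 1e-3, K_D = 0.5, tau = 0))
#' steadyState(ps, n0 = 2)$mrna  # 0.5 / 1e-3 = 500
#' @export
steadyState <- function(params, n0) {
  stopifnot(is(params, "GrmParamSet"))
  if (!is.finite(n0) || n0 <= 0) stop("n0 must be positive")
  def <- grmModelDef(params@modelName)
  y <- .cppSteadyState(def$id, packParams(params), n0)
  switch(params@modelName,
    simple = list(mrna = y[1]),
    iffl = list(tf = y[1], mrna = y[2]),
    cycle3 = list(states = c(C = y[1], O = y[2], A = y[3]), mrna = y[4]),
    v4 = list(states = c(C = y[1], O = y[2], A = y[3]), tf = y[4],
              mrna = y[5]))
}

#' Forward-simulate a transcription model driven by an NFkB input grid
#'
#' Integrates the model's delay ODEs from the steady-state window start
#' (-60 min by default) with the initial condition at the steady state
#' under the pre-stimulus input, and returns the state at the requested
#' evaluation times.  Delayed input terms are grid lookups; delayed state
#' terms (A(t - tau), TF(t - tau_TF)) use the integration's own stored
#' history.
#'
#' @param params a \linkS4class{GrmParamSet}.
#' @param grid an \linkS4class{NfkbInputGrid} covering the simulation
#'   window (including delayed lookups).
#' @param evalTimes evaluation times in minutes (default the 13 sampling
#'   points 0, 15, ..., 180).
#' @param tStartS start of the steady-state window in seconds (default
#'   -3600, i.e. -60 min).
#' @param dt integration step in seconds (default 2 s for simple/iffl,
#'   5 s for the promoter-cycle models).
#' @param n0 pre-stimulus input level; defaults to the grid value at t = 0.
#' @return a \linkS4class{GrmSimResult} (fold change not yet filled; see
#'   \code{\link{simFoldChange}}).
#' @export
simulateGrm <- function(params, grid, evalTimes = seq(0, 180, by = 15),
                        tStartS = -3600, dt = NULL, n0 = NA_real_) {
  stopifnot(is(params, "GrmParamSet"), is(grid, "NfkbInputGrid"))
  model <- params@modelName
  def <- grmModelDef(model)
  if (is.null(dt)) dt <- defaultDt(model)
  tEndS <- max(minToSec(max(evalTimes)), 10800)
  if (abs(tStartS) %% dt != 0 || tEndS %% dt != 0)
    stop("tStartS and the simulation end must be multiples of dt")
  if (grid@tEndS < tEndS)
    stop("grid does not cover the simulation window")
  res <- .cppSimulate(def$id, packParams(params), grid@values, grid@tStartS,
                      tStartS, tEndS, dt, minToSec(evalTimes), n0)
  if (!res$ok) stop("simulation failed (non-finite state or solver failure)")
  states <- matrix(numeric(0), nrow = 0, ncol = 3,
                   dimnames = list(NULL, c("C", "O", "A")))
  if (model %in% c("cycle3", "v4"))
    states <- cbind(C = res$C, O = res$O, A = res$A)
  new("GrmSimResult", modelName = model, evalTimes = as.numeric(evalTimes),
      mrna = res$mrna, tf = if (is.null(res$tf)) numeric(0) else res$tf,
      states = states, foldChange = numeric(0),
      mfi = NA_real_, auc = NA_real_)
}

#' Fill the fold change (and MFI / AUC) of a simulation result
#'
#' Fold change is mRNA(t) / mRNA(0); the max-fold induction (MFI) is its
#' maximum over 0-180 min and the AUC its trapezoidal integral over the
#' same window.
#'
#' @param res a \linkS4class{GrmSimResult} whose \code{evalTimes} include 0.
#' @return the result with \code{foldChange}, \code{mfi} and \code{auc}
#'   filled.
#' @export
simFoldChange <- function(res) {
  stopifnot(is(res, "GrmSimResult"))
  i0 <- which(res@evalTimes == 0)
  if (length(i0) != 1) stop("evalTimes must contain t = 0 exactly once")
  m0 <- res@mrna[i0]
  if (!is.finite(m0) || m0 <= 0) stop("mRNA at t = 0 must be positive")
  res@foldChange <- res@mrna / m0
  win <- res@evalTimes >= 0 & res@evalTimes <= 180
  res@mfi <- mfi(res@foldChange[win])
  res@auc <- auc(res@foldChange[win], res@evalTimes[win])
  res
}

#' Max-fold induction of a fold-change series
#'
#' @param fc fold-change values over the 0-180 min window.
#' @return the maximum of the series.
#' @examples
#' mfi(c(1, 2.5, 4, 3))  # 4
#' @export
mfi <- function(fc) {
  if (is(fc, "GrmSimResult")) fc <- fc@foldChange
  if (length(fc) == 0) stop("empty fold-change series")
  max(fc)
}

#' Area under a fold-change time course
#'
#' Trapezoidal integral of the series against its sampling times, in
#' fold x minutes.
#'
#' @param fc fold-change values.
#' @param times sampling times in minutes, ascending, same length.
#' @return the trapezoidal integral.
#' @examples
#' auc(c(1, 3), c(0, 15))  # 30
#' @export
auc <- function(fc, times) {
  if (length(fc) != length(times)) stop("fc and times must have equal length")
  if (length(fc) < 2) stop("need at least two points")
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  pracma::trapz(times, fc)
}
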