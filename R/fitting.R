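# Two-step bounded multistart fitting of one model to one gene in one
# biological replicate.
#
# Stage 1 minimizes the nRMSD of the jointly max-normalized fold change
# in the CONTROL condition from 100 (default) initial parameter sets
# drawn inside the model's global bounds.  Parameter sets passing the
# nRMSD filter (threshold 0.5, escalated to 0.6 / 0.7 when fewer than
# two survive) define per-parameter min/max bounds.  Stage 2 redraws 100
# starts inside those bounds and minimizes the siIkBa nRMSD; each stage-2
# record is finalized with both conditions' nRMSD and MFI/AUC summaries.

#' Jointly max-normalize a control / siIkBa pair of series
#'
#' One affine map from the pooled min and max of both series (the
#' "entire dataset") sends the pooled minimum to 0 and the pooled maximum
#' to 1.
#'
#' @param ctrl,si numeric series (e.g. fold changes).
#' @return list with normalized \code{ctrl} and \code{si}.
#' @examples
#' maxNormalize(c(1, 3), c(1, 2))  # ctrl 0,1; si 0,0.5
#' @export
maxNormalize <- function(ctrl, si) {
  pooled <- range(c(ctrl, si))
  rg <- diff(pooled)
  if (!is.finite(rg) || rg <= 0)
    stop("cannot max-normalize: zero pooled range")
  list(ctrl = (ctrl - pooled[1]) / rg, si = (si - pooled[1]) / rg)
}

#' Normalized root-mean-square deviation
#'
#' \eqn{\sqrt{(1/n) \sum_i \|x_i - y_i\|^2}} between two equally long,
#' max-normalized series.
#'
#' @param x,y numeric series of equal length.
#' @return the RMSD.
#' @examples
#' nrmsd(c(0, 1), c(1, 0))  # 1
#' @export
nrmsd <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 1) stop("empty series")
  sqrt(mean((x - y)^2))
}

#' Fitting objective: fold-change nRMSD plus steady-state drift penalty
#'
#' Simulates BOTH conditions with the candidate parameters, computes the
#' simulated fold changes at the data sampling times, max-normalizes them
#' jointly over the two conditions (mirroring the joint normalization of
#' the data), and returns the nRMSD against the (jointly normalized) data
#' in the target condition plus the steady-state drift
#' \eqn{|\hat m(0) - \hat m(-60\,\mathrm{min})|} on the same normalized
#' scale (both terms unweighted).  A failed simulation returns the
#' sentinel value 1e6 so derivative-free search can continue.
#'
#' @param freeValues named (or model-ordered) numeric vector of free
#'   parameter values inside the global bounds.
#' @param model model name.
#' @param grids \code{list(ctrl =, si =)} of \linkS4class{NfkbInputGrid}.
#' @param dataFc \code{list(ctrl =, si =)} raw fold-change series at
#'   \code{evalTimes}.
#' @param targetCondition \code{"ctrl"} or \code{"siIkBa"}.
#' @param evalTimes sampling times in minutes.
#' @param penalty include the steady-state drift term (default TRUE).
#' @param dt integration step override (seconds).
#' @return non-negative objective value.
#' @export
grmObjective <- function(freeValues, model, grids, dataFc,
                         targetCondition = c("ctrl", "siIkBa"),
                         evalTimes = seq(0, 180, by = 15), penalty = TRUE,
                         dt = NULL) {
  targetCondition <- match.arg(targetCondition)
  def <- grmModelDef(model)
  if (!is.null(names(freeValues))) freeValues <- freeValues[def$free]
  names(freeValues) <- def$free
  dataNorm <- maxNormalize(dataFc$ctrl, dataFc$si)
  ps <- grmParamSet(model, freeValues)
  if (is.null(dt)) dt <- defaultDt(model)
  .cppObjective(def$id, packParams(ps),
                grids$ctrl@values, grids$ctrl@tStartS,
                grids$si@values, grids$si@tStartS,
                dataNorm$ctrl, dataNorm$si,
                minToSec(evalTimes),
                if (targetCondition == "ctrl") 0L else 1L,
                -3600, 10800, dt, penalty)
}

# fast internal objective factory: pre-packs everything invariant across
# evaluations of one optimization
objectiveFactory <- function(model, grids, dataFc, targetCondition,
                             evalTimes, penalty = TRUE, dt = NULL) {
  def <- grmModelDef(model)
  dataNorm <- maxNormalize(dataFc$ctrl, dataFc$si)
  if (is.null(dt)) dt <- defaultDt(model)
  target <- if (targetCondition == "ctrl") 0L else 1L
  evalS <- minToSec(evalTimes)
  gcV <- grids$ctrl@values; gcT0 <- grids$ctrl@tStartS
  gsV <- grids$si@values; gsT0 <- grids$si@tStartS
  # direct packing into the C++ layout (no S4 construction per evaluation)
  x <- def$fixed
  idx <- setNames(seq_along(def$free), def$free)
  packFree <- switch(model,
    simple = function(f) c(x[["k_syn"]], f[idx[["k_deg"]]], f[idx[["K_D"]]],
                           x[["h"]], f[idx[["tau"]]]),
    iffl = function(f) c(x[["k_syn"]], f[idx[["k_deg"]]], f[idx[["K_D1"]]],
                         f[idx[["K_D2"]]], x[["h"]], f[idx[["tau"]]],
                         x[["k_degTF"]], x[["K_DTF"]], x[["h_TF"]],
                         x[["tau_TF"]]),
    cycle3 = function(f) c(x[["k_syn"]], f[idx[["k_deg"]]], f[idx[["k_1"]]],
                           f[idx[["k_2"]]], 0.01 * f[idx[["k_1"]]],
                           0.01 * f[idx[["k_2"]]], x[["k_m3"]],
                           f[idx[["K_D1"]]], f[idx[["K_D2"]]], x[["K_D3"]],
                           f[idx[["tau"]]]),
    v4 = function(f) c(x[["k_syn"]], f[idx[["k_deg"]]], f[idx[["k_1"]]],
                       f[idx[["k_2"]]], 0.01 * f[idx[["k_1"]]],
                       0.01 * f[idx[["k_2"]]], x[["k_m3"]],
                       f[idx[["K_D1"]]], f[idx[["K_D2"]]], x[["K_D3"]],
                       f[idx[["K_DTF2"]]], x[["h"]], f[idx[["tau"]]],
                       x[["k_degTF"]], x[["K_DTF"]], x[["h_TF"]],
                       x[["tau_TF"]]))
  function(free, penaltyOn = penalty, targetOverride = target) {
    .cppObjective(def$id, packFree(free), gcV, gcT0, gsV, gsT0,
                  dataNorm$ctrl, dataNorm$si, evalS, targetOverride,
                  -3600, 10800, dt, penaltyOn)
  }
}

#' Draw initial parameter vectors inside bounds
#'
#' Rate and affinity parameters are drawn log-uniformly (their bounds
#' span several decades); the delay tau is drawn uniformly.
#'
#' @param bounds 2 x p matrix with rows \code{lo}, \code{hi} and named
#'   columns.
#' @param n number of draws (default 100).
#' @param seed RNG seed.
#' @param logScale named logical; defaults to TRUE for every parameter
#'   except \code{tau}.
#' @return an n x p matrix of in-bounds draws.
#' @export
sampleInitial <- function(bounds, n = 100, seed = 1L, logScale = NULL) {
  if (n < 1) stop("n must be >= 1")
  p <- colnames(bounds)
  if (is.null(logScale))
    logScale <- setNames(p != "tau", p)
  set.seed(seed)
  draws <- vapply(p, function(nm) {
    lo <- bounds["lo", nm]; hi <- bounds["hi", nm]
    if (logScale[[nm]]) {
      exp(runif(n, log(lo), log(hi)))
    } else {
      runif(n, lo, hi)
    }
  }, numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, p))
  draws
}

# map between the box (lo, hi) and an unconstrained search space: the
# box is unit-scaled (after a log transform for the log-scale rate /
# affinity parameters) and the unconstrained coordinate is folded back
# into the unit interval by a triangular wave, so bounds act as
# reflecting walls and the objective keeps full sensitivity near them
# (a squashing transform would create flat plateaus where the simplex
# search stalls)
makeTransform <- function(bounds, logScale) {
  p <- colnames(bounds)
  g <- function(x) ifelse(logScale[p], log(x), x)
  glo <- g(bounds["lo", ]); ghi <- g(bounds["hi", ])
  span <- ghi - glo
  eps <- 1e-9
  toU <- function(x) {
    pmin(pmax((g(x) - glo) / span, eps), 1 - eps)
  }
  toX <- function(u) {
    z <- abs(u %% 2)
    z <- ifelse(z > 1, 2 - z, z)
    z <- pmin(pmax(z, eps), 1 - eps)
    gx <- glo + span * z
    ifelse(logScale[p], exp(gx), gx)
  }
  list(toU = toU, toX = toX)
}

#' Bounded derivative-free local optimization
#'
#' Subspace-searching Nelder-Mead: the box constraint is removed by a
#' log/logit change of coordinates and the simplex search runs in the
#' unconstrained space, stopping at relative tolerance 1e-4 or after
#' \code{maxEval} evaluations.  The returned objective never exceeds the
#' starting value.
#'
#' @param fn objective taking a free-parameter vector.
#' @param x0 starting point inside \code{bounds}.
#' @param bounds 2 x p bounds matrix, rows \code{lo}/\code{hi}.
#' @param logScale named logical (default: TRUE except \code{tau}).
#' @param relTol relative convergence tolerance (default 1e-4).
#' @param maxEval evaluation cap (default 2000).
#' @return list with \code{par}, \code{value} and \code{nEvals}.
#' @export
localOptimize <- function(fn, x0, bounds, logScale = NULL, relTol = 1e-4,
                          maxEval = 2000) {
  p <- colnames(bounds)
  if (is.null(logScale)) logScale <- setNames(p != "tau", p)
  tr <- makeTransform(bounds, logScale)
  f0 <- fn(x0)
  if (!is.finite(f0)) stop("objective is not finite at the starting point")
  wrapped <- function(u) {
    v <- fn(tr$toX(u))
    if (!is.finite(v)) 1e6 else v
  }
  if (length(x0) == 1) {
    # Nelder-Mead is unreliable in 1-D; use golden-section instead
    opt <- stats::optimize(function(u) wrapped(u), interval = c(0, 1),
                           tol = relTol)
    u <- opt$minimum
    if (opt$objective <= f0)
      return(list(par = setNames(tr$toX(u), p), value = opt$objective,
                  nEvals = NA_integer_))
    return(list(par = x0, value = f0, nEvals = NA_integer_))
  }
  # subplex-style behavior: repeated Nelder-Mead rounds (each rebuilds the
  # simplex around the current best point) until a round no longer improves
  # by the relative tolerance, within the overall evaluation budget
  u <- tr$toU(x0)
  fBest <- f0
  evals <- 0L
  repeat {
    res <- optim(u, wrapped, method = "Nelder-Mead",
                 control = list(reltol = relTol,
                                maxit = max(50L, maxEval - evals)))
    evals <- evals + unname(res$counts[1])
    improved <- res$value < fBest - relTol * (abs(fBest) + relTol)
    if (res$value <= fBest) {
      u <- res$par
      fBest <- res$value
    }
    if (!improved || evals >= maxEval) break
  }
  if (fBest <= f0) {
    list(par = setNames(tr$toX(u), p), value = fBest, nEvals = evals)
  } else {
    list(par = x0, value = f0, nEvals = evals)
  }
}

# finalize a fitted parameter vector: both conditions' nRMSD and the
# MFI / AUC of the fitted simulations
finalizeRecord <- function(free, model, grids, obj, evalTimes) {
  out <- list(nrmsd_ctrl = obj(free, penaltyOn = FALSE, targetOverride = 0L),
              nrmsd_si = obj(free, penaltyOn = FALSE, targetOverride = 1L))
  ps <- grmParamSet(model, free)
  for (cond in c("ctrl", "si")) {
    sim <- simFoldChange(simulateGrm(ps, grids[[cond]],
                                     evalTimes = evalTimes))
    out[[paste0("mfi_", cond)]] <- sim@mfi
    out[[paste0("auc_", cond)]] <- sim@auc
  }
  out
}

#' Stage 1: multistart control-condition fits over the global bounds
#'
#' @param dataFc \code{list(ctrl =, si =)} raw fold-change series of one
#'   replicate.
#' @param model model name.
#' @param grids \code{list(ctrl =, si =)} input grids of the same
#'   replicate.
#' @param n number of starts (default 100).
#' @param seed RNG seed for the initial draws.
#' @param evalTimes sampling times in minutes.
#' @param relTol,maxEval optimizer controls.
#' @return data.frame with one row per start: the optimized free
#'   parameters, \code{objective} (control nRMSD + penalty),
#'   \code{nrmsd_ctrl}, \code{n_evals}, \code{start} and \code{seed}.
#' @export
stage1Fit <- function(dataFc, model, grids, n = 100, seed = 1L,
                      evalTimes = seq(0, 180, by = 15), relTol = 1e-4,
                      maxEval = 2000) {
  def <- grmModelDef(model)
  if (is.null(dataFc$ctrl)) stop("control data required for stage 1")
  obj <- objectiveFactory(model, grids, dataFc, "ctrl", evalTimes)
  starts <- sampleInitial(def$bounds, n, seed, def$logScale)
  recs <- lapply(seq_len(n), function(i) {
    fit <- localOptimize(function(x) obj(x), starts[i, ], def$bounds,
                         def$logScale, relTol, maxEval)
    c(as.list(fit$par),
      list(objective = fit$value,
           nrmsd_ctrl = obj(fit$par, penaltyOn = FALSE),
           n_evals = fit$nEvals, start = i, seed = seed))
  })
  out <- do.call(rbind, lapply(recs, as.data.frame))
  out$model_name <- model
  out
}

#' Derive stage-2 bounds from stage-1 survivors
#'
#' Records with control nRMSD below the first threshold admitting at
#' least \code{minSurvivors} survivors (0.5, escalated to 0.6 then 0.7)
#' define elementwise min/max bounds for stage 2.  Degenerate dimensions
#' (min = max) are widened by a relative 0.1%, clipped to the global
#' bounds.
#'
#' @param records stage-1 data.frame.
#' @param model model name.
#' @param thresholds escalation ladder (default 0.5, 0.6, 0.7).
#' @param minSurvivors minimum survivors before escalation stops
#'   (default 2; min/max bounds need two points to be non-degenerate).
#' @return 2 x p bounds matrix nested inside the global bounds.
#' @export
deriveBounds <- function(records, model, thresholds = c(0.5, 0.6, 0.7),
                         minSurvivors = 2) {
  if (nrow(records) == 0) stop("no stage-1 records")
  def <- grmModelDef(model)
  keep <- NULL
  for (th in thresholds) {
    keep <- records[records$nrmsd_ctrl < th, , drop = FALSE]
    if (nrow(keep) >= minSurvivors) break
  }
  if (is.null(keep) || nrow(keep) == 0)
    stop(sprintf("no parameter sets below nRMSD %g",
                 thresholds[length(thresholds)]))
  b <- vapply(def$free, function(nm) {
    v <- keep[[nm]]
    c(lo = min(v), hi = max(v))
  }, numeric(2))
  rownames(b) <- c("lo", "hi")
  degen <- b["hi", ] - b["lo", ] <= 0
  if (any(degen)) {
    b["lo", degen] <- pmax(b["lo", degen] * 0.999, def$bounds["lo", degen])
    b["hi", degen] <- pmin(b["hi", degen] * 1.001, def$bounds["hi", degen])
    # tau can be 0; widen additively in that case
    still <- b["hi", ] - b["lo", ] <= 0
    b["hi", still] <- pmin(b["lo", still] + 1e-6 +
                             0.001 * (def$bounds["hi", still] -
                                        def$bounds["lo", still]),
                           def$bounds["hi", still])
  }
  b
}

#' Stage 2: multistart siIkBa-condition fits within the stage-1 bounds
#'
#' Each returned record is finalized by computing both conditions' nRMSD
#' and the MFI / AUC of the fitted simulations from the single optimized
#' parameter set.
#'
#' @inheritParams stage1Fit
#' @param stage2Bounds bounds from \code{\link{deriveBounds}}.
#' @return data.frame with one row per start: optimized parameters,
#'   \code{objective}, \code{nrmsd_ctrl}, \code{nrmsd_si},
#'   \code{mfi_ctrl}, \code{mfi_si}, \code{auc_ctrl}, \code{auc_si},
#'   \code{n_evals}, \code{start}, \code{seed}.
#' @export
stage2Fit <- function(dataFc, model, grids, stage2Bounds, n = 100,
                      seed = 1L, evalTimes = seq(0, 180, by = 15),
                      relTol = 1e-4, maxEval = 2000) {
  def <- grmModelDef(model)
  obj <- objectiveFactory(model, grids, dataFc, "siIkBa", evalTimes)
  starts <- sampleInitial(stage2Bounds, n, seed, def$logScale)
  recs <- lapply(seq_len(n), function(i) {
    fit <- localOptimize(function(x) obj(x), starts[i, ], stage2Bounds,
                         def$logScale, relTol, maxEval)
    fin <- finalizeRecord(fit$par, model, grids, obj, evalTimes)
    c(as.list(fit$par),
      list(objective = fit$value), fin,
      list(n_evals = fit$nEvals, start = i, seed = seed))
  })
  out <- do.call(rbind, lapply(recs, as.data.frame))
  out$model_name <- model
  out
}

#' Two-step fit of one model to one gene in both replicates
#'
#' Runs stage 1 (control), bound derivation and stage 2 (siIkBa) for each
#' biological replicate with replicate-specific seeds derived from
#' \code{seed}.
#'
#' @param geneData per-replicate fold changes:
#'   \code{list(rep1 = list(ctrl =, si =), rep2 = ...)}.
#' @param model model name.
#' @param inputGrids per-replicate grids, same structure.
#' @param n starts per stage (default 100).
#' @param seed master seed.
#' @param thresholds stage-1 filter escalation ladder.
#' @param evalTimes sampling times in minutes.
#' @param relTol,maxEval optimizer controls.
#' @return list with stage-2 data.frames \code{rep1}, \code{rep2} and the
#'   stage-1 results and derived bounds under \code{details}.
#' @export
fitGeneModel <- function(geneData, model, inputGrids, n = 100, seed = 1L,
                         thresholds = c(0.5, 0.6, 0.7),
                         evalTimes = seq(0, 180, by = 15), relTol = 1e-4,
                         maxEval = 2000) {
  reps <- names(geneData)
  set.seed(seed)
  subSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                2 * length(reps)),
                     nrow = length(reps))
  out <- list(details = list())
  for (k in seq_along(reps)) {
    r <- reps[k]
    s1 <- stage1Fit(geneData[[r]], model, inputGrids[[r]], n,
                    seed = subSeeds[k, 1], evalTimes = evalTimes,
                    relTol = relTol, maxEval = maxEval)
    b2 <- deriveBounds(s1, model, thresholds)
    s2 <- stage2Fit(geneData[[r]], model, inputGrids[[r]], b2, n,
                    seed = subSeeds[k, 2], evalTimes = evalTimes,
                    relTol = relTol, maxEval = maxEval)
    s2$replicate <- k
    out[[r]] <- s2
    out$details[[r]] <- list(stage1 = s1, bounds = b2)
  }
  out
}
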