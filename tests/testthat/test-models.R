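test_that("Hill activation matches its closed form", {
  expect_equal(hillActivation(3, K = 1, h = 2), 9 / 10)
  expect_equal(hillActivation(0, K = 5, h = 2), 0)
  expect_equal(hillActivation(1 / 7, K = 7, h = 3.5), 0.5)
  expect_error(hillActivation(-1, 1, 1), ">= 0")
})

test_that("delayed lookup shifts and holds", {
  vals <- rep(2, 25201)
  vals[(14400 + 60 + 1):25201] <- 9  # step at t = 60 s
  g <- nfkbInputGrid(vals)
  expect_equal(delayedValue(g, 100, 0), 9)
  expect_equal(delayedValue(g, 100, 60), 2)   # shifted step
  expect_equal(delayedValue(g, 120, 60), 9)
  expect_equal(delayedValue(g, 100, 7200), 2) # pre-window hold
  expect_error(delayedValue(g, -14000, 7200), "before the grid start")
})

test_that("steady states satisfy the equilibrium equations", {
  ps <- grmParamSet("simple", c(k_deg = 1e-3, K_D = 0.5, tau = 1))
  expect_equal(steadyState(ps, 2)$mrna, 0.5 / 1e-3)
  # saturation limit: K_D * n0 -> large gives k_syn / k_deg
  ps2 <- grmParamSet("simple", c(k_deg = 1e-3, K_D = 900, tau = 1))
  expect_equal(steadyState(ps2, 100)$mrna, 1 / 1e-3, tolerance = 1e-4)
  # negligible drive in the promoter cycle: closed state dominates
  ps3 <- grmParamSet("cycle3", c(k_1 = 6.1e-5, k_2 = 0.01, k_deg = 1e-3,
                                 K_D1 = 0.0011, K_D2 = 0.1, tau = 1))
  st <- steadyState(ps3, 2)$states
  expect_gt(st[["C"]], 0.99)
  expect_equal(sum(st), 1, tolerance = 1e-9)
  # promoter-cycle steady state satisfies all three rate balances
  ps4 <- exampleParams("v4")
  st4 <- steadyState(ps4, 2)$states
  fr <- freeParams(ps4)
  a <- fr[["k_1"]] * hillActivation(2, fr[["K_D1"]], 1)
  b <- fr[["k_2"]] * hillActivation(2, fr[["K_D2"]], 1)
  g <- 0.5 * st4[["A"]] / (0.5 * st4[["A"]] + 1)
  expect_equal(-a * st4[["C"]] + 0.01 * fr[["k_1"]] * st4[["O"]] + g, 0,
               tolerance = 1e-12)
  expect_equal(b * st4[["O"]] - 0.01 * fr[["k_2"]] * st4[["A"]] - g, 0,
               tolerance = 1e-12)
})

test_that("constant input preserves the steady state over the window", {
  for (model in grmModelNames()) {
    ps <- exampleParams(model)
    sim <- simulateGrm(ps, constGrid(5), evalTimes = seq(-60, 180, 30))
    ss <- steadyState(ps, 5)
    expect_lt(max(abs(mrnaValues(sim) - ss$mrna)) / ss$mrna, 1e-6)
    if (model %in% c("cycle3", "v4")) {
      st <- promoterStates(sim)
      expect_lt(max(abs(sweep(st, 2, ss$states))), 1e-6)
    }
  }
})

test_that("promoter-state fractions are conserved and positive", {
  set.seed(42)
  for (model in c("cycle3", "v4")) {
    def <- grmModelDef(model)
    draws <- sampleInitial(def$bounds, 5, seed = 42, def$logScale)
    for (i in seq_len(nrow(draws))) {
      ps <- grmParamSet(model, draws[i, ])
      sim <- simulateGrm(ps, stdInputs()$rep1$ctrl)
      st <- promoterStates(sim)
      expect_lt(max(abs(rowSums(st) - 1)), 1e-6)
      expect_gte(min(st), -1e-9)
      expect_gte(min(mrnaValues(sim)), -1e-9)
    }
  }
})

test_that("simple-model step response matches the exponential closed form", {
  n0 <- 2; n1 <- 50; kdeg <- 1e-3; KD <- 0.5
  # constant grid at the post-step level with the pre-step steady state
  # supplied as n0: an input step at t = 0
  ps <- grmParamSet("simple", c(k_deg = kdeg, K_D = KD, tau = 1e-9))
  et <- seq(0, 180, 5)
  sim <- simulateGrm(ps, constGrid(n1), evalTimes = et, n0 = n0)
  ss0 <- hillActivation(n0, KD, 1) / kdeg
  ss1 <- hillActivation(n1, KD, 1) / kdeg
  closed <- ss1 + (ss0 - ss1) * exp(-kdeg * et * 60)
  expect_lt(max(abs(mrnaValues(sim) - closed) / closed), 1e-4)
})

test_that("iffl with competitor coupling removed reduces to simple h = 2", {
  # K_D2 at the lower bound with a test-only zeroed competitor: compare
  # against an iffl whose competitor term is structurally absent by
  # making TF contribute nothing (K_D2 -> tiny via bounds override)
  b <- grmModelDef("iffl")$bounds
  b["lo", "K_D2"] <- 1e-18
  psI <- grmParamSet("iffl", c(k_deg = 5e-4, K_D1 = 0.1, K_D2 = 1e-15,
                               tau = 600), bounds = b)
  grid <- stdInputs()$rep1$ctrl
  simI <- simulateGrm(psI, grid)
  # reference: the simple-model equation with h = 2 (closed-form steady
  # state and the same integrator), via a v4-free direct computation
  psS <- grmParamSet("simple", c(k_deg = 5e-4, K_D = 0.1, tau = 600))
  # simple model has h fixed at 1; emulate h = 2 by squaring through an
  # independent fine-grid integration of dm/dt = hill2 - k m
  vals <- gridValues(grid); t0 <- grid@tStartS
  u <- function(t) vals[pmin(pmax(round(t) - t0 + 1, 1), length(vals))]
  h2 <- function(x) (0.1 * x)^2 / ((0.1 * x)^2 + 1)
  n0 <- u(0)
  m <- h2(n0) / 5e-4
  dt <- 1
  mOut <- numeric(13)
  mOut[1] <- m
  ti <- 0
  for (k in seq_len(10800)) {
    # RK4 on the 1-s grid
    f <- function(tt, mm) h2(u(tt - 600)) - 5e-4 * mm
    k1 <- f(ti, m); k2 <- f(ti + 0.5, m + 0.5 * k1)
    k3 <- f(ti + 0.5, m + 0.5 * k2); k4 <- f(ti + 1, m + k3)
    m <- m + (k1 + 2 * k2 + 2 * k3 + k4) / 6
    ti <- ti + 1
    if (ti %% 900 == 0) mOut[ti / 900 + 1] <- m
  }
  expect_lt(max(abs(mrnaValues(simI) - mOut) / mOut), 1e-5)
})

test_that("fold change, MFI and AUC summarize a simulation", {
  ps <- exampleParams("simple")
  sim <- simFoldChange(simulateGrm(ps, stdInputs()$rep1$ctrl))
  fc <- foldChangeValues(sim)
  expect_equal(fc[1], 1)
  expect_equal(fc, mrnaValues(sim) / mrnaValues(sim)[1])
  expect_equal(sim@mfi, max(fc))
  expect_equal(sim@auc, auc(fc, defaultEvalTimes))
  expect_equal(mfi(c(1, 2.5, 4, 3)), 4)
  expect_equal(mfi(rep(1, 5)), 1)
  expect_equal(auc(c(1, 3), c(0, 15)), 30)
  expect_equal(auc(rep(1, 13), defaultEvalTimes), 180)
  # linearity of the trapezoidal integral
  a1 <- runif(13); a2 <- runif(13)
  expect_equal(auc(a1 + a2, defaultEvalTimes),
               auc(a1, defaultEvalTimes) + auc(a2, defaultEvalTimes))
  expect_error(auc(1:3, 1:4), "equal length")
  expect_error(mfi(numeric(0)), "empty")
})

test_that("integrators agree with an independent reference solver", {
  skip_if_not_installed("deSolve")
  grid <- stdInputs()$rep1$si
  vals <- gridValues(grid)
  uf <- stats::approxfun(gridTimes(grid), vals, rule = 2)
  hill <- function(x, K, h) {
    z <- (K * x)^h
    z / (z + 1)
  }
  evalMin <- defaultEvalTimes
  times <- sort(unique(c(-3600, 0, evalMin * 60)))
  ctl <- list(mxhist = 1e5)

  for (model in grmModelNames()) {
    free <- exampleFree(model)
    ps <- grmParamSet(model, free)
    ss <- steadyState(ps, uf(0))
    f <- fixedParams(ps)
    ref <- switch(model,
      simple = {
        rhs <- function(t, y, p)
          list(hill(uf(t - free[["tau"]]), free[["K_D"]], 1) -
                 free[["k_deg"]] * y[1])
        deSolve::ode(c(m = ss$mrna), times, rhs, NULL, method = "lsoda",
                     rtol = 1e-9, atol = 1e-12, maxsteps = 1e5)
      },
      iffl = {
        y0 <- c(TF = ss$tf, m = ss$mrna)
        rhs <- function(t, y, p) {
          TFlag <- if (t - f[["tau_TF"]] <= -3600) y0[[1]] else
            deSolve::lagvalue(t - f[["tau_TF"]], 1)
          ul <- uf(t - free[["tau"]])
          x1 <- (free[["K_D1"]] * ul)^2
          x2 <- (free[["K_D2"]] * TFlag)^2
          list(c(hill(ul, f[["K_DTF"]], 1) - f[["k_degTF"]] * y[1],
                 x1 / (x1 + x2 + 1) - free[["k_deg"]] * y[2]))
        }
        deSolve::dede(y0, times, rhs, NULL, rtol = 1e-9, atol = 1e-12,
                      control = ctl, maxsteps = 1e5)
      }, {
        # cycle3 / v4
        isv4 <- model == "v4"
        y0 <- unname(c(ss$states, if (isv4) ss$tf, ss$mrna))
        km1 <- 0.01 * free[["k_1"]]; km2 <- 0.01 * free[["k_2"]]
        rhs <- function(t, y, p) {
          us <- uf(t - if (isv4) free[["tau"]] else 0)
          a <- free[["k_1"]] * hill(us, free[["K_D1"]], 1)
          b <- free[["k_2"]] * hill(us, free[["K_D2"]], 1)
          g <- 0.5 * y[3] / (0.5 * y[3] + 1)
          dC <- -a * y[1] + km1 * y[2] + g
          dO <- a * y[1] - (b + km1) * y[2] + km2 * y[3]
          dA <- b * y[2] - km2 * y[3] - g
          Alag <- if (t - free[["tau"]] <= -3600) y0[3] else
            deSolve::lagvalue(t - free[["tau"]], 3)
          if (isv4) {
            dTF <- hill(uf(t), f[["K_DTF"]], 1) - f[["k_degTF"]] * y[4]
            TFlag <- if (t - f[["tau_TF"]] <= -3600) y0[4] else
              deSolve::lagvalue(t - f[["tau_TF"]], 4)
            x1 <- Alag^2; x2 <- (free[["K_DTF2"]] * TFlag)^2
            list(c(dC, dO, dA, dTF, x1 / (x1 + x2 + 1) - free[["k_deg"]] * y[5]))
          } else {
            list(c(dC, dO, dA, Alag - free[["k_deg"]] * y[4]))
          }
        }
        deSolve::dede(y0, times, rhs, NULL, rtol = 1e-9, atol = 1e-12,
                      control = ctl, maxsteps = 1e5)
      })
    refM <- ref[match(evalMin * 60, ref[, 1]), ncol(ref)]
    mine <- mrnaValues(simulateGrm(ps, grid, evalTimes = evalMin))
    expect_lt(max(abs(mine - refM) / pmax(refM, 1e-300)), 1e-3,
              label = sprintf("%s vs reference solver", model))
  }
})

test_that("parameter sets validate their bounds and constants", {
  expect_error(grmParamSet("simple", c(k_deg = 1, K_D = 0.1, tau = 600)),
               "outside bounds")
  expect_error(grmParamSet("nope", c(a = 1)), "unknown model")
  ps <- exampleParams("v4")
  expect_equal(fixedParams(ps)[["tau_TF"]], 7200)
  expect_equal(fixedParams(ps)[["k_degTF"]], 8.022537e-6)
  expect_equal(fixedParams(ps)[["K_DTF"]], 100)
  expect_equal(unname(paramBounds(ps)[, "k_2"]), c(0.007, 69.315))
  expect_equal(unname(paramBounds(exampleParams("cycle3"))[, "k_2"]),
               c(0.007, 69.31))
})

test_that("v4 promoter states equal cycle3 states on a tau-shifted input", {
  # v4 drives its promoter states with NFkB(t - tau); cycle3 with
  # NFkB(t).  Feeding cycle3 an input grid delayed by tau must therefore
  # reproduce v4's promoter-state trajectories (the competitor coupling
  # touches only the mRNA equation).
  tau <- 900
  grid <- stdInputs()$rep1$ctrl
  vals <- gridValues(grid)
  shifted <- c(rep(vals[1], tau), vals[seq_len(length(vals) - tau)])
  gridShift <- nfkbInputGrid(shifted, grid@tStartS, grid@tEndS)
  base <- c(k_1 = 1.2e-4, k_2 = 0.08, k_deg = 1e-3, K_D1 = 2,
            K_D2 = 4e-3)
  simC <- simulateGrm(grmParamSet("cycle3", c(base, tau = tau)), gridShift)
  simV <- simulateGrm(grmParamSet("v4", c(base, K_DTF2 = 5e-3, tau = tau)),
                      grid)
  expect_lt(max(abs(promoterStates(simC) - promoterStates(simV))), 1e-6)
})
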