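test_that("joint max-normalization spans [0, 1] over the pooled pair", {
  out <- maxNormalize(c(1, 3), c(1, 2))
  expect_equal(out$ctrl, c(0, 1))
  expect_equal(out$si, c(0, 0.5))
  # idempotence on an already [0, 1]-spanning pair
  again <- maxNormalize(out$ctrl, out$si)
  expect_equal(again, out)
  expect_error(maxNormalize(c(2, 2), c(2, 2)), "zero pooled range")
})

test_that("nrmsd matches the hand-computed RMSD formula", {
  expect_equal(nrmsd(c(0, 1), c(0, 1)), 0)
  expect_equal(nrmsd(c(0, 1), c(1, 0)), 1)
  expect_equal(nrmsd(c(0, 0, 0), c(0.3, 0.3, 0.3)), 0.3)
  expect_error(nrmsd(1:3, 1:4), "lengths differ")
})

test_that("objective is near zero at the ground truth and penalizes drift", {
  d <- oneGeneData("simple")
  free <- exampleFree("simple")
  obj <- grmObjective(free, "simple", d$grids$rep1, d$fc$rep1, "ctrl")
  expect_lt(obj, 1e-3)
  # steady-state initialization makes the penalty term negligible
  noPen <- grmObjective(free, "simple", d$grids$rep1, d$fc$rep1, "ctrl",
                        penalty = FALSE)
  expect_lt(abs(obj - noPen), 1e-6)
  # a flat response against varying data scores the nrmsd of a flat line
  flat <- c(k_deg = 1.9e-3, K_D = 999, tau = 1)  # saturated: fc stays ~1
  objFlat <- grmObjective(flat, "simple", d$grids$rep1, d$fc$rep1, "ctrl",
                          penalty = FALSE)
  expect_gt(objFlat, 0.2)
})

test_that("initial sampling is in-bounds, log-scaled and reproducible", {
  def <- grmModelDef("cycle3")
  draws <- sampleInitial(def$bounds, n = 100, seed = 5)
  expect_identical(dim(draws), c(100L, 6L))
  expect_true(all(draws >= rep(def$bounds["lo", ], each = 100)))
  expect_true(all(draws <= rep(def$bounds["hi", ], each = 100)))
  expect_identical(draws, sampleInitial(def$bounds, n = 100, seed = 5))
  # log-uniform rates: the median of k_deg sits near the geometric midpoint
  gm <- sqrt(prod(def$bounds[, "k_deg"]))
  expect_lt(abs(log(median(draws[, "k_deg"]) / gm)), 1)
  # tau uniform: median near the arithmetic midpoint
  expect_lt(abs(median(draws[, "tau"]) - 3600) / 3600, 0.35)
  expect_error(sampleInitial(def$bounds, n = 0), "n must be")
})

test_that("local optimization solves bounded quadratic test problems", {
  b <- rbind(lo = c(a = 0.1, tau = 0), hi = c(a = 10, tau = 100))
  target <- c(2, 30)
  fn <- function(x) sum((x - target)^2)
  fit <- localOptimize(fn, c(a = 1, tau = 80), b)
  expect_equal(unname(fit$par), target, tolerance = 1e-2)
  expect_lte(fit$value, fn(c(1, 80)))
  # start at the minimum: no deterioration
  atMin <- localOptimize(fn, c(a = 2, tau = 30), b)
  expect_lte(atMin$value, fn(c(a = 2, tau = 30)) + 1e-12)
  # boundary-constrained minimum lands on the boundary
  fn2 <- function(x) sum((x - c(20, 30))^2)  # argmin outside the box
  fit2 <- localOptimize(fn2, c(a = 1, tau = 30), b)
  expect_equal(unname(fit2$par[1]), 10, tolerance = 1e-3)
})

test_that("stage-1 fitting returns n in-bounds records that improve", {
  d <- oneGeneData("simple")
  s1 <- stage1Fit(d$fc$rep1, "simple", d$grids$rep1, n = 6, seed = 2)
  expect_identical(nrow(s1), 6L)
  def <- grmModelDef("simple")
  for (nm in def$free) {
    expect_true(all(s1[[nm]] >= def$bounds["lo", nm]))
    expect_true(all(s1[[nm]] <= def$bounds["hi", nm]))
  }
  # optimizer contract: each record's objective is at or below its start
  starts <- sampleInitial(def$bounds, 6, seed = 2, def$logScale)
  for (i in 1:6) {
    f0 <- grmObjective(starts[i, ], "simple", d$grids$rep1, d$fc$rep1, "ctrl")
    expect_lte(s1$objective[i], f0 + 1e-12)
  }
  # zero-noise self-fit reaches a good control fit
  expect_lte(min(s1$nrmsd_ctrl), 0.1)
})

test_that("stage-2 bounds derive from survivors with threshold escalation", {
  rec <- data.frame(k_deg = c(1e-4, 4e-4, 1e-3), K_D = c(0.1, 0.3, 0.9),
                    tau = c(100, 300, 900),
                    nrmsd_ctrl = c(0.3, 0.4, 0.55))
  b <- deriveBounds(rec, "simple")
  expect_equal(unname(b[, "k_deg"]), c(1e-4, 4e-4))
  expect_equal(unname(b[, "K_D"]), c(0.1, 0.3))
  expect_equal(unname(b[, "tau"]), c(100, 300))
  # all records at 0.65: escalates to the 0.7 threshold, all survive
  rec2 <- rec
  rec2$nrmsd_ctrl <- rep(0.65, 3)
  b2 <- deriveBounds(rec2, "simple")
  expect_equal(unname(b2[, "tau"]), c(100, 900))
  # single survivor at 0.5: escalation continues until >= 2 survive
  rec3 <- rec
  rec3$nrmsd_ctrl <- c(0.45, 0.55, 0.68)
  b3 <- deriveBounds(rec3, "simple")
  expect_equal(unname(b3[, "tau"]), c(100, 300))
  # nothing below the final threshold: error
  rec4 <- rec
  rec4$nrmsd_ctrl <- rep(0.9, 3)
  expect_error(deriveBounds(rec4, "simple"), "no parameter sets")
  # derived bounds always nest inside the global bounds
  def <- grmModelDef("simple")
  expect_true(all(b["lo", def$free] >= def$bounds["lo", def$free]))
  expect_true(all(b["hi", def$free] <= def$bounds["hi", def$free]))
})

test_that("stage 2 finalizes records with both conditions' summaries", {
  d <- oneGeneData("simple")
  s1 <- stage1Fit(d$fc$rep1, "simple", d$grids$rep1, n = 6, seed = 2)
  b2 <- deriveBounds(s1, "simple")
  s2 <- stage2Fit(d$fc$rep1, "simple", d$grids$rep1, b2, n = 6, seed = 3)
  expect_identical(nrow(s2), 6L)
  for (nm in grmModelDef("simple")$free) {
    expect_true(all(s2[[nm]] >= b2["lo", nm] - 1e-12))
    expect_true(all(s2[[nm]] <= b2["hi", nm] + 1e-12))
  }
  expect_true(all(c("nrmsd_ctrl", "nrmsd_si", "mfi_ctrl", "mfi_si",
                    "auc_ctrl", "auc_si") %in% names(s2)))
  expect_lte(min(s2$nrmsd_si), 0.1)
  # recomputed control nrmsd equals a penalty-free objective call
  i <- which.min(s2$nrmsd_si)
  free <- unlist(s2[i, grmModelDef("simple")$free])
  expect_equal(s2$nrmsd_ctrl[i],
               grmObjective(free, "simple", d$grids$rep1, d$fc$rep1,
                            "ctrl", penalty = FALSE))
})

test_that("the two-step protocol is deterministic given the seed", {
  d <- oneGeneData("simple")
  a <- fitGeneModel(d$fc, "simple", d$grids, n = 4, seed = 99)
  b <- fitGeneModel(d$fc, "simple", d$grids, n = 4, seed = 99)
  expect_identical(a$rep1, b$rep1)
  expect_identical(a$rep2, b$rep2)
})
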