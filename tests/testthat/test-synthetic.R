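test_that("control trajectory has the two-pulse shape", {
  shape <- nfkbShapeParams(peak1Height = 10)
  tc <- makeNfkbTimeCourse(shape, "ctrl")
  v <- signalValues(tc)
  t <- timePoints(tc)
  expect_equal(v[t == 0], shape$baseline)
  # maximized at the grid point nearest the first peak time
  expect_equal(t[which.max(v)], 30)
  # exactly two local maxima on the default grid
  d <- diff(v)
  nmax <- sum(d[-length(d)] > 0 & d[-1] < 0) + (d[length(d)] > 0)
  expect_identical(nmax, 2L)
})

test_that("siIkBa trajectory saturates without post-peak decline", {
  shape <- nfkbShapeParams(siPlateau = 6)
  tc <- makeNfkbTimeCourse(shape, "siIkBa")
  v <- signalValues(tc)
  expect_equal(v[1], shape$baseline)
  expect_lte(max(v), 6)
  expect_gte(v[length(v)], 0.8 * max(v))
  # single global maximum in the final third of the window
  expect_gte(timePoints(tc)[which.max(v)], 120)
})

test_that("generators are deterministic given the seed", {
  shape <- nfkbShapeParams()
  a <- makeNfkbTimeCourse(shape, "ctrl", noiseCv = 0.05, seed = 3)
  b <- makeNfkbTimeCourse(shape, "ctrl", noiseCv = 0.05, seed = 3)
  expect_identical(signalValues(a), signalValues(b))
  c2 <- makeNfkbTimeCourse(shape, "ctrl", noiseCv = 0.05, seed = 4)
  expect_false(identical(signalValues(a), signalValues(c2)))
})

test_that("replicate 2 is an amplitude-scaled, time-perturbed replicate 1", {
  # with the timing perturbation disabled, replicate 2 is a pure
  # amplitude scaling of replicate 1
  pure <- nfkbShapeParams(replicateScale = 0.7, rep2TimeShift = 0,
                          rep2WidthScale = 1)
  r1 <- signalValues(makeNfkbTimeCourse(pure, "ctrl", replicate = 1))
  r2 <- signalValues(makeNfkbTimeCourse(pure, "ctrl", replicate = 2))
  expect_equal(r2 - pure$baseline, 0.7 * (r1 - pure$baseline))
  # the default shape also perturbs timing, so that the prepared
  # replicate inputs differ (a pure amplitude change is undone exactly
  # by the anchored rescaling)
  shape <- nfkbShapeParams()
  d2 <- signalValues(makeNfkbTimeCourse(shape, "ctrl", replicate = 2))
  expect_false(isTRUE(all.equal(d2 - 1, 0.7 * (r1 - 1))))
})

test_that("shape invariants are enforced", {
  expect_error(nfkbShapeParams(peak1Time = 80), "peak1Time < troughTime")
  expect_error(nfkbShapeParams(peak2Height = 9), "peak1Height > peak2Height")
  expect_error(nfkbShapeParams(siPlateau = 1), "siPlateau")
  expect_error(makeNfkbTimeCourse(nfkbShapeParams(), "ctrl",
                                  times = c(0, 30, 20, 180)), "ascending")
  expect_error(makeNfkbTimeCourse(nfkbShapeParams(), "ctrl",
                                  times = c(15, 30, 180)), "start at 0")
})

test_that("zero-noise gene table equals the noiseless simulation", {
  grids <- stdGrids()
  genes <- makeGroundTruthGenes(2, models = c("simple", "iffl"), seed = 11)
  tbl <- makeGeneTable(genes, grids)
  expect_identical(dim(tbl), c(2L, 52L))
  sim <- simulateGrm(genes[[1]]$params, grids$rep1$ctrl)
  expect_equal(unname(tbl[1, sprintf("ctrl_rep1_t%d", defaultEvalTimes)]),
               mrnaValues(sim), tolerance = 1e-12)
})

test_that("gene table noise is mean-one multiplicative log-normal", {
  # two different seeds give different tables sharing the noiseless mean
  grids <- stdGrids()
  base <- makeGroundTruthGenes(1, models = "simple", seed = 21)[[1]]
  noiseless <- makeGeneTable(list(base), grids)
  n <- 200
  cv <- 0.1
  draws <- vapply(seq_len(n), function(i) {
    g <- base
    g$noise_cv <- cv
    g$seed <- i
    makeGeneTable(list(g), grids)[1, "ctrl_rep1_t90"]
  }, numeric(1))
  expect_false(draws[1] == draws[2])
  mu <- noiseless[1, "ctrl_rep1_t90"]
  expect_lt(abs(mean(draws) - mu) / mu, 3 * cv / sqrt(n))
})

test_that("counts fixture has the advertised scaling", {
  fx <- makeCountsFixture(nGenes = 200, lengths = rep(1000, 200),
                          sizeFactors = c(1, 2), seed = 9)
  expect_true(all(fx$counts >= 0))
  expect_identical(fx$counts, makeCountsFixture(nGenes = 200,
                                                lengths = rep(1000, 200),
                                                sizeFactors = c(1, 2),
                                                seed = 9)$counts)
  # doubling the size factor doubles expected counts (Poisson means)
  ratio <- sum(fx$counts[, 2]) / sum(fx$counts[, 1])
  expect_lt(abs(ratio - 2), 0.15)
  expect_error(makeCountsFixture(lengths = c(-1, rep(1000, 49))),
               "positive")
})
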