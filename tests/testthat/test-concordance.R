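mkRecord <- function(k_deg = 2e-4, K_D = 0.1, tau = 600, nc = 0.1,
                     ns = 0.1) {
  data.frame(model_name = "simple", k_deg = k_deg, K_D = K_D, tau = tau,
             nrmsd_ctrl = nc, nrmsd_si = ns)
}

test_that("pairing is the full Cartesian product", {
  r1 <- do.call(rbind, replicate(100, mkRecord(), simplify = FALSE))
  r2 <- do.call(rbind, replicate(100, mkRecord(), simplify = FALSE))
  expect_identical(nrow(pairAll(r1, r2)), 10000L)
  expect_identical(nrow(pairAll(r1[1, ], r2[1, ])), 1L)
  expect_identical(nrow(pairAll(r1[1:3, ], r2[1:4, ])), 12L)
  expect_error(pairAll(r1[0, ], r2), "empty")
})

test_that("pair scores follow the ratio-difference-nRMSD rule", {
  a <- mkRecord(k_deg = 2e-4, tau = 500)
  b <- mkRecord(k_deg = 8e-4, tau = 620)
  sc <- scorePair(a, b, c("k_deg", "K_D"))
  expect_equal(unname(sc$ratios[["k_deg"]]), 4)
  expect_equal(unname(sc$ratios[["K_D"]]), 1)
  expect_equal(sc$tauScore, 120)
  expect_equal(sc$nrmsdScore, 0.4)
  expect_equal(sc$total, sum(sc$ratios) + sc$tauScore + sc$nrmsdScore)
  # symmetry
  sc2 <- scorePair(b, a, c("k_deg", "K_D"))
  expect_equal(sc$total, sc2$total)
  # identical records: ratios exactly 1, tau score 0
  self <- scorePair(a, a, c("k_deg", "K_D"))
  expect_true(all(self$ratios == 1))
  expect_equal(self$tauScore, 0)
  bad <- mkRecord()
  bad$model_name <- "iffl"
  expect_error(scorePair(a, bad, "k_deg"), "model mismatch")
  neg <- mkRecord(k_deg = -1)
  expect_error(scorePair(neg, b, "k_deg"), "non-positive")
})

test_that("scored parameters depend on model and gene class", {
  expect_setequal(scoredParamsFor("simple"), c("k_deg", "K_D"))
  expect_setequal(scoredParamsFor("iffl"), c("k_deg", "K_D1", "K_D2"))
  expect_setequal(scoredParamsFor("cycle3", "ERG_sub2"),
                  c("k_1", "k_2", "k_deg"))
  expect_setequal(scoredParamsFor("v4", "ERG_sub2"),
                  c("k_1", "k_2", "k_deg"))
  expect_setequal(scoredParamsFor("v4", "DRG_sub2"),
                  c("k_deg", "k_1", "k_2", "K_D1", "K_D2", "K_DTF2"))
  expect_setequal(scoredParamsFor("cycle3", "IRG_sub2"),
                  c("k_1", "k_2", "k_deg", "K_D1", "K_D2"))
  expect_error(scoredParamsFor("simple", "nope"))
})

test_that("concordant selection minimizes the total with stable ties", {
  r1 <- rbind(mkRecord(k_deg = 2e-4, tau = 100, nc = 0.2, ns = 0.2),
              mkRecord(k_deg = 4e-4, tau = 500, nc = 0.05, ns = 0.05),
              mkRecord(k_deg = 1e-3, tau = 3000, nc = 0.4, ns = 0.3))
  r2 <- rbind(mkRecord(k_deg = 4.2e-4, tau = 510, nc = 0.06, ns = 0.04),
              mkRecord(k_deg = 2e-4, tau = 2000, nc = 0.2, ns = 0.2))
  sel <- selectConcordant(r1, r2, c("k_deg", "K_D"))
  # the near-identical good pair (row 2, row 1) wins
  expect_identical(c(sel$i, sel$j), c(2L, 1L))
  expect_equal(sel$score$total,
               scorePair(r1[2, ], r2[1, ], c("k_deg", "K_D"))$total)
  # a self-pair of identical replicates beats any non-identical pair
  # with equal nRMSDs
  same <- mkRecord(nc = 0.1, ns = 0.1)
  other <- mkRecord(k_deg = 3e-4, tau = 601, nc = 0.1, ns = 0.1)
  sel2 <- selectConcordant(rbind(same, other), rbind(same, other),
                           c("k_deg", "K_D"))
  expect_identical(c(sel2$i, sel2$j), c(1L, 1L))
  # exact tie: lower index wins
  r <- rbind(mkRecord(), mkRecord())
  sel3 <- selectConcordant(r, r, c("k_deg", "K_D"))
  expect_identical(c(sel3$i, sel3$j), c(1L, 1L))
})

test_that("adding a strictly worse record never changes the selection", {
  set.seed(8)
  r1 <- do.call(rbind, lapply(1:5, function(i)
    mkRecord(k_deg = exp(runif(1, log(2e-5), log(2e-3))),
             tau = runif(1, 0, 7200), nc = runif(1, 0, 0.4),
             ns = runif(1, 0, 0.4))))
  r2 <- do.call(rbind, lapply(1:5, function(i)
    mkRecord(k_deg = exp(runif(1, log(2e-5), log(2e-3))),
             tau = runif(1, 0, 7200), nc = runif(1, 0, 0.4),
             ns = runif(1, 0, 0.4))))
  base <- selectConcordant(r1, r2, c("k_deg", "K_D"))
  # a record dominated by the selected one: identical parameters but
  # strictly worse fit quality
  worse <- r1[base$i, ]
  worse$nrmsd_ctrl <- worse$nrmsd_ctrl + 1
  worse$nrmsd_si <- worse$nrmsd_si + 1
  withWorse <- selectConcordant(rbind(r1, worse), r2, c("k_deg", "K_D"))
  expect_identical(c(base$i, base$j), c(withWorse$i, withWorse$j))
})
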