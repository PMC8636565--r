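# Shared fixtures: prepared once per test run.

defaultEvalTimes <- seq(0, 180, by = 15)

# standard synthetic inputs (both replicates)
stdInputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthInputs()
    cache
  }
})

stdGrids <- function() {
  inp <- stdInputs()
  list(rep1 = inp$rep1, rep2 = inp$rep2)
}

# a constant input grid at the given level
constGrid <- function(level, tStartS = -14400, tEndS = 10800) {
  nfkbInputGrid(rep(level, tEndS - tStartS + 1), tStartS, tEndS)
}

# representative in-bounds parameter sets for each model
exampleFree <- function(model) {
  switch(model,
    simple = c(k_deg = 5e-4, K_D = 0.1, tau = 600),
    iffl = c(k_deg = 1e-3, K_D1 = 30, K_D2 = 3e-3, tau = 900),
    cycle3 = c(k_1 = 1e-4, k_2 = 0.03, k_deg = 1.2e-3, K_D1 = 10,
               K_D2 = 2e-3, tau = 900),
    v4 = c(k_deg = 1.2e-3, k_1 = 1e-4, k_2 = 0.03, K_D1 = 10,
           K_D2 = 2e-3, K_DTF2 = 5e-3, tau = 900))
}

exampleParams <- function(model) grmParamSet(model, exampleFree(model))

# one-gene zero-noise dataset generated from a given model
oneGeneData <- function(model, free = exampleFree(model), seed = 7L) {
  grids <- stdGrids()
  genes <- list(list(gene_id = "g", model_name = model,
                     params = grmParamSet(model, free), noise_cv = 0,
                     seed = seed))
  tbl <- makeGeneTable(genes, grids)
  list(tbl = tbl, grids = grids,
       fc = list(rep1 = geneFoldChange(tbl, "g", 1),
                 rep2 = geneFoldChange(tbl, "g", 2)))
}
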