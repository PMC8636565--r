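# Synthetic-data generator: NFkB input trajectories with the qualitative
# features of the measured data (control: dominant first peak near 30 min,
# trough near 75 min, dampened second peak near 120 min; siIkBa: slower
# rise to a prolonged plateau at a lower fold change; replicate 2
# consistently lower in amplitude), and per-gene expression tables
# simulated from the four transcription models with known ground truth.

#' Shape parameters of the synthetic nuclear-NFkB trajectories
#'
#' The control trajectory is a sum of two log-normal pulse kernels
#' (a dominant first peak and a dampened second peak separated by a
#' trough); the siIkBa trajectory is a saturating rise to a plateau.
#' Replicate 2 is replicate 1 with the amplitude above baseline scaled
#' by \code{replicateScale}.
#'
#' @param peak1Time,peak1Height time (min) and height (fold units) of the
#'   dominant control peak.
#' @param troughTime time (min) of the control trough between the peaks.
#' @param peak2Time,peak2Height time and height of the dampened second
#'   control peak.
#' @param siRiseTime half-rise time (min) of the siIkBa saturating rise.
#' @param siPlateau siIkBa plateau height (fold units), above baseline but
#'   below the control first peak.
#' @param replicateScale amplitude multiplier for replicate 2 (0-1).
#' @param rep2TimeShift minutes added to the pulse centers and the
#'   siIkBa half-rise time in replicate 2 (biological replicates differ
#'   in timing as well as amplitude; with a pure amplitude change the
#'   prepared replicate inputs would be identical, because the anchored
#'   rescaling exactly undoes an amplitude scaling).
#' @param rep2WidthScale multiplier on the pulse widths in replicate 2.
#' @param baseline pre-stimulus fold change (1 before rescaling).
#' @param pulse1Width,pulse2Width log-normal widths of the two control
#'   pulses (log-time units).
#' @return a validated list of class \code{NfkbShapeParams}.
#' @export
nfkbShapeParams <- function(peak1Time = 30, peak1Height = 8, troughTime = 75,
                            peak2Time = 120, peak2Height = 4.5,
                            siRiseTime = 60, siPlateau = 4,
                            replicateScale = 0.7, baseline = 1,
                            pulse1Width = 0.4, pulse2Width = 0.42,
                            rep2TimeShift = 5, rep2WidthScale = 1.1) {
  shape <- list(peak1Time = peak1Time, peak1Height = peak1Height,
                troughTime = troughTime, peak2Time = peak2Time,
                peak2Height = peak2Height, siRiseTime = siRiseTime,
                siPlateau = siPlateau, replicateScale = replicateScale,
                baseline = baseline, pulse1Width = pulse1Width,
                pulse2Width = pulse2Width, rep2TimeShift = rep2TimeShift,
                rep2WidthScale = rep2WidthScale)
  if (!(peak1Time < troughTime && troughTime < peak2Time))
    stop("require peak1Time < troughTime < peak2Time")
  if (!(peak1Height > peak2Height && peak2Height > baseline))
    stop("require peak1Height > peak2Height > baseline")
  if (siPlateau <= baseline) stop("siPlateau must exceed baseline")
  if (replicateScale <= 0) stop("replicateScale must be positive")
  class(shape) <- "NfkbShapeParams"
  shape
}

# log-normal pulse kernel: 1 at t = center, 0 at t = 0, smooth and positive
lognormPulse <- function(t, center, width) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log(t[pos] / center))^2 / (2 * width^2))
  out
}

#' Generate a synthetic nuclear-NFkB time course
#'
#' @param shape an \code{\link{nfkbShapeParams}} object.
#' @param condition \code{"ctrl"} (two-pulse shape) or \code{"siIkBa"}
#'   (saturating rise).
#' @param times sampling times in minutes, ascending from 0, covering at
#'   least 0-180 (default every 15 min).
#' @param replicate 1, or 2 for the amplitude-scaled replicate.
#' @param noiseCv multiplicative log-normal noise CV (default 0:
#'   deterministic shapes).
#' @param seed RNG seed used when \code{noiseCv > 0}.
#' @return an \linkS4class{NfkbTimeCourse}.
#' @examples
#' makeNfkbTimeCourse(nfkbShapeParams(), "ctrl")
#' @export
makeNfkbTimeCourse <- function(shape, condition = c("ctrl", "siIkBa"),
                               times = seq(0, 180, by = 15), replicate = 1L,
                               noiseCv = 0, seed = 1L) {
  stopifnot(inherits(shape, "NfkbShapeParams"))
  condition <- match.arg(condition)
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  if (times[1] != 0) stop("times must start at 0")
  if (max(times) < 180) stop("times must cover at least 0-180 min")
  b <- shape$baseline
  # replicate 2 differs in timing and width as well as amplitude
  shift <- if (replicate == 2) shape$rep2TimeShift else 0
  wscale <- if (replicate == 2) shape$rep2WidthScale else 1
  v <- if (condition == "ctrl") {
    b +
      (shape$peak1Height - b) * lognormPulse(times, shape$peak1Time + shift,
                                             shape$pulse1Width * wscale) +
      (shape$peak2Height - b) * lognormPulse(times, shape$peak2Time + shift,
                                             shape$pulse2Width * wscale)
  } else {
    z <- (times / (shape$siRiseTime + shift))^2
    b + (shape$siPlateau - b) * z / (z + 1)
  }
  if (replicate == 2) v <- b + shape$replicateScale * (v - b)
  if (noiseCv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noiseCv^2))
    noise <- exp(rnorm(length(v), -sdlog^2 / 2, sdlog))
    noise[times == 0] <- 1  # t = 0 stays at baseline
    v <- b + (v - b) * noise
  }
  nfkbTimeCourse(times, v, condition, replicate)
}

#' Draw ground-truth genes for a synthetic cohort
#'
#' True parameters are drawn from sub-ranges of each model's global
#' bounds chosen so that each mechanism displays its signature dynamic on
#' the standard input (monotone induction for the simple model, reduced
#' siIkBa induction for the IFFL, post-induction repression for the
#' promoter-cycle models).  True delays are drawn between 10 and 45
#' minutes: shorter delays are not identifiable from expression sampled
#' every 15 minutes.
#'
#' @param n number of genes.
#' @param models model names to cycle through (default all four).
#' @param noiseCv measurement noise CV stored with each gene (default 0).
#' @param seed RNG seed.
#' @return a list of ground-truth genes, each a list with \code{gene_id},
#'   \code{model_name}, \code{params} (a \linkS4class{GrmParamSet}),
#'   \code{noise_cv} and \code{seed}.
#' @export
makeGroundTruthGenes <- function(n, models = grmModelNames(), noiseCv = 0,
                                 seed = 1L) {
  set.seed(seed)
  models <- rep(models, length.out = n)
  geneSeeds <- sample.int(.Machine$integer.max - 1L, n)
  logU <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  lapply(seq_len(n), function(i) {
    model <- models[i]
    # sub-ranges chosen (once, by forward simulation on the standard
    # input) so each mechanism shows its signature: simple -- monotone
    # tracking induction; iffl -- partially saturated sharp response,
    # reduced in siIkBa; cycle3/v4 -- the open-promoter pool charged
    # before stimulation (slow closed->open recharge k_1, baseline
    # open->active flux below the recharge) discharges through the
    # active state on stimulation, giving post-induction repression
    free <- switch(model,
      simple = c(k_deg = logU(3e-4, 1.8e-3), K_D = logU(0.02, 0.2),
                 tau = runif(1, 600, 2700)),
      iffl = c(k_deg = logU(8e-4, 1.8e-3), K_D1 = logU(8, 40),
               K_D2 = logU(1.2e-3, 4e-3), tau = runif(1, 600, 2700)),
      cycle3 = c(k_1 = logU(1e-4, 2e-4), k_2 = logU(0.06, 0.15),
                 k_deg = logU(8e-4, 1.8e-3), K_D1 = logU(1, 4),
                 K_D2 = logU(3e-3, 6e-3), tau = runif(1, 600, 2700)),
      v4 = c(k_deg = logU(8e-4, 1.8e-3), k_1 = logU(1e-4, 2e-4),
             k_2 = logU(0.06, 0.15), K_D1 = logU(1, 4),
             K_D2 = logU(3e-3, 6e-3), K_DTF2 = logU(1.5e-3, 1.5e-2),
             tau = runif(1, 600, 2700)))
    list(gene_id = sprintf("g%03d_%s", i, model), model_name = model,
         params = grmParamSet(model, free), noise_cv = noiseCv,
         seed = geneSeeds[i])
  })
}

#' Simulate a per-gene expression table from ground-truth genes
#'
#' For each gene, condition and replicate, the true model is simulated on
#' the replicate's input grids and sampled at \code{sampleTimes};
#' multiplicative log-normal noise with the gene's CV (mean 1) is then
#' applied.  With \code{noise_cv = 0} the table equals the noiseless
#' simulation.
#'
#' @param genes list from \code{\link{makeGroundTruthGenes}}.
#' @param inputs per-replicate input grids:
#'   \code{list(rep1 = list(ctrl =, si =), rep2 = ...)}; a single
#'   \code{list(ctrl =, si =)} pair is treated as one replicate.
#' @param sampleTimes sampling times in minutes (default 0-180 every 15).
#' @return a numeric matrix, genes x (condition, replicate, time) columns
#'   named \code{<condition>_rep<k>_t<min>}, with the ground truth
#'   attached as attribute \code{"truth"}.
#' @export
makeGeneTable <- function(genes, inputs, sampleTimes = seq(0, 180, by = 15)) {
  if (!is.null(inputs$ctrl)) inputs <- list(rep1 = inputs)
  reps <- names(inputs)
  cols <- unlist(lapply(c("ctrl", "si"), function(cond)
    lapply(seq_along(reps), function(k)
      sprintf("%s_rep%d_t%d",
              if (cond == "ctrl") "ctrl" else "siIkBa", k, sampleTimes))))
  tbl <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(vapply(genes, `[[`, "", "gene_id"), cols))
  for (g in seq_along(genes)) {
    gene <- genes[[g]]
    set.seed(gene$seed)
    sdlog <- if (gene$noise_cv > 0) sqrt(log(1 + gene$noise_cv^2)) else 0
    for (cond in c("ctrl", "si")) {
      condName <- if (cond == "ctrl") "ctrl" else "siIkBa"
      for (k in seq_along(reps)) {
        sim <- simulateGrm(gene$params, inputs[[k]][[cond]],
                           evalTimes = sampleTimes)
        v <- mrnaValues(sim)
        if (sdlog > 0)
          v <- v * exp(rnorm(length(v), -sdlog^2 / 2, sdlog))
        tbl[g, sprintf("%s_rep%d_t%d", condName, k, sampleTimes)] <- v
      }
    }
  }
  attr(tbl, "truth") <- genes
  tbl
}

#' Extract one gene's fold-change series from an expression table
#'
#' @param tbl matrix from \code{\link{makeGeneTable}} (or read from disk).
#' @param geneId row name.
#' @param replicate replicate index.
#' @param sampleTimes the sampling times encoded in the column names.
#' @return list with fold-change vectors \code{ctrl} and \code{si}.
#' @export
geneFoldChange <- function(tbl, geneId, replicate,
                           sampleTimes = seq(0, 180, by = 15)) {
  get1 <- function(cond) {
    v <- tbl[geneId, sprintf("%s_rep%d_t%d", cond, replicate, sampleTimes)]
    if (v[1] <= 0) stop("expression at t = 0 must be positive")
    unname(v / v[1])
  }
  list(ctrl = get1("ctrl"), si = get1("siIkBa"))
}

#' Counts fixture with known per-sample scaling
#'
#' Poisson counts with expectation
#' \code{mu_g * (length_g / 1000) * sizeFactor_s}, so the per-kilobase,
#' size-normalized expression recovers \code{mu_g} in expectation.  Used
#' to verify \code{\link{normalizeCounts}} against ground truth.
#'
#' @param nGenes number of genes.
#' @param lengths transcript lengths in bp (positive; default drawn
#'   500-5000).
#' @param sizeFactors per-sample scaling (positive).
#' @param seed RNG seed.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{lengths}, \code{sizeFactors} and the expression means
#'   \code{mu}.
#' @export
makeCountsFixture <- function(nGenes = 50, lengths = NULL,
                              sizeFactors = c(1, 1, 1), seed = 1L) {
  set.seed(seed)
  if (is.null(lengths))
    lengths <- sample(500:5000, nGenes, replace = TRUE)
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  mu <- exp(runif(nGenes, log(50), log(2000)))
  lambda <- outer(mu * lengths / 1000, sizeFactors)
  counts <- matrix(rpois(length(lambda), lambda), nrow = nGenes,
                   dimnames = list(sprintf("gene%03d", seq_len(nGenes)),
                                   sprintf("sample%d",
                                           seq_along(sizeFactors))))
  list(counts = counts, lengths = lengths, sizeFactors = sizeFactors,
       mu = mu)
}
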