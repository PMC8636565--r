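# Cross-replicate concordance: score all pairs of optimized parameter
# sets from replicates 1 and 2 and select the most concordant pair.
#
# Score components: for each scored
# rate / affinity parameter the larger value divided by the smaller
# (>= 1); for tau the absolute difference in seconds; plus the sum of the
# two records' fit nRMSDs.  The components are summed unweighted (an
# optional weight on the tau term is exposed because seconds can dominate
# the dimensionless terms).

#' All cross-replicate pairs of fit records
#'
#' @param rep1,rep2 stage-2 fit data.frames for replicates 1 and 2.
#' @return data.frame of index pairs (\code{i}, \code{j}), the full
#'   Cartesian product (\code{nrow(rep1) * nrow(rep2)} rows).
#' @export
pairAll <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) stop("empty record list")
  expand.grid(i = seq_len(nrow(rep1)), j = seq_len(nrow(rep2)),
              KEEP.OUT.ATTRS = FALSE)
}

# nRMSD contribution of one record: its own replicate's fit quality in
# both conditions
recordNrmsd <- function(rec) rec$nrmsd_ctrl + rec$nrmsd_si

#' Concordance score of one cross-replicate pair
#'
#' @param a,b single-row fit records (same model) from replicates 1
#'   and 2.
#' @param scoredParams names of the rate / affinity parameters to score
#'   (see \code{\link{scoredParamsFor}}); tau and nRMSD are always
#'   scored.
#' @param tauWeight weight on the tau term (default 1, the plain
#'   unweighted sum).
#' @return list with \code{ratios} (named, each >= 1), \code{tauScore}
#'   (seconds), \code{nrmsdScore} and \code{total}.
#' @export
scorePair <- function(a, b, scoredParams, tauWeight = 1) {
  if (!identical(a$model_name, b$model_name)) stop("model mismatch")
  ratios <- vapply(scoredParams, function(nm) {
    va <- a[[nm]]; vb <- b[[nm]]
    if (va <= 0 || vb <= 0) stop(sprintf("non-positive parameter %s", nm))
    max(va, vb) / min(va, vb)
  }, numeric(1))
  tauScore <- abs(a$tau - b$tau)
  nrmsdScore <- recordNrmsd(a) + recordNrmsd(b)
  list(ratios = ratios, tauScore = tauScore, nrmsdScore = nrmsdScore,
       total = sum(ratios) + tauWeight * tauScore + nrmsdScore)
}

#' Which parameters enter the concordance score
#'
#' The simple and IFFL models score all their free rate / affinity
#' parameters.  For the promoter-cycle models fitted to early-response
#' genes of subcluster 2 only k_1, k_2 and k_deg are scored; for other
#' gene classes all free rate / affinity parameters are scored.  tau and
#' the nRMSD sum are always part of the score.
#'
#' @param model model name.
#' @param geneClass \code{"ERG_sub2"}, \code{"IRG_sub2"},
#'   \code{"DRG_sub2"} or \code{"other"}.
#' @return character vector of scored parameter names (excluding tau).
#' @export
scoredParamsFor <- function(model,
                            geneClass = c("other", "ERG_sub2", "IRG_sub2",
                                          "DRG_sub2")) {
  geneClass <- match.arg(geneClass)
  def <- grmModelDef(model)
  all <- setdiff(def$free, "tau")
  if (model %in% c("cycle3", "v4") && geneClass == "ERG_sub2")
    return(c("k_1", "k_2", "k_deg"))
  all
}

#' Select the concordant cross-replicate pair
#'
#' Scores every pair (vectorized over the full Cartesian product) and
#' returns the pair with the smallest total; ties are broken by the
#' smaller nRMSD score, then by the lower pair index.
#'
#' @param rep1,rep2 stage-2 fit data.frames.
#' @param scoredParams from \code{\link{scoredParamsFor}}.
#' @param tauWeight weight on the tau term (default 1).
#' @return list with indices \code{i}, \code{j}, the records
#'   \code{rep1}, \code{rep2}, and the \code{score} breakdown.
#' @export
selectConcordant <- function(rep1, rep2, scoredParams, tauWeight = 1) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) stop("empty record list")
  total <- matrix(0, nrow(rep1), nrow(rep2))
  for (nm in scoredParams) {
    la <- log(rep1[[nm]]); lb <- log(rep2[[nm]])
    if (any(!is.finite(la)) || any(!is.finite(lb)))
      stop(sprintf("non-positive parameter %s", nm))
    total <- total + exp(abs(outer(la, lb, `-`)))
  }
  total <- total + tauWeight * abs(outer(rep1$tau, rep2$tau, `-`))
  nr <- outer(recordNrmsd(rep1), recordNrmsd(rep2), `+`)
  total <- total + nr
  best <- which(total == min(total))
  if (length(best) > 1) {
    best <- best[order(nr[best], best)][1]
  }
  ij <- arrayInd(best, dim(total))
  i <- ij[1]; j <- ij[2]
  list(i = i, j = j, rep1 = rep1[i, , drop = FALSE],
       rep2 = rep2[j, , drop = FALSE],
       score = scorePair(rep1[i, , drop = FALSE], rep2[j, , drop = FALSE],
                         scoredParams, tauWeight))
}
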