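# Good-fit and best-fit classification.
#
# A (gene, model) pair is a good fit when the concordant pair's control
# nRMSD is < 0.5 in BOTH replicates, its siIkBa nRMSD is < 0.39 in BOTH
# replicates (strict inequalities), and the fitted
# simulations show the induction relation observed in the data:
# control > siIkBa in at least one of MFI or AUC.  Among a gene's
# good-fit models the one with the smallest total nRMSD (the sum of the
# four components: ctrl/siIkBa x replicate 1/2) is the best fit; a gene
# with no good-fit model is "unexplained".

#' Good-fit classification of one concordant pair
#'
#' @param pair result of \code{\link{selectConcordant}} (finalized
#'   records from both replicates).
#' @param ctrlThreshold control nRMSD threshold (default 0.5).
#' @param siThreshold siIkBa nRMSD threshold (default 0.39).
#' @param mfiAucFrom which replicate's fitted simulation supplies the
#'   MFI / AUC relation test: \code{"rep1"} (default) or \code{"both"}
#'   (require the relation in each replicate).
#' @return list with logical \code{good} and character \code{reasons}
#'   (failed conditions; empty when good).
#' @export
classifyGoodFit <- function(pair, ctrlThreshold = 0.5, siThreshold = 0.39,
                            mfiAucFrom = c("rep1", "both")) {
  mfiAucFrom <- match.arg(mfiAucFrom)
  reasons <- character()
  for (k in 1:2) {
    rec <- pair[[paste0("rep", k)]]
    if (is.null(rec$nrmsd_ctrl) || is.null(rec$nrmsd_si) ||
        is.null(rec$mfi_ctrl) || is.null(rec$auc_ctrl))
      stop("pair records are missing nRMSD or MFI/AUC summaries")
    if (!(rec$nrmsd_ctrl < ctrlThreshold))
      reasons <- c(reasons, sprintf("ctrl rep%d nRMSD", k))
    if (!(rec$nrmsd_si < siThreshold))
      reasons <- c(reasons, sprintf("siIkBa rep%d nRMSD", k))
  }
  relOk <- function(rec) rec$mfi_ctrl > rec$mfi_si || rec$auc_ctrl > rec$auc_si
  ok <- if (mfiAucFrom == "rep1") relOk(pair$rep1)
        else relOk(pair$rep1) && relOk(pair$rep2)
  if (!ok) reasons <- c(reasons, "induction relation")
  list(good = length(reasons) == 0, reasons = reasons)
}

#' Total nRMSD of a concordant pair
#'
#' Sum of the four components: control and siIkBa nRMSD in replicates 1
#' and 2.
#'
#' @param pair result of \code{\link{selectConcordant}}.
#' @return the total nRMSD.
#' @export
totalNrmsd <- function(pair) {
  pair$rep1$nrmsd_ctrl + pair$rep1$nrmsd_si +
    pair$rep2$nrmsd_ctrl + pair$rep2$nrmsd_si
}

#' Best-fit model call for one gene
#'
#' @param geneId gene identifier.
#' @param modelResults named list (one element per model) of
#'   \code{list(pair =, good =, reasons =)} as produced by the pipeline.
#' @return one-row data.frame: \code{gene_id}, \code{best_fit} (model
#'   name or \code{"unexplained"}), and per-model \code{good_<model>} /
#'   \code{total_nrmsd_<model>} columns.
#' @export
pickBestModel <- function(geneId, modelResults) {
  models <- names(modelResults)
  good <- vapply(modelResults, function(x) isTRUE(x$good), logical(1))
  totals <- vapply(modelResults, function(x) totalNrmsd(x$pair), numeric(1))
  best <- if (any(good)) {
    cand <- models[good]
    cand[which.min(totals[good])]
  } else "unexplained"
  out <- data.frame(gene_id = geneId, best_fit = best,
                    stringsAsFactors = FALSE)
  for (m in models) {
    out[[paste0("good_", m)]] <- good[[m]]
    out[[paste0("total_nrmsd_", m)]] <- totals[[m]]
  }
  out
}
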