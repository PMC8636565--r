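# File formats and count normalization.
#
# Time courses travel as CSV (time_min, condition, replicate, value);
# expression tables as TSV (rows = genes, columns <condition>_rep<k>_t<min>);
# fit records as JSON-lines; decisions as TSV; configuration as YAML.

#' TPM normalization of raw counts (length, library size, RLE factor)
#'
#' Counts are first length-normalized to reads per 1000 bp,
#' \eqn{X_t = R_t / L_t \cdot 10^3}, then scaled by the library size
#' \eqn{S_t} and the RLE (relative log expression, median-of-ratios)
#' normalization factor \eqn{N_t}:
#' \eqn{TPM_t = X_t / (S_t N_t) \cdot 10^6}.  When size factors are not
#' supplied, \eqn{N_t} is estimated with
#' \code{edgeR::calcNormFactors(method = "RLE")} (median ratio to the
#' geometric-mean reference over genes with all-positive counts) and
#' \eqn{S_t} is the column sum.
#'
#' @param counts genes x samples matrix of raw mapped read counts.
#' @param lengths transcript lengths in bp (positive, one per gene).
#' @param sizeFactors optional per-sample \eqn{S_t N_t} products; when
#'   supplied they are used as-is (for bit-exact replication of external
#'   factors).
#' @return TPM matrix with attributes \code{librarySizes} and
#'   \code{normFactors} when estimated.
#' @export
normalizeCounts <- function(counts, lengths, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("one length per gene required")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  X <- counts / lengths * 1e3
  if (is.null(sizeFactors)) {
    if (!any(rowSums(counts > 0) == ncol(counts)))
      stop("cannot estimate size factors: no gene has all-positive counts")
    S <- colSums(counts)
    N <- edgeR::calcNormFactors(counts, method = "RLE")
    tpm <- sweep(X, 2, S * N, "/") * 1e6
    attr(tpm, "librarySizes") <- S
    attr(tpm, "normFactors") <- N
  } else {
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    tpm <- sweep(X, 2, sizeFactors, "/") * 1e6
  }
  tpm
}

#' Read time courses from CSV
#'
#' Expects columns \code{time_min}, \code{condition}, \code{replicate},
#' \code{value}; returns one \linkS4class{NfkbTimeCourse} per
#' (condition, replicate) combination.
#'
#' @param path CSV file.
#' @return named list of \linkS4class{NfkbTimeCourse} objects, names
#'   \code{<condition>_rep<k>}.
#' @export
readTimeCourse <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_min", "condition", "replicate", "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!is.numeric(df$time_min) || !is.numeric(df$value))
    stop("time_min and value must be numeric")
  if (any(df$time_min < 0)) stop("negative times are not allowed")
  out <- list()
  for (cond in unique(df$condition)) {
    for (k in unique(df$replicate[df$condition == cond])) {
      sub <- df[df$condition == cond & df$replicate == k, ]
      sub <- sub[order(sub$time_min), ]
      out[[sprintf("%s_rep%d", cond, k)]] <-
        nfkbTimeCourse(sub$time_min, sub$value, cond, k)
    }
  }
  out
}

#' Write time courses to CSV
#'
#' @param path output CSV file.
#' @param tcs a single \linkS4class{NfkbTimeCourse} or a list of them.
#' @export
writeTimeCourse <- function(path, tcs) {
  if (is(tcs, "NfkbTimeCourse")) tcs <- list(tcs)
  df <- do.call(rbind, lapply(tcs, function(tc)
    data.frame(time_min = tc@times, condition = tc@condition,
               replicate = tc@replicate, value = tc@values)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an expression table (TSV, genes x columns)
#'
#' @param path TSV file.
#' @param tbl matrix from \code{\link{makeGeneTable}}.
#' @export
writeExpressionTable <- function(path, tbl) {
  df <- data.frame(gene_id = rownames(tbl), tbl, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("missing required column: gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Write / read fit records as JSON-lines
#'
#' One JSON object per line, one line per optimization record.
#'
#' @param path output file.
#' @param records fit data.frame.
#' @export
writeFitRecords <- function(path, records) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname writeFitRecords
#' @export
readFitRecords <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

#' Write gene decisions to TSV
#'
#' @param path output file.
#' @param decisions decision data.frame from the pipeline.
#' @export
writeDecisions <- function(path, decisions) {
  write.table(decisions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.configKeys <- c("n_starts", "seed", "thresholds", "ctrl_threshold",
                 "si_threshold", "tau_weight", "noise_cv", "basal",
                 "rescale_lo", "rescale_hi", "gene_class", "models",
                 "n_genes", "rel_tol", "max_eval")

#' Default pipeline configuration
#'
#' @return named list of the recognized configuration values.
#' @export
defaultConfig <- function() {
  list(n_starts = 100, seed = 1, thresholds = c(0.5, 0.6, 0.7),
       ctrl_threshold = 0.5, si_threshold = 0.39, tau_weight = 1,
       noise_cv = 0.1, basal = 0, rescale_lo = 2, rescale_hi = 100,
       gene_class = "ERG_sub2", models = grmModelNames(), n_genes = 20,
       rel_tol = 1e-4, max_eval = 1200)
}

#' Load a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' \code{\link{defaultConfig}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  out <- defaultConfig()
  out[names(cfg)] <- cfg
  out
}
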