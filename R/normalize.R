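#' Normalize a count matrix
#'
#' Counts-per-million divides each sample by its library size (in
#' millions); RPKM additionally divides by gene length in kilobases. The
#' raw counts are retained alongside the normalized matrix so the
#' count-model methods (AR(1), HMM emissions, static tests) can keep
#' operating on integers.
#'
#' @param exp a \code{\link{tse}} object holding raw counts.
#' @param method one of \code{"none"}, \code{"cpm"}, \code{"rpkm"}.
#' @param gene_lengths named numeric vector of gene lengths in bases,
#'   required for RPKM.
#' @return A \code{tse} with the normalized matrix, the method recorded,
#'   and raw counts kept in \code{$raw_counts}.
#' @export
normalize_experiment <- function(exp, method = c("none", "cpm", "rpkm"),
                                 gene_lengths = NULL) {
  stopifnot(inherits(exp, "tse"))
  method <- match.arg(method)
  if (method == "none") return(exp)
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  scaled <- sweep(raw, 2L, exp$lib_sizes / 1e6, "/")
  if (method == "rpkm") {
    if (is.null(gene_lengths))
      stop("rpkm normalization requires gene_lengths")
    len <- gene_lengths[rownames(raw)]
    if (anyNA(len))
      stop("gene_lengths missing for: ",
           paste(head(rownames(raw)[is.na(len)]), collapse = ", "))
    scaled <- scaled / (len / 1e3)
  }
  tse(scaled, time = exp$samples$time, condition = exp$samples$condition,
      replicate = exp$samples$replicate, lib_sizes = exp$lib_sizes,
      normalized = TRUE, norm_method = method, raw_counts = raw)
}

#' Filter genes by total count and coefficient of variation
#'
#' Genes whose total count falls below \code{min_total_count}, or whose
#' coefficient of variation (sd/mean across all samples, computed on the
#' normalized matrix when present) falls below \code{cv_threshold}, are
#' removed. Low-CV genes are near-constant and carry no temporal signal,
#' so they are uninformative for TDE testing.
#'
#' @param exp a \code{\link{tse}} object.
#' @param min_total_count minimum summed count for a gene to survive.
#' @param cv_threshold minimum CV; \code{NULL} disables the CV filter.
#' @return The surviving subset as a \code{tse}; the number removed by
#'   each criterion is attached as attribute \code{"filter_log"}. The
#'   operation is idempotent.
#' @export
filter_genes <- function(exp, min_total_count = 1, cv_threshold = NULL) {
  stopifnot(inherits(exp, "tse"),
            min_total_count >= 0,
            is.null(cv_threshold) || cv_threshold >= 0)
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  keep_total <- rowSums(raw) >= min_total_count
  keep_cv <- rep(TRUE, nrow(exp$counts))
  if (!is.null(cv_threshold)) {
    mu <- rowMeans(exp$counts)
    s <- apply(exp$counts, 1L, sd)
    cv <- ifelse(mu > 0, s / mu, 0)
    keep_cv <- cv >= cv_threshold
  }
  keep <- keep_total & keep_cv
  if (!any(keep))
    warning("all genes removed by filtering")
  out <- exp[keep, ]
  attr(out, "filter_log") <- c(removed_total = sum(!keep_total),
                               removed_cv = sum(keep_total & !keep_cv),
                               kept = sum(keep))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; the default multiple-testing
#' correction for every per-gene test table in the package.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, order-preserving and each at least its raw p.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues))
    stop("p-values contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
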