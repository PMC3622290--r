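#' Construct a time-series expression experiment
#'
#' Bundles a genes x samples matrix of read counts with per-sample
#' annotation (time point, biological condition, replicate index) and
#' library sizes. This is the container every method in the package
#' consumes: counts are indexed as \eqn{y_{ijcl}} for gene i, time j,
#' condition c and replicate l.
#'
#' Samples are reordered by (condition, time, replicate) on construction.
#' Times may be arbitrary numeric labels (e.g. days 7, 11, 14, 21) and are
#' used as real coordinates by the spline-based methods.
#'
#' @param counts numeric matrix, genes x samples, non-negative; integer
#'   unless \code{normalized = TRUE}. Row names are gene ids (generated if
#'   absent), column names are sample names.
#' @param time numeric vector of time labels, one per sample.
#' @param condition vector of condition labels, one per sample.
#' @param replicate vector of replicate indices, one per sample.
#' @param lib_sizes positive totals per sample; defaults to column sums of
#'   \code{counts} (or of \code{raw_counts} when supplied).
#' @param normalized logical; set when \code{counts} already holds
#'   normalized expression values rather than raw counts.
#' @param norm_method name of the normalization applied, if any.
#' @param raw_counts optional raw count matrix retained alongside a
#'   normalized matrix, for the count-model methods.
#' @return An object of class \code{"tse"}.
#' @examples
#' counts <- matrix(rpois(20, 10), 2, 10,
#'                  dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
#' exp <- tse(counts, time = rep(1:5, 2), condition = rep(c("A", "B"), each = 5),
#'            replicate = rep(1, 10))
#' exp
#' @export
tse <- function(counts, time, condition, replicate,
                lib_sizes = NULL, normalized = FALSE,
                norm_method = if (normalized) "external" else "none",
                raw_counts = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  n <- ncol(counts)
  if (length(time) != n || length(condition) != n || length(replicate) != n)
    stop("time, condition and replicate must each have one entry per sample")
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (anyNA(counts))
    stop("counts contain missing values")
  if (any(counts < 0))
    stop("counts contain negative entries")
  if (!normalized && any(counts != round(counts)))
    stop("raw counts must be integers; set normalized = TRUE for ",
         "pre-normalized matrices")
  if (anyDuplicated(rownames(counts)))
    stop("gene ids must be unique")
  time <- as.numeric(time)
  if (length(unique(time)) < 2L)
    stop("at least 2 distinct time points are required")
  key <- paste(time, condition, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (time, condition, replicate) triple: ",
         gsub("\r", ", ", dup))
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- if (!is.null(raw_counts)) colSums(raw_counts)
                 else colSums(counts)
    # an all-zero sample would give a zero library size downstream
    lib_sizes[lib_sizes <= 0] <- 1
  }
  if (length(lib_sizes) != n || any(lib_sizes <= 0))
    stop("lib_sizes must be strictly positive, one per sample")

  ord <- order(condition, time, replicate)
  samples <- data.frame(sample = colnames(counts),
                        time = time, condition = as.character(condition),
                        replicate = replicate,
                        stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts[, ord, drop = FALSE],
                 samples = samples,
                 lib_sizes = unname(lib_sizes[ord]),
                 normalized = normalized,
                 norm_method = norm_method,
                 raw_counts = if (!is.null(raw_counts))
                   raw_counts[, ord, drop = FALSE]),
            class = "tse")
}

#' @export
print.tse <- function(x, ...) {
  cat("Time-series expression experiment\n")
  cat(sprintf("  %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  time points: %s\n",
              paste(sort(unique(x$samples$time)), collapse = ", ")))
  cat(sprintf("  conditions:  %s\n",
              paste(unique(x$samples$condition), collapse = ", ")))
  cat(sprintf("  replicates per (time, condition): %s\n",
              paste(sort(unique(table(paste(x$samples$time,
                                            x$samples$condition)))),
                    collapse = "-")))
  cat(sprintf("  normalized:  %s (%s)\n", x$normalized, x$norm_method))
  invisible(x)
}

#' @export
dim.tse <- function(x) dim(x$counts)

#' Subset an experiment by gene and/or sample
#'
#' @param x a \code{tse} object.
#' @param i gene index (numeric, logical or character).
#' @param j sample index.
#' @param ... unused.
#' @return A \code{tse} with the selected genes/samples.
#' @export
`[.tse` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  s <- x$samples[j, , drop = FALSE]
  tse(x$counts[i, j, drop = FALSE], time = s$time, condition = s$condition,
      replicate = s$replicate, lib_sizes = x$lib_sizes[j],
      normalized = x$normalized, norm_method = x$norm_method,
      raw_counts = if (!is.null(x$raw_counts))
        x$raw_counts[i, j, drop = FALSE])
}

#' @export
gene_ids <- function(exp) rownames(exp$counts)

#' Extract one gene's expression series within a condition
#'
#' Values are ordered by time with replicates kept grouped within each
#' time point, matching the Y_i = [y_i(t_1), ..., y_i(t_m)] layout the
#' per-gene methods operate on.
#'
#' @param exp a \code{tse} object.
#' @param gene gene id or row index.
#' @param condition condition label, or \code{"pooled"} to take every
#'   sample regardless of condition.
#' @param use_raw return raw counts even if the experiment is normalized.
#' @return A list of class \code{"gene_series"} with elements
#'   \code{gene_id}, \code{values}, \code{times}, \code{replicates},
#'   \code{lib_sizes} and \code{condition}.
#' @export
gene_series <- function(exp, gene, condition = "pooled", use_raw = FALSE) {
  stopifnot(inherits(exp, "tse"))
  keep <- if (identical(condition, "pooled")) rep(TRUE, ncol(exp$counts))
          else exp$samples$condition == condition
  if (!any(keep))
    stop("condition not present in experiment: ", condition)
  mat <- if (use_raw && !is.null(exp$raw_counts)) exp$raw_counts
         else exp$counts
  v <- mat[gene, keep]
  tt <- exp$samples$time[keep]
  rr <- exp$samples$replicate[keep]
  ord <- order(tt, rr)
  structure(list(gene_id = if (is.character(gene)) gene
                           else rownames(mat)[gene],
                 values = unname(v[ord]), times = tt[ord],
                 replicates = rr[ord],
                 lib_sizes = exp$lib_sizes[keep][ord],
                 condition = condition),
            class = "gene_series")
}

#' @export
print.gene_series <- function(x, ...) {
  cat(sprintf("gene_series %s (condition %s): %d observations, %d times\n",
              x$gene_id, x$condition, length(x$values),
              length(unique(x$times))))
  invisible(x)
}
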