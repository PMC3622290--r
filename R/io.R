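read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.table(path, header = TRUE, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Read a count matrix and sample metadata into an experiment
#'
#' The counts file is TSV or CSV with a gene-id first column and one
#' column per sample; the metadata file has one row per sample with
#' columns \code{sample}, \code{time}, \code{condition} and
#' \code{replicate}. Sample columns are matched to metadata rows by name.
#'
#' @param counts_path path to the counts table.
#' @param metadata_path path to the sample metadata table.
#' @param normalized whether the matrix holds pre-normalized values.
#' @return A validated \code{\link{tse}} object with samples ordered by
#'   (condition, time, replicate).
#' @export
read_experiment <- function(counts_path, metadata_path, normalized = FALSE) {
  ct <- read_delim_auto(counts_path)
  md <- read_delim_auto(metadata_path)
  need <- c("sample", "time", "condition", "replicate")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  gene_id <- as.character(ct[[1L]])
  mat <- as.matrix(ct[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric entries in counts matrix")
  rownames(mat) <- gene_id
  missing_md <- setdiff(colnames(mat), md$sample)
  if (length(missing_md))
    stop("sample columns without metadata rows: ",
         paste(missing_md, collapse = ", "))
  missing_ct <- setdiff(md$sample, colnames(mat))
  if (length(missing_ct))
    stop("metadata rows without sample columns: ",
         paste(missing_ct, collapse = ", "))
  md <- md[match(colnames(mat), md$sample), , drop = FALSE]
  tse(mat, time = md$time, condition = md$condition,
      replicate = md$replicate,
      lib_sizes = if ("lib_size" %in% names(md)) md$lib_size,
      normalized = normalized)
}

#' Write an experiment to counts + metadata tables
#'
#' Inverse of \code{\link{read_experiment}}: integer counts round-trip
#' bit-exactly.
#'
#' @param exp a \code{tse} object.
#' @param counts_path,metadata_path output paths (TSV or CSV by extension).
#' @return Invisibly, the two paths.
#' @export
write_experiment <- function(exp, counts_path, metadata_path) {
  stopifnot(inherits(exp, "tse"))
  sep <- if (grepl("\\.csv$", counts_path, ignore.case = TRUE)) "," else "\t"
  ct <- data.frame(gene_id = rownames(exp$counts), exp$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(ct, counts_path, sep = sep, quote = FALSE, row.names = FALSE)
  md <- exp$samples
  md$lib_size <- exp$lib_sizes
  write.table(md, metadata_path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Write a per-gene test result table
#'
#' Standard result serialization shared by every caller: TSV with columns
#' gene_id, statistic, p_value, fdr, call.
#'
#' @param table data.frame with at least those columns.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
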