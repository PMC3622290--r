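#' Build a 2x2 contingency table for one gene across two libraries
#'
#' Rows are (reads in gene g, reads not in gene g), columns the two
#' libraries: cells \code{(x, y; lib1 - x, lib2 - y)}.
#'
#' @param x,y counts of gene g in libraries 1 and 2.
#' @param lib1,lib2 total reads in each library.
#' @return 2x2 integer matrix.
#' @export
contingency_2x2 <- function(x, y, lib1, lib2) {
  tab <- matrix(c(x, lib1 - x, y, lib2 - y), 2, 2,
                dimnames = list(c("gene", "other"), c("lib1", "lib2")))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency cells must be non-negative integers ",
         "(are the library totals at least the gene counts?)")
  tab
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum, over all tables with the observed
#' margins, of hypergeometric point probabilities no larger than the
#' observed one (the minimum-likelihood convention of standard exact
#' tests).
#'
#' @param table a 2x2 matrix of non-negative integer counts (e.g. from
#'   \code{\link{contingency_2x2}}).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(table < 0)) stop("negative cells")
  if (any(table != round(table))) stop("non-integer cells")
  # dhyper summation can overshoot 1 by rounding
  min(1, fisher.test(table)$p.value)
}

#' Audic-Claverie statistic for two counts
#'
#' Under the null that x and y come from the same Poisson rate, with a
#' flat prior over the rate, the predictive distribution of y given x
#' for equal-size libraries is
#' \deqn{p(y | x) = 2^{-(x+y+1)} \binom{x+y}{x},}
#' a negative binomial with size x+1 and probability 1/2. The two-sided
#' p-value is \eqn{2\min\{P(Y \le y | x), P(Y \ge y | x)\}} capped at 1,
#' computed in log space via the NB tail so large counts are safe.
#'
#' Unequal library sizes N1, N2 generalize to a negative binomial with
#' probability \eqn{N_1/(N_1+N_2)}; this variant must be requested
#' explicitly with \code{unequal = TRUE}.
#'
#' @param x,y non-negative integer counts.
#' @param lib1,lib2 library sizes (only needed when unequal).
#' @param unequal allow the generalized unequal-size form.
#' @return List with \code{predictive_prob} (p(y|x)) and \code{p_value}
#'   (two-sided).
#' @export
audic_claverie <- function(x, y, lib1 = NULL, lib2 = NULL,
                           unequal = FALSE) {
  if (x < 0 || y < 0 || x != round(x) || y != round(y))
    stop("counts must be non-negative integers")
  if (!is.null(lib1) && !is.null(lib2) && lib1 != lib2 && !unequal)
    stop("library sizes differ; set unequal = TRUE for the ",
         "generalized statistic")
  prob <- if (unequal && !is.null(lib1)) lib1 / (lib1 + lib2) else 0.5
  # predictive over y given x is NB(size = x + 1, prob)
  pred <- exp(lchoose(x + y, x) + (x + 1) * log(prob) +
                y * log1p(-prob))
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- if (y == 0) 1
           else pnbinom(y - 1, size = x + 1, prob = prob,
                        lower.tail = FALSE)
  list(predictive_prob = pred,
       p_value = min(1, 2 * min(lower, upper)))
}

moments_dispersion <- function(values, groups) {
  mus <- tapply(values, groups, mean)
  vs <- tapply(values, groups, var)
  ok <- !is.na(vs) & tabulate(factor(groups))[seq_along(vs)] >= 2
  if (!any(ok)) return(Inf)
  excess <- sum(pmax(vs[ok] - mus[ok], 0))
  if (excess <= 0) return(Inf)
  sum(mus[ok]^2) / excess
}

#' Poisson / negative-binomial log-linear likelihood-ratio test
#'
#' The pooling static baseline: a log-linear GLM of the counts on time,
#' condition and their interaction is compared against the null model
#' without any time terms by a likelihood-ratio test on the chi-squared
#' scale. With replicates, a per-gene dispersion is estimated by
#' moments and a fixed-dispersion negative-binomial family is used
#' instead of Poisson.
#'
#' @param counts non-negative integer counts, one per sample.
#' @param time time label per sample (treated as a factor).
#' @param condition optional condition label per sample.
#' @param likelihood \code{"auto"} (NB when replicated cells show
#'   extra-Poisson variation), \code{"poisson"}, or \code{"negbin"}.
#' @param offset optional per-sample log offset (e.g. log library size).
#' @return List with \code{statistic} (LRT deviance), \code{df},
#'   \code{p_value}, \code{likelihood} used; p is NA (with a note) when
#'   the GLM fails to converge.
#' @export
poisson_loglinear_lrt <- function(counts, time, condition = NULL,
                                  likelihood = c("auto", "poisson",
                                                 "negbin"),
                                  offset = NULL) {
  likelihood <- match.arg(likelihood)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tf <- factor(time)
  if (nlevels(tf) < 2L) stop("need at least 2 time levels")
  cf <- if (!is.null(condition)) factor(condition)
  if (!is.null(cf) && nlevels(cf) < 2L) cf <- NULL
  dat <- data.frame(y = counts, tf = tf)
  if (!is.null(cf)) dat$cf <- cf
  full_f <- if (is.null(cf)) y ~ tf else y ~ tf * cf
  null_f <- if (is.null(cf)) y ~ 1 else y ~ cf
  cells <- if (is.null(cf)) as.character(tf) else paste(tf, cf)
  replicated <- any(table(cells) >= 2)
  fam <- stats::poisson()
  used <- "poisson"
  if (likelihood == "negbin" ||
      (likelihood == "auto" && replicated)) {
    k <- moments_dispersion(counts, cells)
    if (is.finite(k)) {
      fam <- MASS::negative.binomial(theta = k)
      used <- "negbin"
    } else if (likelihood == "negbin") {
      # no detectable overdispersion: NB with very large size
      fam <- MASS::negative.binomial(theta = 1e6)
      used <- "negbin"
    }
  }
  off <- if (is.null(offset)) rep(0, length(counts)) else offset
  fit <- tryCatch({
    full <- glm(full_f, family = fam, data = dat, offset = off)
    null <- glm(null_f, family = fam, data = dat, offset = off)
    list(full = full, null = null)
  }, error = function(e) e, warning = function(w) {
    # refit, keeping the result but noting non-convergence warnings
    full <- suppressWarnings(glm(full_f, family = fam, data = dat,
                                 offset = off))
    null <- suppressWarnings(glm(null_f, family = fam, data = dat,
                                 offset = off))
    if (!full$converged || !null$converged) simpleError("not converged")
    else list(full = full, null = null)
  })
  if (inherits(fit, "error"))
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, likelihood = used,
                note = conditionMessage(fit)))
  stat <- fit$null$deviance - fit$full$deviance
  df <- fit$null$df.residual - fit$full$df.residual
  list(statistic = stat, df = df,
       p_value = pchisq(pmax(stat, 0), df, lower.tail = FALSE),
       likelihood = used, note = "")
}

# pooled (time, condition) cells: summed counts + summed library sizes
pool_cells <- function(exp) {
  key <- paste(exp$samples$condition, exp$samples$time, sep = "\r")
  ukey <- unique(key)
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  counts <- sapply(ukey, function(k)
    rowSums(raw[, key == k, drop = FALSE]))
  lib <- sapply(ukey, function(k) sum(exp$lib_sizes[key == k]))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  list(counts = as.matrix(counts), lib = lib,
       condition = parts[, 1], time = as.numeric(parts[, 2]))
}

#' Union-of-pairwise TDE calling with a static two-sample test
#'
#' Reproduces the classical static workflow: replicates are pooled
#' within each (time, condition) cell, the chosen two-sample test is
#' run for every admissible pair of cells — each pair of time points
#' within a condition, and each pair of conditions within a time point
#' — p-values are BH-adjusted within each comparison, and a gene is
#' called TDE if it is significant in at least one comparison. The
#' per-comparison detail table is returned alongside the union call.
#'
#' @param exp a \code{\link{tse}}.
#' @param test \code{"fisher"} or \code{"ac"} (Audic-Claverie; uses the
#'   generalized form when the pooled library sizes differ).
#' @param fdr_level per-comparison BH threshold (default 0.05).
#' @return data.frame of class \code{"union_tde"} with columns gene_id,
#'   n_comparisons, n_significant, min_fdr, call; the full detail table
#'   is in attribute \code{"detail"}.
#' @export
union_pairwise_tde <- function(exp, test = c("fisher", "ac"),
                               fdr_level = 0.05) {
  stopifnot(inherits(exp, "tse"))
  test <- match.arg(test)
  cells <- pool_cells(exp)
  n_cell <- length(cells$lib)
  pairs <- which(upper.tri(matrix(0, n_cell, n_cell)), arr.ind = TRUE)
  admissible <- (cells$condition[pairs[, 1]] ==
                   cells$condition[pairs[, 2]]) |
                (cells$time[pairs[, 1]] == cells$time[pairs[, 2]])
  pairs <- pairs[admissible, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("need more than one time point or condition")
  genes <- rownames(cells$counts)
  detail <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    xa <- cells$counts[, a]; xb <- cells$counts[, b]
    la <- cells$lib[a]; lb <- cells$lib[b]
    p <- if (test == "fisher") {
      vapply(seq_along(genes), function(g)
        fisher_exact(contingency_2x2(xa[g], xb[g], la, lb)),
        numeric(1))
    } else {
      vapply(seq_along(genes), function(g)
        audic_claverie(xa[g], xb[g], la, lb,
                       unequal = la != lb)$p_value, numeric(1))
    }
    detail[[r]] <- data.frame(
      gene_id = genes,
      comparison = sprintf("%s:t%s_vs_%s:t%s",
                           cells$condition[a], cells$time[a],
                           cells$condition[b], cells$time[b]),
      p_value = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  sig <- detail$fdr < fdr_level
  agg <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  agg$n_comparisons <- as.integer(table(detail$gene_id)[genes])
  nsig <- tapply(sig, detail$gene_id, sum)[genes]
  agg$n_significant <- as.integer(nsig)
  agg$min_fdr <- as.numeric(tapply(detail$fdr, detail$gene_id,
                                   min)[genes])
  agg$call <- ifelse(agg$n_significant > 0, "TDE", "EE")
  class(agg) <- c("union_tde", "data.frame")
  attr(agg, "detail") <- detail
  attr(agg, "params") <- list(test = test, fdr_level = fdr_level)
  agg
}

#' @export
print.union_tde <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Union-of-pairwise %s test: %d genes, %d comparisons each\n",
              p$test, nrow(x), x$n_comparisons[1]))
  cat(sprintf("  TDE (significant in >= 1 comparison at FDR < %g): %d\n",
              p$fdr_level, sum(x$call == "TDE")))
  invisible(x)
}

#' Log-linear LRT screen across genes
#'
#' Applies \code{\link{poisson_loglinear_lrt}} to every gene and
#' BH-adjusts across genes.
#'
#' @param exp a \code{\link{tse}}.
#' @param likelihood passed to \code{\link{poisson_loglinear_lrt}}.
#' @param fdr_level FDR threshold for the TDE call.
#' @param use_offset include log library sizes as offsets.
#' @return data.frame with gene_id, statistic, df, p_value, fdr, call.
#' @export
run_loglinear <- function(exp, likelihood = "auto", fdr_level = 0.05,
                          use_offset = TRUE) {
  stopifnot(inherits(exp, "tse"))
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  off <- if (use_offset) {
    lo <- log(exp$lib_sizes)
    lo - mean(lo)
  }
  cond <- if (length(unique(exp$samples$condition)) > 1L)
    exp$samples$condition
  res <- lapply(seq_len(nrow(raw)), function(g)
    poisson_loglinear_lrt(raw[g, ], exp$samples$time, cond,
                          likelihood = likelihood, offset = off))
  out <- data.frame(gene_id = rownames(raw),
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    df = vapply(res, function(r)
                      as.numeric(r$df), numeric(1)),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    fdr = NA_real_, call = NA_character_,
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out$call[ok] <- ifelse(out$fdr[ok] < fdr_level, "TDE", "EE")
  out
}
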