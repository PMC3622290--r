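#' Granger causality F-test between two trajectories
#'
#' Tests whether past values of \code{y} improve the prediction of
#' \code{x} beyond x's own past: the restricted regression uses
#' \code{lag} own lags of x, the full regression adds \code{lag} lags of
#' y, and \eqn{F = ((RSS_r - RSS_f)/lag) / (RSS_f / dof_f)} with an F
#' reference distribution. In the pair screen this is applied to spline
#' residuals, so the test targets dependence beyond the smooth trends.
#'
#' @param x,y equal-length numeric series (x is the response).
#' @param lag number of lags (default 1).
#' @return List with \code{F}, \code{p_value}, \code{df1}, \code{df2}.
#' @export
granger_test <- function(x, y, lag = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (lag < 1) stop("lag must be >= 1")
  if (n <= 2 * lag + 2)
    stop("series too short for lag ", lag,
         ": need length > 2*lag + 2")
  resp <- x[(lag + 1):n]
  Xr <- sapply(seq_len(lag), function(l) x[(lag + 1 - l):(n - l)])
  Xf <- cbind(Xr, sapply(seq_len(lag), function(l) y[(lag + 1 - l):(n - l)]))
  fit_r <- lm.fit(cbind(1, Xr), resp)
  fit_f <- lm.fit(cbind(1, Xf), resp)
  rss_r <- sum(fit_r$residuals^2)
  rss_f <- sum(fit_f$residuals^2)
  df2 <- length(resp) - (2 * lag + 1)
  if (rss_f < 1e-300 && rss_r < 1e-300)
    return(list(F = NA_real_, p_value = NA_real_, df1 = lag, df2 = df2,
                testable = FALSE))
  Fstat <- ((rss_r - rss_f) / lag) / (rss_f / df2)
  list(F = Fstat, p_value = pf(Fstat, lag, df2, lower.tail = FALSE),
       df1 = lag, df2 = df2, testable = TRUE)
}

#' Glass d-score of one pair's correlation
#'
#' Standardizes the correlation of pair (i, j) against gene i's
#' background distribution of correlations with all other genes:
#' \eqn{d = (r_{ij} - \bar r_i) / s_{r_i}}.
#'
#' @param correlations numeric vector of gene i's correlations with its
#'   partner genes (self-correlation excluded; at least 3 partners).
#' @param j index of the partner of interest within \code{correlations}.
#' @return The d-score; \code{NA} with attribute \code{"testable"} =
#'   FALSE when the background has zero spread.
#' @export
glass_d <- function(correlations, j) {
  if (length(correlations) < 3L)
    stop("need at least 3 partner correlations")
  if (j < 1L || j > length(correlations)) stop("j out of range")
  s <- sd(correlations)
  if (!is.finite(s) || s == 0)
    return(structure(NA_real_, testable = FALSE))
  structure((correlations[j] - mean(correlations)) / s, testable = TRUE)
}

#' Best lagged Pearson correlation between two trajectories
#'
#' Correlates x with time-shifted copies of y over shifts
#' \code{-max_lag..max_lag}; a positive lag means y is delayed relative
#' to x (y_t tracks x_{t-lag}). Returns the lag maximizing |r|, ties
#' broken toward the smaller |lag| and then the negative lag.
#'
#' @param x,y equal-length numeric series.
#' @param max_lag maximum shift to consider.
#' @return List with \code{best_lag}, \code{r}, and the full
#'   \code{by_lag} table.
#' @export
lagged_correlation <- function(x, y, max_lag = 2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  lags <- seq(-max_lag, max_lag)
  lags <- lags[n - abs(lags) >= 3]   # need overlap of >= 3
  if (!length(lags)) stop("series too short for any admissible lag")
  rvals <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[seq_len(n - l)]; ys <- y[seq_len(n - l) + l]
    } else {
      xs <- x[seq_len(n + l) - l]; ys <- y[seq_len(n + l)]
    }
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  if (all(is.na(rvals)))
    return(list(best_lag = NA_integer_, r = NA_real_,
                by_lag = data.frame(lag = lags, r = rvals),
                testable = FALSE))
  ord <- order(abs(lags), lags)   # |lag| first, negative before positive
  best <- ord[which.max(abs(rvals)[ord])]
  list(best_lag = lags[best], r = rvals[best],
       by_lag = data.frame(lag = lags, r = rvals), testable = TRUE)
}

# per-gene trajectory: per-time mean of (normalized) expression,
# log2(x + 1)
gene_trajectories <- function(exp, genes, condition = "pooled") {
  t(vapply(genes, function(g) {
    s <- gene_series(exp, g, condition)
    log2(as.numeric(tapply(s$values, s$times, mean)) + 1)
  }, numeric(length(unique(
    if (identical(condition, "pooled")) exp$samples$time
    else exp$samples$time[exp$samples$condition == condition])))))
}

pair_stat_matrix <- function(traj, metric, lag, max_lag) {
  n <- nrow(traj)
  if (metric == "glass_d") {
    R <- suppressWarnings(cor(t(traj)))
    R[!is.finite(R)] <- 0
    d <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      bg <- R[i, -i]
      s <- sd(bg); mu <- mean(bg)
      if (is.finite(s) && s > 0) d[i, -i] <- (bg - mu) / s
    }
    # unordered pair score: average of the two directional d-scores
    (d + t(d)) / 2
  } else if (metric == "lagged_corr") {
    out <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lc <- lagged_correlation(traj[i, ], traj[j, ], max_lag)
      out[i, j] <- out[j, i] <- lc$r
    }
    out
  } else stop("unknown metric")
}

#' Screen all pairs of TDE genes for coupled trajectories
#'
#' Scores every unordered pair among the supplied genes with one of the
#' three dependence metrics. Granger causality uses its analytic F
#' p-value on spline residuals (both gene orders tested, smaller p
#' kept); the Glass d-score and lagged correlation build a permutation
#' null by shuffling each trajectory's time order (1,000 repetitions by
#' default, null statistics pooled across pairs). BH FDR is applied
#' across pairs.
#'
#' @param exp a \code{\link{tse}}.
#' @param tde_genes character vector of at least 4 gene ids (typically
#'   the significant TDE set from an upstream screen).
#' @param metric \code{"glass_d"}, \code{"granger"} or
#'   \code{"lagged_corr"}.
#' @param condition condition label or \code{"pooled"}.
#' @param n_perm permutation repetitions (default 1000).
#' @param seed integer seed.
#' @param lag Granger lag (default 1).
#' @param max_lag lagged-correlation search window (default 2).
#' @param fdr_level FDR threshold for the coupled call.
#' @param max_pairs guard on the number of pairs; raise
#'   \code{allow_large} to exceed it.
#' @param allow_large permit more than \code{max_pairs} pairs.
#' @return data.frame of class \code{"pair_screen"} with columns
#'   gene_i, gene_j, metric, statistic, best_lag, p_value, fdr, call.
#' @export
pair_screen <- function(exp, tde_genes,
                        metric = c("glass_d", "granger", "lagged_corr"),
                        condition = "pooled", n_perm = 1000, seed = 1,
                        lag = 1, max_lag = 2, fdr_level = 0.05,
                        max_pairs = 50000, allow_large = FALSE) {
  stopifnot(inherits(exp, "tse"))
  metric <- match.arg(metric)
  tde_genes <- as.character(tde_genes)
  if (length(tde_genes) < 4L) stop("need at least 4 TDE genes")
  if (!all(tde_genes %in% gene_ids(exp)))
    stop("genes not in experiment: ",
         paste(head(setdiff(tde_genes, gene_ids(exp))), collapse = ", "))
  n <- length(tde_genes)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs && !allow_large)
    stop(n_pairs, " pairs exceeds max_pairs = ", max_pairs,
         "; set allow_large = TRUE to proceed")
  traj <- gene_trajectories(exp, tde_genes, condition)
  pairs <- t(combn(n, 2))
  set.seed(seed)

  if (metric == "granger") {
    res <- t(apply(traj, 1L, function(v)
      tryCatch(fit_spline(v, times = seq_along(v))$residuals,
               error = function(e) v - mean(v))))
    stat <- p <- best_lag <- rep(NA_real_, nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      g1 <- tryCatch(granger_test(res[i, ], res[j, ], lag),
                     error = function(e) list(F = NA, p_value = NA))
      g2 <- tryCatch(granger_test(res[j, ], res[i, ], lag),
                     error = function(e) list(F = NA, p_value = NA))
      ps <- c(g1$p_value, g2$p_value)
      if (all(is.na(ps))) next
      kbest <- which.min(ps)
      p[r] <- ps[kbest]
      stat[r] <- c(g1$F, g2$F)[kbest]
    }
  } else {
    obs <- pair_stat_matrix(traj, metric, lag, max_lag)
    stat <- obs[pairs]
    best_lag <- rep(NA_real_, nrow(pairs))
    if (metric == "lagged_corr") {
      for (r in seq_len(nrow(pairs))) {
        lc <- lagged_correlation(traj[pairs[r, 1], ],
                                 traj[pairs[r, 2], ], max_lag)
        stat[r] <- lc$r; best_lag[r] <- lc$best_lag
      }
    }
    m <- ncol(traj)
    null_stats <- numeric(0)
    per_rep <- max(1L, min(nrow(pairs), 200L))
    for (b in seq_len(n_perm)) {
      ptraj <- traj[, sample.int(m), drop = FALSE]
      # independent time shuffles per gene destroy cross-gene coupling
      for (i in seq_len(n)) ptraj[i, ] <- ptraj[i, sample.int(m)]
      pm <- pair_stat_matrix(ptraj, metric, lag, max_lag)
      vals <- pm[pairs[sample.int(nrow(pairs),
                                  min(per_rep, nrow(pairs))), ,
                       drop = FALSE]]
      null_stats <- c(null_stats, vals[is.finite(vals)])
    }
    p <- vapply(stat, function(s) {
      if (!is.finite(s)) return(NA_real_)
      (1 + sum(abs(null_stats) >= abs(s))) / (length(null_stats) + 1)
    }, numeric(1))
  }

  out <- data.frame(gene_i = tde_genes[pairs[, 1]],
                    gene_j = tde_genes[pairs[, 2]],
                    metric = metric, statistic = stat,
                    best_lag = if (metric == "lagged_corr") best_lag
                               else NA_real_,
                    p_value = p, fdr = NA_real_, call = "untestable",
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out$call[ok] <- ifelse(out$fdr[ok] < fdr_level, "coupled", "ns")
  out <- out[order(out$p_value, -abs(out$statistic)), ]
  rownames(out) <- NULL
  class(out) <- c("pair_screen", "data.frame")
  attr(out, "params") <- list(metric = metric, n_perm = n_perm,
                              seed = seed, fdr_level = fdr_level)
  out
}

#' @export
print.pair_screen <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Pair screen (%s): %d pairs, %d coupled at FDR < %g\n",
              p$metric, nrow(x), sum(x$call == "coupled"), p$fdr_level))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
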