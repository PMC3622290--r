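#' Fit a cubic smoothing spline to a gene's time series
#'
#' Replicates enter as repeated abscissae; the smoothing parameter is
#' chosen by generalized cross-validation when \code{smoothing = "auto"}.
#' A numeric \code{smoothing} is used as the \code{spar} argument of
#' \code{\link[stats]{smooth.spline}}; \code{smoothing = 0} requests the
#' near-interpolation limit.
#'
#' @param series a \code{\link{gene_series}}, or a numeric vector of
#'   values (then \code{times} must be given).
#' @param smoothing \code{"auto"} or a numeric spar value.
#' @param times numeric time coordinates when \code{series} is a vector.
#' @return A list of class \code{"spline_fit"}: \code{fitted},
#'   \code{residuals} (observed minus fitted, per observation),
#'   \code{times}, \code{values}, \code{spar}, \code{df}.
#' @export
fit_spline <- function(series, smoothing = "auto", times = NULL) {
  if (inherits(series, "gene_series")) {
    values <- series$values
    times <- series$times
  } else {
    values <- as.numeric(series)
    if (is.null(times)) times <- seq_along(values)
  }
  if (any(!is.finite(values)))
    stop("series contains non-finite values")
  if (length(unique(times)) < 4L)
    stop("smoothing spline needs >= 4 distinct time points; ",
         "use a lower-order (linear) fallback explicitly for shorter series")
  if (sd(values) == 0) {
    # constant series: the spline is the constant itself
    return(structure(list(fitted = values, residuals = values * 0,
                          times = times, values = values,
                          spar = NA_real_, df = 1), class = "spline_fit"))
  }
  fit <- if (identical(smoothing, "auto")) {
    smooth.spline(times, values, cv = FALSE)
  } else if (is.numeric(smoothing) && smoothing <= 0) {
    smooth.spline(times, values, lambda = 1e-12)
  } else {
    smooth.spline(times, values, spar = smoothing)
  }
  fitted <- predict(fit, times)$y
  structure(list(fitted = fitted, residuals = values - fitted,
                 times = times, values = values,
                 spar = fit$spar, df = fit$df),
            class = "spline_fit")
}

#' Residual autocorrelation at one lag
#'
#' The per-lag trajectory statistic: for residuals \eqn{r_1, ..., r_m}
#' around the spline fit,
#' \deqn{ACR(k) = \frac{1}{(m-k)\sigma^2} \sum_{j=1}^{m-k} r_j r_{j+k}.}
#'
#' @param residuals numeric residual vector, time-ordered.
#' @param k lag, \code{1 <= k < length(residuals)}.
#' @param sigma2 residual variance used for scaling (the maximum
#'   likelihood variance \code{mean(residuals^2)} makes the statistic
#'   scale-free).
#' @return The lag-k normalized autocorrelation sum.
#' @export
residual_acf <- function(residuals, k, sigma2) {
  m <- length(residuals)
  if (k < 1L || k >= m)
    stop("lag k must satisfy 1 <= k < length(residuals)")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("degenerate residual series (sigma2 <= 0): gene not testable")
  idx <- seq_len(m - k)
  sum(residuals[idx] * residuals[idx + k]) / ((m - k) * sigma2)
}

#' Trajectory index of a spline fit
#'
#' Aggregates the residual autocorrelation over every admissible lag,
#' k = 1..m-1, using the ML residual variance for scaling. The default
#' aggregate is the signed sum \eqn{\sum_k ACR(k)}: temporal dependence
#' in expression manifests as positive autocorrelation, and the signed
#' sum lets the zero-mean noise contributed by the sparse high lags
#' cancel instead of accumulating. The sum over lags is what lets the
#' index exceed 1 for strongly dependent trajectories.
#' \code{aggregate = "abs"} gives \eqn{\sum_k |ACR(k)|} instead, and
#' the per-lag values are always attached so any other aggregation can
#' be audited.
#'
#' @param fit a \code{"spline_fit"} (or a bare residual vector).
#' @param aggregate \code{"signed"} (default) or \code{"abs"}.
#' @return The index, with the per-lag values attached as attribute
#'   \code{"per_lag"}; \code{NA} with attribute \code{"testable"} =
#'   FALSE for degenerate (constant-residual) series.
#' @export
seti_index <- function(fit, aggregate = c("signed", "abs")) {
  aggregate <- match.arg(aggregate)
  res <- if (inherits(fit, "spline_fit")) fit$residuals else as.numeric(fit)
  m <- length(res)
  sigma2 <- mean(res^2)
  if (!is.finite(sigma2) || sigma2 < 1e-300)
    return(structure(NA_real_, testable = FALSE))
  per_lag <- vapply(seq_len(m - 1L), residual_acf, numeric(1),
                    residuals = res, sigma2 = sigma2)
  val <- if (aggregate == "abs") sum(abs(per_lag)) else sum(per_lag)
  structure(val, per_lag = per_lag, testable = TRUE)
}

series_blocks <- function(times) split(seq_along(times), times)

seti_of_series <- function(values, times, smoothing = "auto",
                           aggregate = "signed") {
  seti_index(fit_spline(values, smoothing = smoothing, times = times),
             aggregate = aggregate)
}

#' Permutation test for the trajectory index
#'
#' Permutes the time order of the observations — replicate blocks are
#' shuffled as units so within-time exchangeability is preserved — and
#' refits the spline and index each time. Under the null of no temporal
#' differential expression the observed index is exchangeable with the
#' permuted ones; the p-value uses add-one smoothing,
#' \eqn{p = (1 + \#\{index^{perm} \ge index^{obs}\}) / (N + 1)}.
#'
#' @param series a \code{\link{gene_series}} or numeric vector.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param times times when \code{series} is a vector.
#' @param smoothing passed to \code{\link{fit_spline}}.
#' @param aggregate passed to \code{\link{seti_index}}.
#' @return List with \code{p_value}, \code{observed}, \code{n_perm}.
#' @export
seti_permutation_test <- function(series, n_perm = 10000, seed = 1,
                                  times = NULL, smoothing = "auto",
                                  aggregate = "signed") {
  if (inherits(series, "gene_series")) {
    values <- series$values; times <- series$times
  } else {
    values <- as.numeric(series)
    if (is.null(times)) times <- seq_along(values)
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  obs <- seti_of_series(values, times, smoothing, aggregate)
  if (!isTRUE(attr(obs, "testable")))
    return(list(p_value = NA_real_, observed = NA_real_,
                n_perm = n_perm, testable = FALSE))
  blocks <- series_blocks(times)
  utimes <- as.numeric(names(blocks))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    ord <- sample.int(length(blocks))
    # block p takes time slot p; observations inherit the slot's time
    perm_values <- unlist(lapply(blocks[ord], function(i) values[i]),
                          use.names = FALSE)
    perm_times <- rep(utimes, lengths(blocks)[ord])
    stat <- seti_of_series(perm_values, perm_times, smoothing, aggregate)
    if (is.na(stat)) stat <- 0
    if (stat >= obs) count <- count + 1L
  }
  list(p_value = (1 + count) / (n_perm + 1),
       observed = as.numeric(obs), n_perm = n_perm, testable = TRUE)
}

#' Bootstrap confidence interval for the trajectory index
#'
#' Residual bootstrap: spline residuals are resampled with replacement,
#' added back to the fitted curve, and the index recomputed. Returns the
#' trimmed mean of the bootstrap replicates, the bootstrap bias, and the
#' percentile 95\% interval.
#'
#' @param series a \code{\link{gene_series}} or numeric vector.
#' @param n_boot bootstrap replicates (default 100).
#' @param trim trim fraction for the trimmed mean (default 0.1).
#' @param seed integer seed.
#' @param times,smoothing,aggregate as in
#'   \code{\link{seti_permutation_test}}.
#' @return List with \code{trimmed_mean}, \code{bias}, \code{ci_low},
#'   \code{ci_high}, \code{observed}.
#' @export
seti_bootstrap <- function(series, n_boot = 100, trim = 0.1, seed = 1,
                           times = NULL, smoothing = "auto",
                           aggregate = "signed") {
  if (inherits(series, "gene_series")) {
    values <- series$values; times <- series$times
  } else {
    values <- as.numeric(series)
    if (is.null(times)) times <- seq_along(values)
  }
  fit <- fit_spline(values, smoothing = smoothing, times = times)
  obs <- seti_index(fit, aggregate)
  if (!isTRUE(attr(obs, "testable")))
    return(list(trimmed_mean = NA_real_, bias = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                observed = NA_real_, testable = FALSE))
  if (all(abs(fit$residuals) < 1e-8)) {
    # zero-noise series: every resample reproduces the observed index
    return(list(trimmed_mean = as.numeric(obs), bias = 0,
                ci_low = as.numeric(obs), ci_high = as.numeric(obs),
                observed = as.numeric(obs), testable = TRUE))
  }
  set.seed(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ystar <- fit$fitted + sample(fit$residuals, replace = TRUE)
    stat <- seti_of_series(ystar, times, smoothing, aggregate)
    boot[b] <- if (is.na(stat)) 0 else as.numeric(stat)
  }
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  list(trimmed_mean = mean(boot, trim = trim),
       bias = mean(boot) - as.numeric(obs),
       ci_low = ci[1], ci_high = ci[2],
       observed = as.numeric(obs), testable = TRUE)
}

#' Statistical evolutionary trajectory index screen
#'
#' Runs the full SETI pipeline within one biological condition: per gene,
#' a cubic smoothing spline fit, the residual-autocorrelation trajectory
#' index, a permutation p-value and a bootstrap trimmed-mean/CI, then
#' Benjamini-Hochberg FDR across genes. Genes are ranked by index,
#' largest first.
#'
#' @param exp a \code{\link{tse}} object.
#' @param condition condition label (or \code{"pooled"}).
#' @param n_perm permutations per gene (default 10000).
#' @param n_boot bootstrap replicates per gene (default 100).
#' @param trim trimmed-mean fraction (default 0.1).
#' @param seed master seed; per-gene seeds are derived from it.
#' @param fdr_level FDR threshold for the TDE call (default 0.05).
#' @param smoothing passed to \code{\link{fit_spline}}.
#' @param transform \code{"log2"} (default) fits the spline to
#'   \code{log2(value + 1)}, the scale expression trajectories are
#'   usually inspected on; \code{"none"} uses the matrix as is.
#' @param aggregate passed to \code{\link{seti_index}}.
#' @return A data.frame of class \code{"seti_result"} with columns
#'   gene_id, seti, boot_trimmed_mean, boot_bias, ci95_low, ci95_high,
#'   p_value, fdr, call; untestable genes carry NA statistics and call
#'   \code{"untestable"}.
#' @export
run_seti <- function(exp, condition = "pooled", n_perm = 10000,
                     n_boot = 100, trim = 0.1, seed = 1,
                     fdr_level = 0.05, smoothing = "auto",
                     transform = c("log2", "none"),
                     aggregate = "signed") {
  transform <- match.arg(transform)
  stopifnot(inherits(exp, "tse"))
  if (!identical(condition, "pooled") &&
      !condition %in% exp$samples$condition)
    stop("condition not present in experiment: ", condition)
  genes <- gene_ids(exp)
  n <- length(genes)
  out <- data.frame(gene_id = genes, seti = NA_real_,
                    boot_trimmed_mean = NA_real_, boot_bias = NA_real_,
                    ci95_low = NA_real_, ci95_high = NA_real_,
                    p_value = NA_real_, fdr = NA_real_,
                    call = "untestable", stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    s <- gene_series(exp, genes[g], condition)
    if (transform == "log2") s$values <- log2(s$values + 1)
    gseed <- (seed + 7919L * g) %% .Machine$integer.max
    pt <- seti_permutation_test(s, n_perm = n_perm, seed = gseed,
                                smoothing = smoothing,
                                aggregate = aggregate)
    if (!isTRUE(pt$testable)) next
    bt <- seti_bootstrap(s, n_boot = n_boot, trim = trim, seed = gseed,
                         smoothing = smoothing, aggregate = aggregate)
    out$seti[g] <- pt$observed
    out$p_value[g] <- pt$p_value
    out$boot_trimmed_mean[g] <- bt$trimmed_mean
    out$boot_bias[g] <- bt$bias
    out$ci95_low[g] <- bt$ci_low
    out$ci95_high[g] <- bt$ci_high
  }
  testable <- !is.na(out$p_value)
  if (!any(testable))
    warning("no testable genes for SETI")
  out$fdr[testable] <- bh_fdr(out$p_value[testable])
  out$call[testable] <- ifelse(out$fdr[testable] < fdr_level, "TDE", "EE")
  out <- out[order(-ifelse(is.na(out$seti), -Inf, out$seti)), ]
  rownames(out) <- NULL
  class(out) <- c("seti_result", "data.frame")
  attr(out, "params") <- list(condition = condition, n_perm = n_perm,
                              n_boot = n_boot, trim = trim, seed = seed,
                              fdr_level = fdr_level)
  out
}

#' @export
print.seti_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("SETI screen: %d genes, condition %s, N=%d permutations\n",
              nrow(x), p$condition, p$n_perm))
  cat(sprintf("  TDE at FDR < %g: %d;  untestable: %d\n",
              p$fdr_level, sum(x$call == "TDE"),
              sum(x$call == "untestable")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
residuals.spline_fit <- function(object, ...) object$residuals

#' @export
fitted.spline_fit <- function(object, ...) object$fitted

#' Plot a spline fit over the observed trajectory
#'
#' @param x a \code{"spline_fit"}.
#' @param ... passed to \code{plot}.
#' @export
plot.spline_fit <- function(x, ...) {
  plot(x$times, x$values, xlab = "time", ylab = "expression",
       pch = 16, ...)
  ord <- order(x$times)
  lines(x$times[ord], x$fitted[ord], col = "steelblue", lwd = 2)
  invisible(x)
}
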