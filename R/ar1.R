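#' Specification for a Bayesian AR(1) count-model fit
#'
#' Bundles the likelihood choice, MCMC settings and priors used by
#' \code{\link{fit_poisson_ar1}} and \code{\link{fit_negbin_ar1}}. The
#' priors are weakly informative: \eqn{\beta \sim N(0, 10^2)},
#' \eqn{\sigma^2 \sim InvGamma(0.01, 0.01)}, \eqn{\phi \sim U(-1, 1)}
#' (stationarity enforced), and for the negative binomial
#' \eqn{\log k \sim N(0, 2^2)}.
#'
#' @param likelihood \code{"poisson"} or \code{"negbin"}.
#' @param n_iter total MCMC iterations (default 6000).
#' @param n_burnin burn-in iterations discarded (default 1000).
#' @param beta_sd prior sd of the intercept.
#' @param sigma_shape,sigma_rate inverse-gamma prior on the innovation
#'   variance.
#' @param logk_mean,logk_sd log-normal prior on the NB size parameter.
#' @param init_variance \code{"stationary"} uses
#'   \eqn{Var(w_1) = \sigma^2/(1-\phi^2)}; \code{"literal"} uses
#'   \eqn{\sigma^2 (1-\phi^2)}.
#' @param offset \code{"libsize"} (centered log library size),
#'   \code{"none"}, or a numeric per-observation offset.
#' @param seed integer seed.
#' @return A list of class \code{"ar1_spec"}.
#' @export
ar1_spec <- function(likelihood = c("poisson", "negbin"), n_iter = 6000,
                     n_burnin = 1000, beta_sd = 10, sigma_shape = 0.01,
                     sigma_rate = 0.01, logk_mean = 0, logk_sd = 2,
                     init_variance = c("stationary", "literal"),
                     offset = "libsize", seed = 1) {
  likelihood <- match.arg(likelihood)
  init_variance <- match.arg(init_variance)
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  structure(list(likelihood = likelihood, n_iter = n_iter,
                 n_burnin = n_burnin, beta_sd = beta_sd,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 logk_mean = logk_mean, logk_sd = logk_sd,
                 init_variance = init_variance, offset = offset,
                 seed = seed),
            class = "ar1_spec")
}

resolve_offset <- function(spec, lib_sizes, n_obs) {
  if (is.numeric(spec$offset)) {
    if (length(spec$offset) != n_obs)
      stop("numeric offset must have one entry per observation")
    return(spec$offset)
  }
  if (identical(spec$offset, "none")) return(rep(0, n_obs))
  lo <- log(lib_sizes)
  lo - mean(lo)  # relative depth only; beta keeps the count scale
}

ar1_mcmc <- function(y, tidx, offset, m, spec, init = NULL,
                     return_state = FALSE) {
  set.seed(spec$seed)
  ar1_mcmc_cpp(as.numeric(y), as.integer(tidx), as.numeric(offset),
               as.integer(m),
               likelihood = if (spec$likelihood == "poisson") 0L else 1L,
               n_iter = as.integer(spec$n_iter),
               n_burnin = as.integer(spec$n_burnin),
               stationary = spec$init_variance == "stationary",
               beta_sd = spec$beta_sd, sig_a = spec$sigma_shape,
               sig_b = spec$sigma_rate, logk_mu = spec$logk_mean,
               logk_sd = spec$logk_sd, init = init,
               return_state = return_state)
}

summarize_ar1 <- function(gene_id, draws, spec, degenerate = FALSE,
                          note = NULL) {
  if (degenerate) {
    out <- list(gene_id = gene_id, draws = NULL,
                ci95 = c(NA_real_, NA_real_), tail_prob = NA_real_,
                call = "EE", degenerate = TRUE, note = note,
                accept = NULL, w_mean = NULL, spec = spec)
    class(out) <- "ar1_fit"
    return(out)
  }
  phi <- draws$phi
  ci <- unname(quantile(phi, c(0.025, 0.975)))
  tail_prob <- max(mean(phi > 0), mean(phi < 0))
  call <- if (ci[1] > 0 || ci[2] < 0) "TDE" else "EE"
  d <- data.frame(phi = phi, beta = draws$beta, sigma2 = draws$sigma2)
  if (length(draws$k)) d$k <- draws$k
  out <- list(gene_id = gene_id, draws = d, ci95 = ci,
              tail_prob = tail_prob, call = call, degenerate = FALSE,
              note = note, accept = draws$accept,
              w_mean = draws$w_mean, spec = spec)
  class(out) <- "ar1_fit"
  out
}

check_count_series <- function(values, normalized) {
  if (normalized || any(values != round(values)))
    stop("AR(1) count models need raw integer counts; ",
         "pass use_raw counts, not normalized values")
  if (any(values < 0)) stop("negative counts")
}

#' Fit the Bayesian Poisson AR(1) model to one gene
#'
#' Models the count at each time point as Poisson with log-mean
#' \eqn{w_j + \beta} (plus an optional depth offset), where the latent
#' path follows a stationary AR(1): \eqn{w_1 \sim N(0, \sigma^2/(1-\phi^2))},
#' \eqn{w_j = \phi w_{j-1} + u_j}. Posterior inference is by
#' Metropolis-within-Gibbs MCMC; the gene is called TDE when the 95\%
#' credible interval of the autocorrelation \eqn{\phi} excludes 0, and
#' the tail probability \eqn{\max\{P(\phi>0|y), P(\phi<0|y)\}} ranks the
#' strength of temporal dependence.
#'
#' The model assumes a single measurement per time point; replicates are
#' summed within each time point (the offset then uses the summed
#' library size).
#'
#' @param series a \code{\link{gene_series}} of raw counts, or a numeric
#'   count vector (one per time point).
#' @param spec an \code{\link{ar1_spec}} with
#'   \code{likelihood = "poisson"}.
#' @param normalized set when the values are known to be normalized
#'   (raises an error: the model needs raw counts).
#' @return An object of class \code{"ar1_fit"}: posterior \code{draws}
#'   (phi, beta, sigma2), \code{ci95} of phi, \code{tail_prob},
#'   \code{call} (TDE/EE), acceptance rates and the posterior-mean
#'   latent path.
#' @export
fit_poisson_ar1 <- function(series, spec = ar1_spec("poisson"),
                            normalized = FALSE) {
  if (inherits(series, "gene_series")) {
    gene_id <- series$gene_id
    # collapse replicates: counts sum within a time point, depths add
    agg_y <- tapply(series$values, series$times, sum)
    agg_ls <- tapply(series$lib_sizes, series$times, sum)
    values <- as.numeric(agg_y)
    lib_sizes <- as.numeric(agg_ls)
  } else {
    gene_id <- "series"
    values <- as.numeric(series)
    lib_sizes <- rep(1, length(values))
  }
  check_count_series(values, normalized)
  m <- length(values)
  if (m < 4L) stop("AR(1) model needs at least 4 time points")
  if (all(values == 0))
    return(summarize_ar1(gene_id, NULL, spec, degenerate = TRUE,
                         note = "all-zero series"))
  offset <- resolve_offset(spec, lib_sizes, m)
  draws <- ar1_mcmc(values, seq_len(m), offset, m, spec)
  summarize_ar1(gene_id, draws, spec)
}

#' Fit the Bayesian negative-binomial AR(1) model to one gene
#'
#' As \code{\link{fit_poisson_ar1}}, but replicates within a time point
#' share the latent value \eqn{w_j} and counts follow a negative
#' binomial with mean \eqn{\mu_j} and variance \eqn{\mu_j + \mu_j^2/k};
#' \eqn{k^{-1}} is the dispersion. The size parameter k is sampled by
#' Metropolis with a log-normal prior.
#'
#' @param series a \code{\link{gene_series}} with at least one time
#'   point holding 2 or more replicates.
#' @param spec an \code{\link{ar1_spec}} with
#'   \code{likelihood = "negbin"}.
#' @param normalized as in \code{\link{fit_poisson_ar1}}.
#' @return An \code{"ar1_fit"} whose draws include \code{k}.
#' @export
fit_negbin_ar1 <- function(series, spec = ar1_spec("negbin"),
                           normalized = FALSE) {
  if (!inherits(series, "gene_series"))
    stop("fit_negbin_ar1 needs a gene_series (replicate structure)")
  if (spec$likelihood != "negbin") spec$likelihood <- "negbin"
  reps <- table(series$times)
  if (all(reps < 2L))
    stop("no replicated time points; use the Poisson AR(1) model instead")
  check_count_series(series$values, normalized)
  utimes <- sort(unique(series$times))
  m <- length(utimes)
  if (m < 4L) stop("AR(1) model needs at least 4 time points")
  if (all(series$values == 0))
    return(summarize_ar1(series$gene_id, NULL, spec, degenerate = TRUE,
                         note = "all-zero series"))
  tidx <- match(series$times, utimes)
  offset <- resolve_offset(spec, series$lib_sizes, length(series$values))
  draws <- ar1_mcmc(series$values, tidx, offset, m, spec)
  summarize_ar1(series$gene_id, draws, spec)
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s AR(1) fit: gene %s\n",
              x$spec$likelihood, x$gene_id))
  if (x$degenerate) {
    cat("  degenerate series (", x$note, "): call EE\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  phi: mean %.3f, 95%% CI [%.3f, %.3f]\n",
              mean(x$draws$phi), x$ci95[1], x$ci95[2]))
  cat(sprintf("  tail probability %.3f -> call %s\n", x$tail_prob, x$call))
  if (!is.null(x$draws$k))
    cat(sprintf("  NB size k: posterior median %.2f\n", median(x$draws$k)))
  invisible(x)
}

#' @export
coef.ar1_fit <- function(object, ...) {
  if (object$degenerate) return(c(phi = NA_real_, beta = NA_real_,
                                  sigma2 = NA_real_))
  out <- c(phi = mean(object$draws$phi), beta = mean(object$draws$beta),
           sigma2 = mean(object$draws$sigma2))
  if (!is.null(object$draws$k)) out <- c(out, k = median(object$draws$k))
  out
}

#' @export
summary.ar1_fit <- function(object, ...) {
  if (object$degenerate) return(print(object))
  print(object)
  cat("  acceptance rates:\n")
  print(round(object$accept, 3))
  invisible(object)
}

#' Gene-by-gene AR(1) screen within one condition
#'
#' Fits the Poisson or negative-binomial AR(1) model to every gene in a
#' condition and tabulates the credible-interval TDE calls and tail
#' probabilities. Per-gene seeds are derived deterministically from the
#' master seed, so the screen is reproducible and resumable; a sampler
#' failure on one gene is flagged, not fatal.
#'
#' @param exp a \code{\link{tse}} object (raw counts are used).
#' @param condition condition label or \code{"pooled"}.
#' @param spec an \code{\link{ar1_spec}}.
#' @param keep_draws retain the per-gene posterior draws in the result's
#'   \code{"fits"} attribute.
#' @return A data.frame of class \code{"ar1_result"} with columns
#'   gene_id, phi_mean, ci95_low, ci95_high, tail_prob, call, note.
#' @export
run_ar1 <- function(exp, condition = "pooled", spec = ar1_spec(),
                    keep_draws = FALSE) {
  stopifnot(inherits(exp, "tse"))
  if (!identical(condition, "pooled") &&
      !condition %in% exp$samples$condition)
    stop("condition not present in experiment: ", condition)
  genes <- gene_ids(exp)
  out <- data.frame(gene_id = genes, phi_mean = NA_real_,
                    ci95_low = NA_real_, ci95_high = NA_real_,
                    tail_prob = NA_real_, call = NA_character_,
                    note = "", stringsAsFactors = FALSE)
  fits <- if (keep_draws) vector("list", length(genes))
  for (g in seq_along(genes)) {
    s <- gene_series(exp, genes[g], condition, use_raw = TRUE)
    gspec <- spec
    gspec$seed <- (spec$seed + 104729L * g) %% .Machine$integer.max
    fit <- tryCatch(
      if (spec$likelihood == "poisson") fit_poisson_ar1(s, gspec)
      else fit_negbin_ar1(s, gspec),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$note[g] <- conditionMessage(fit)
      next
    }
    out$phi_mean[g] <- if (fit$degenerate) NA_real_ else mean(fit$draws$phi)
    out$ci95_low[g] <- fit$ci95[1]
    out$ci95_high[g] <- fit$ci95[2]
    out$tail_prob[g] <- fit$tail_prob
    out$call[g] <- fit$call
    if (!is.null(fit$note)) out$note[g] <- fit$note
    if (keep_draws) fits[[g]] <- fit
  }
  class(out) <- c("ar1_result", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "condition") <- condition
  if (keep_draws) attr(out, "fits") <- fits
  out
}

#' @export
print.ar1_result <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("AR(1) %s screen: %d genes, condition %s, %d iterations\n",
              spec$likelihood, nrow(x), attr(x, "condition"), spec$n_iter))
  cat(sprintf("  TDE: %d, EE: %d, failed/flagged: %d\n",
              sum(x$call == "TDE", na.rm = TRUE),
              sum(x$call == "EE", na.rm = TRUE), sum(is.na(x$call))))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Posterior summaries of the autocorrelation, graphically
#'
#' Trace and histogram of the post-burn-in draws of phi, with the 95%
#' credible interval marked.
#'
#' @param x an \code{"ar1_fit"}.
#' @param ... unused.
#' @export
plot.ar1_fit <- function(x, ...) {
  if (x$degenerate) {
    warning("degenerate fit: nothing to plot")
    return(invisible(x))
  }
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$draws$phi, type = "l", xlab = "iteration (post burn-in)",
       ylab = expression(phi), main = x$gene_id)
  hist(x$draws$phi, breaks = 40, main = "",
       xlab = expression(phi), freq = FALSE)
  abline(v = x$ci95, lty = 2, col = "firebrick")
  invisible(x)
}

#' Simulate count series from the posterior of a fitted AR(1) model
#'
#' Posterior predictive draws: each simulation samples one retained
#' MCMC draw of (phi, beta, sigma2[, k]) and generates a fresh latent
#' path and counts of the fitted length.
#'
#' @param object an \code{"ar1_fit"}.
#' @param nsim number of series to simulate.
#' @param seed optional seed.
#' @param ... unused.
#' @return Integer matrix, \code{nsim} rows by m columns.
#' @export
simulate.ar1_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$degenerate) stop("degenerate fit: no posterior draws")
  if (!is.null(seed)) set.seed(seed)
  m <- length(object$w_mean)
  nb <- !is.null(object$draws$k)
  out <- matrix(0L, nsim, m)
  rows <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  for (i in seq_len(nsim)) {
    d <- object$draws[rows[i], ]
    w <- numeric(m)
    w[1] <- rnorm(1, 0, sqrt(d$sigma2 / (1 - d$phi^2)))
    for (j in seq_len(m - 1))
      w[j + 1] <- d$phi * w[j] + rnorm(1, 0, sqrt(d$sigma2))
    mu <- exp(pmin(w + d$beta, 30))
    out[i, ] <- if (nb) rnbinom(m, size = d$k, mu = mu)
                else rpois(m, mu)
  }
  out
}
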