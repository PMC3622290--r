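#' Specification of a gold-standard simulated time-series dataset
#'
#' Describes the generative design used to benchmark TDE callers:
#' equally expressed (EE) genes carry a latent white-noise path
#' (\eqn{\phi = 0}); temporally differentially expressed (TDE) genes a
#' latent stationary Gaussian AR(1) path with \eqn{\phi} drawn from
#' \code{phi_values}. The latent path maps through a log link to Poisson
#' (or negative-binomial) counts.
#'
#' @param n_genes number of genes (default 1000).
#' @param phi_values autocorrelations used for TDE genes (default 0.1,
#'   0.25, 0.5, 0.75, 0.9).
#' @param prop_tde fraction of TDE genes (default 0.5), split evenly
#'   across \code{phi_values}.
#' @param nT number of time points (5 or 10 in the benchmark grid).
#' @param nR replicates per time point (1, 3 or 5).
#' @param beta_range baseline log-mean drawn Uniform over this range.
#' @param sigma innovation standard deviation of the latent path.
#' @param likelihood \code{"poisson"} or \code{"negbin"}.
#' @param nb_k NB size parameter when \code{likelihood = "negbin"}.
#' @param constant_ee when TRUE, EE genes have a strictly constant mean
#'   (no latent noise at all) — useful for calibrating static tests.
#' @param seed master seed; per-gene seeds are derived from it.
#' @return A list of class \code{"sim_spec"}.
#' @export
sim_spec <- function(n_genes = 1000,
                     phi_values = c(0.1, 0.25, 0.5, 0.75, 0.9),
                     prop_tde = 0.5, nT = 10, nR = 1,
                     beta_range = c(1, 5), sigma = 0.5,
                     likelihood = c("poisson", "negbin"), nb_k = 5,
                     constant_ee = FALSE, seed = 1) {
  likelihood <- match.arg(likelihood)
  stopifnot(all(abs(phi_values) < 1), nT >= 2, sigma > 0,
            prop_tde >= 0, prop_tde <= 1, nR >= 1)
  structure(list(n_genes = n_genes, phi_values = phi_values,
                 prop_tde = prop_tde, nT = nT, nR = nR,
                 beta_range = beta_range, sigma = sigma,
                 likelihood = likelihood, nb_k = nb_k,
                 constant_ee = constant_ee, seed = seed),
            class = "sim_spec")
}

#' Simulate one gene's latent AR(1) path and counts
#'
#' The latent path is the stationary Gaussian AR(1) process
#' \eqn{w_1 \sim N(0, \sigma^2/(1-\phi^2))},
#' \eqn{w_j = \phi w_{j-1} + u_j}, \eqn{u_j \sim N(0, \sigma^2)}; the
#' mean at time j is \eqn{\mu_j = e^{w_j + \beta}} and the \code{nR}
#' replicates at time j are drawn iid Poisson(\eqn{\mu_j}) or
#' NB(k, \eqn{\mu_j}).
#'
#' @param phi autocorrelation, |phi| < 1.
#' @param beta baseline log-mean.
#' @param sigma innovation sd.
#' @param nT,nR time points and replicates per time point.
#' @param likelihood \code{"poisson"} or \code{"negbin"}.
#' @param nb_k NB size parameter.
#' @param seed integer seed (deterministic output).
#' @param constant_mu strictly constant mean \eqn{e^\beta} (EE
#'   calibration mode; the latent path is all zero).
#' @return List with \code{counts} (nT x nR matrix), \code{w} (latent
#'   path), \code{mu}.
#' @export
simulate_gene <- function(phi, beta, sigma, nT, nR = 1,
                          likelihood = "poisson", nb_k = 5, seed = 1,
                          constant_mu = FALSE) {
  stopifnot(abs(phi) < 1, sigma > 0, nT >= 2, nR >= 1)
  set.seed(seed)
  if (constant_mu) {
    w <- rep(0, nT)
  } else {
    w <- numeric(nT)
    w[1] <- rnorm(1, 0, sigma / sqrt(1 - phi^2))
    if (nT > 1)
      for (j in 2:nT) w[j] <- phi * w[j - 1] + rnorm(1, 0, sigma)
  }
  if (any(abs(w + beta) > 30))
    stop("latent log-mean exceeds overflow guard; reduce sigma or beta")
  mu <- exp(w + beta)
  counts <- matrix(0L, nT, nR)
  for (j in seq_len(nT)) {
    counts[j, ] <- if (likelihood == "poisson") rpois(nR, mu[j])
                   else rnbinom(nR, size = nb_k, mu = mu[j])
  }
  list(counts = counts, w = w, mu = mu)
}

#' Simulate a gold-standard benchmark dataset
#'
#' Generates independent genes under \code{\link{simulate_gene}} with
#' known per-gene truth (EE/TDE label, true \eqn{\phi} and \eqn{\beta}),
#' packaged as a \code{\link{tse}} plus a truth table. EE genes have
#' \eqn{\phi = 0}; TDE genes are split evenly across the \eqn{\phi}
#' grid. Per-gene seeds derive from the master seed, so the dataset is
#' bit-reproducible.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return A list of class \code{"sim_dataset"}: \code{experiment} (a
#'   \code{tse}), \code{truth} (data.frame: gene_id, label, phi, beta),
#'   \code{latent} (genes x times matrix of latent paths), \code{spec}.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_genes
  n_tde <- round(spec$prop_tde * n)
  phis <- c(rep(0, n - n_tde),
            spec$phi_values[1 + (seq_len(n_tde) - 1) %%
                              length(spec$phi_values)])
  set.seed(spec$seed)
  betas <- runif(n, spec$beta_range[1], spec$beta_range[2])
  counts <- matrix(0L, n, spec$nT * spec$nR)
  latent <- matrix(0, n, spec$nT)
  for (g in seq_len(n)) {
    gs <- (spec$seed + 15485863 + g) %% .Machine$integer.max
    sim <- simulate_gene(phis[g], betas[g], spec$sigma, spec$nT, spec$nR,
                         spec$likelihood, spec$nb_k, seed = gs,
                         constant_mu = spec$constant_ee && phis[g] == 0)
    counts[g, ] <- as.integer(t(sim$counts))  # time-major, reps within
    latent[g, ] <- sim$w
  }
  gene_id <- sprintf("gene%04d", seq_len(n))
  rownames(counts) <- gene_id
  rownames(latent) <- gene_id
  colnames(counts) <- paste0("t", rep(seq_len(spec$nT), each = spec$nR),
                             "r", rep(seq_len(spec$nR), spec$nT))
  exp <- tse(counts,
             time = rep(seq_len(spec$nT), each = spec$nR),
             condition = rep("sim", ncol(counts)),
             replicate = rep(seq_len(spec$nR), spec$nT))
  truth <- data.frame(gene_id = gene_id,
                      label = ifelse(phis == 0, "EE", "TDE"),
                      phi = phis, beta = betas,
                      stringsAsFactors = FALSE)
  structure(list(experiment = exp, truth = truth, latent = latent,
                 spec = spec),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated benchmark: %d genes (%d TDE / %d EE), nT=%d, nR=%d, %s counts\n",
              nrow(x$truth), sum(x$truth$label == "TDE"),
              sum(x$truth$label == "EE"), x$spec$nT, x$spec$nR,
              x$spec$likelihood))
  invisible(x)
}

#' Recall and precision of a caller against simulated truth
#'
#' @param calls data.frame with columns \code{gene_id} and \code{call}
#'   (\code{"TDE"} counts as positive; anything else negative).
#' @param truth the \code{truth} table of a \code{\link{simulate_dataset}}
#'   result (or a \code{sim_dataset}).
#' @return List with \code{recall} (TP/(TP+FN) over true-TDE genes),
#'   \code{precision} (TP/(TP+FP), NA when nothing is called),
#'   \code{recall_by_phi} (named vector over the true phi grid), and the
#'   confusion counts.
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(truth, "sim_dataset")) truth <- truth$truth
  if (!all(c("gene_id", "call") %in% names(calls)))
    stop("calls needs gene_id and call columns")
  idx <- match(truth$gene_id, calls$gene_id)
  if (anyNA(idx))
    stop("calls missing genes present in truth: ",
         paste(head(truth$gene_id[is.na(idx)]), collapse = ", "))
  pos <- calls$call[idx] == "TDE" & !is.na(calls$call[idx])
  true_tde <- truth$label == "TDE"
  tp <- sum(pos & true_tde); fp <- sum(pos & !true_tde)
  fn <- sum(!pos & true_tde); tn <- sum(!pos & !true_tde)
  phis <- sort(unique(truth$phi[true_tde]))
  recall_by_phi <- vapply(phis, function(p) {
    sel <- truth$phi == p & true_tde
    mean(pos[sel])
  }, numeric(1))
  names(recall_by_phi) <- as.character(phis)
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall_by_phi = recall_by_phi,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}
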