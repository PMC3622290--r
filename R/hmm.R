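#' Enumerate set-partition expression states
#'
#' At one time point, the relationship among the C condition means is a
#' set partition of the condition labels: conditions in one block share
#' a latent mean. The number of states is the Bell number B(C) — 2 for
#' C = 2 (EE/DE), 15 for C = 4. States are coded as restricted growth
#' strings ("1111", "1221", ..., "1234"): block numbers in order of
#' first appearance. Enumeration is lexicographic, so the all-equal
#' partition comes first and the all-distinct partition last.
#'
#' @param C number of biological conditions (1..8; the state space grows
#'   as the Bell number, 4140 at C = 8).
#' @return A list of partition states; each has \code{code} (character)
#'   and \code{blocks} (list of integer vectors of condition indices).
#' @examples
#' length(enumerate_partitions(4))  # 15
#' enumerate_partitions(2)[[2]]$code  # "12" — the DE state
#' @export
enumerate_partitions <- function(C) {
  if (C < 1L) stop("C must be at least 1")
  if (C > 8L)
    stop("state space too large: Bell(", C, ") states; C <= 8 supported")
  codes <- list(1L)
  if (C > 1L) {
    for (pos in 2:C) {
      codes <- unlist(lapply(codes, function(a) {
        lapply(seq_len(max(a) + 1L), function(b) c(a, b))
      }), recursive = FALSE)
    }
  }
  lapply(codes, function(a) {
    structure(list(code = paste(a, collapse = ""),
                   blocks = unname(split(seq_len(C), a))),
              class = "partition_state")
  })
}

#' @export
print.partition_state <- function(x, ...) {
  cat(sprintf("partition state [%s]: %s\n", x$code,
              paste(vapply(x$blocks, paste, "", collapse = "="),
                    collapse = " | ")))
  invisible(x)
}

#' Gamma-Poisson marginal log-density of one time point under a state
#'
#' Conditions in one block of the partition share a latent Poisson rate
#' \eqn{\lambda \sim Gamma(\alpha, \beta)} (shape/rate). Integrating
#' \eqn{\lambda} out gives, per block with counts \eqn{y_1..y_n},
#' \eqn{S = \sum y_c}:
#' \deqn{\log f = \alpha\log\beta - \log\Gamma(\alpha)
#'   + \log\Gamma(\alpha + S) - (\alpha + S)\log(\beta + n)
#'   - \sum_c \log(y_c!)}
#' and the joint predictive density of the time point is the product
#' over blocks.
#'
#' @param counts non-negative integer vector, one pooled count per
#'   condition.
#' @param state a partition state from \code{\link{enumerate_partitions}}.
#' @param alpha,beta positive gamma hyperparameters.
#' @return Log predictive density (finite).
#' @export
gp_marginal_density <- function(counts, state, alpha, beta) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma hyperparameters must be positive")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  ld <- -sum(lfactorial(counts))
  for (blk in state$blocks) {
    S <- sum(counts[blk]); n <- length(blk)
    ld <- ld + alpha * log(beta) - lgamma(alpha) +
      lgamma(alpha + S) - (alpha + S) * log(beta + n)
  }
  ld
}

# NB marginal of one block: replicated counts share a latent mean
# lambda ~ Gamma(alpha, beta), y ~ NB(size = k, mu = lambda); the
# integral over lambda has no closed form and is done by quadrature on
# a log-scaled integrand. k -> Inf recovers the gamma-Poisson marginal.
block_nb_marginal <- function(y, alpha, beta, k) {
  logf <- function(lam)
    dgamma(lam, shape = alpha, rate = beta, log = TRUE) +
      vapply(lam, function(l)
        sum(dnbinom(y, size = k, mu = l, log = TRUE)), numeric(1))
  lam0 <- max((alpha + sum(y)) / (beta + length(y)), 1e-3)
  scale <- logf(lam0)
  val <- integrate(function(l) exp(logf(l) - scale), 0, Inf,
                   rel.tol = 1e-10, stop.on.error = FALSE)$value
  log(val) + scale
}

#' Negative-binomial marginal log-density with replicates
#'
#' Emission for replicated designs: all replicates of all conditions in
#' one block share a latent mean \eqn{\lambda \sim Gamma(\alpha,\beta)};
#' counts are NB with size k (variance \eqn{\mu + \mu^2/k}) around it,
#' and \eqn{\lambda} is integrated out numerically. In the
#' dispersion-to-zero limit (k large) this coincides with
#' \code{\link{gp_marginal_density}} applied to the summed counts.
#'
#' @param counts list with one non-negative integer vector of replicate
#'   counts per condition.
#' @param state a partition state.
#' @param alpha,beta positive gamma hyperparameters on the shared mean.
#' @param k NB size parameter (estimated by method of moments across
#'   genes in \code{\link{tde_hmm}}).
#' @return Log predictive density.
#' @export
nb_marginal_density <- function(counts, state, alpha, beta, k) {
  if (alpha <= 0 || beta <= 0 || k <= 0)
    stop("hyperparameters must be positive")
  if (!is.list(counts))
    stop("counts must be a list of per-condition replicate vectors")
  ld <- 0
  for (blk in state$blocks) {
    y <- unlist(counts[blk], use.names = FALSE)
    if (any(y < 0) || any(y != round(y)))
      stop("counts must be non-negative integers")
    ld <- ld + block_nb_marginal(y, alpha, beta, k)
  }
  ld
}

#' Construct a partition-state hidden Markov model
#'
#' One homogeneous Markov chain over the Bell(C) partition states is
#' shared by all genes; emissions at each time point are the
#' gamma-Poisson (\code{"gp"}, no replicates) or negative-binomial
#' (\code{"nbd"}, replicated) block marginals.
#'
#' @param C number of conditions.
#' @param A row-stochastic S x S transition matrix.
#' @param pi0 initial state distribution (length S, sums to 1).
#' @param alpha,beta emission hyperparameters (shared across times).
#' @param emission \code{"gp"} or \code{"nbd"}.
#' @param k NB size parameter (nbd only).
#' @return A list of class \code{"hmm_model"}.
#' @export
hmm_model <- function(C, A, pi0, alpha, beta, emission = c("gp", "nbd"),
                      k = NULL) {
  emission <- match.arg(emission)
  states <- enumerate_partitions(C)
  S <- length(states)
  A <- as.matrix(A)
  if (!all(dim(A) == S)) stop("A must be ", S, " x ", S)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-10))
    stop("A must be row-stochastic")
  if (length(pi0) != S || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-10)
    stop("pi0 must be a length-", S, " probability vector")
  if (alpha <= 0 || beta <= 0) stop("alpha, beta must be positive")
  structure(list(C = C, states = states, A = A, pi0 = as.numeric(pi0),
                 alpha = alpha, beta = beta, emission = emission, k = k),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Partition-state HMM: C=%d conditions, %d states, %s emissions\n",
              x$C, length(x$states), x$emission))
  cat(sprintf("  alpha=%.3g, beta=%.3g%s\n", x$alpha, x$beta,
              if (!is.null(x$k)) sprintf(", k=%.3g", x$k) else ""))
  invisible(x)
}

# emission log-density matrix for one gene: times x states
emission_logdens <- function(model, counts) {
  states <- model$states
  if (model$emission == "gp") {
    x <- as.matrix(counts)  # m x C
    matrix(vapply(states, function(st)
      apply(x, 1L, gp_marginal_density, state = st,
            alpha = model$alpha, beta = model$beta),
      numeric(nrow(x))), nrow = nrow(x))
  } else {
    # counts: list over times, each a list of per-condition replicate
    # vectors
    do.call(rbind, lapply(counts, function(xt)
      vapply(states, nb_marginal_density, numeric(1), counts = xt,
             alpha = model$alpha, beta = model$beta, k = model$k)))
  }
}

# scaled forward-backward on a log-emission matrix (m x S)
fb_core <- function(logB, A, pi0) {
  m <- nrow(logB); S <- ncol(logB)
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, m, S); cvec <- numeric(m)
  a <- pi0 * B[1L, ]
  cvec[1L] <- sum(a); alpha[1L, ] <- a / cvec[1L]
  if (m > 1L) for (t in 2:m) {
    a <- (alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, m, S); beta[m, ] <- 1
  if (m > 1L) for (t in (m - 1L):1L) {
    b <- A %*% (B[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- as.numeric(b) / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # expected transition counts, summed over t
  xi <- matrix(0, S, S)
  if (m > 1L) for (t in 1:(m - 1L)) {
    x <- outer(alpha[t, ], B[t + 1L, ] * beta[t + 1L, ]) * A / cvec[t + 1L]
    xi <- xi + x
  }
  list(gamma = gamma, xi = xi,
       loglik = sum(log(cvec)) + sum(shift))
}

#' Posterior state probabilities for one gene
#'
#' Scaled forward-backward recursions over the partition-state chain.
#'
#' @param counts for \code{"gp"} emissions, an m x C matrix of counts
#'   (times by conditions); for \code{"nbd"}, a list over times of lists
#'   of per-condition replicate vectors. Ignored when
#'   \code{log_emissions} is supplied.
#' @param model an \code{\link{hmm_model}}.
#' @param log_emissions optional precomputed m x S log-emission matrix
#'   (overrides \code{counts}).
#' @return List with \code{posterior} (m x S, rows sum to 1),
#'   \code{loglik}, and \code{xi} (expected transition counts).
#' @export
forward_backward <- function(counts, model, log_emissions = NULL) {
  logB <- if (is.null(log_emissions)) emission_logdens(model, counts)
          else as.matrix(log_emissions)
  if (ncol(logB) != length(model$states))
    stop("log-emission matrix has wrong number of states")
  out <- fb_core(logB, model$A, model$pi0)
  list(posterior = out$gamma, loglik = out$loglik, xi = out$xi)
}

#' Most likely state path for one gene
#'
#' Max-product (Viterbi) decoding; ties break toward the lower state
#' index, i.e. toward the all-equal partition.
#'
#' @inheritParams forward_backward
#' @return Integer vector of state indices (1 = all-equal partition),
#'   with the state codes as names.
#' @export
viterbi <- function(counts, model, log_emissions = NULL) {
  logB <- if (is.null(log_emissions)) emission_logdens(model, counts)
          else as.matrix(log_emissions)
  m <- nrow(logB); S <- ncol(logB)
  logA <- log(model$A); logpi <- log(model$pi0)
  delta <- matrix(-Inf, m, S); psi <- matrix(0L, m, S)
  delta[1L, ] <- logpi + logB[1L, ]
  if (m > 1L) for (t in 2:m) {
    for (s in seq_len(S)) {
      cand <- delta[t - 1L, ] + logA[, s]
      psi[t, s] <- which.max(cand)   # first max: lower index wins ties
      delta[t, s] <- cand[psi[t, s]] + logB[t, s]
    }
  }
  path <- integer(m)
  path[m] <- which.max(delta[m, ])
  if (m > 1L) for (t in (m - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  names(path) <- vapply(model$states[path], `[[`, "", "code")
  path
}

# genes x times x conditions array of pooled counts (gp), or nested
# list [[gene]][[time]][[condition]] of replicate vectors (nbd)
hmm_data <- function(exp, emission) {
  conds <- sort(unique(exp$samples$condition))
  times <- sort(unique(exp$samples$time))
  G <- nrow(exp$counts)
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  if (emission == "gp") {
    x <- array(0L, dim = c(G, length(times), length(conds)))
    for (ti in seq_along(times)) for (ci in seq_along(conds)) {
      sel <- exp$samples$time == times[ti] &
             exp$samples$condition == conds[ci]
      if (!any(sel)) stop("design cell empty: time ", times[ti],
                          ", condition ", conds[ci])
      x[, ti, ci] <- as.integer(round(rowSums(raw[, sel, drop = FALSE])))
    }
    x
  } else {
    lapply(seq_len(G), function(g)
      lapply(seq_along(times), function(ti)
        lapply(seq_along(conds), function(ci) {
          sel <- exp$samples$time == times[ti] &
                 exp$samples$condition == conds[ci]
          as.integer(round(raw[g, sel]))
        })))
  }
}

moments_gamma_hyper <- function(x) {
  m1 <- mean(x); v <- var(x)
  beta <- if (v > m1) m1 / (v - m1) else 1
  alpha <- max(m1 * beta, 1e-3)
  c(alpha = alpha, beta = max(beta, 1e-4))
}

moments_nb_k <- function(exp) {
  raw <- if (!is.null(exp$raw_counts)) exp$raw_counts else exp$counts
  cell <- paste(exp$samples$time, exp$samples$condition)
  mus <- c(); vs <- c()
  for (cl in unique(cell)) {
    sel <- cell == cl
    if (sum(sel) < 2L) next
    mus <- c(mus, rowMeans(raw[, sel, drop = FALSE]))
    vs <- c(vs, apply(raw[, sel, drop = FALSE], 1L, var))
  }
  if (!length(mus)) return(1e6)
  excess <- sum(pmax(vs - mus, 0))
  if (excess <= 0) return(1e6)
  max(sum(mus^2) / excess, 0.1)
}

#' Fit the partition-state HMM by expectation-maximization
#'
#' All genes share one homogeneous chain over the Bell(C) partition
#' states. The E-step runs forward-backward per gene; the M-step
#' re-estimates the transition matrix and initial distribution from
#' expected transition/occupancy counts and, for gamma-Poisson
#' emissions, the hyperparameters (alpha, beta) by maximizing the
#' expected complete-data log-likelihood (shared across times). The
#' observed-data log-likelihood is non-decreasing over iterations; EM
#' stops at relative tolerance \code{tol} or \code{max_iter}. Several
#' random restarts guard against poor local optima.
#'
#' @param exp a \code{\link{tse}} with at least 2 conditions.
#' @param emission \code{"gp"} (counts pooled within condition, no
#'   replication assumed) or \code{"nbd"} (replicates kept; NB size by
#'   method of moments, hyperparameters fixed at moment estimates).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood tolerance.
#' @param restarts random restarts (best final likelihood kept).
#' @param seed seed for the restart jitter.
#' @param update_hyper re-estimate (alpha, beta) in the M-step
#'   (gp only).
#' @return A list of class \code{"hmm_fit"}: \code{model} (the fitted
#'   \code{\link{hmm_model}}), \code{posterior} (genes x times x states),
#'   \code{viterbi} (genes x times state indices), \code{loglik_trace},
#'   \code{occupancy} (times x states posterior mass — the mixture
#'   proportions of the per-time marginal), \code{gene_ids},
#'   \code{times}, \code{conditions}.
#' @export
tde_hmm <- function(exp, emission = c("gp", "nbd"), max_iter = 200,
                    tol = 1e-6, restarts = 3, seed = 1,
                    update_hyper = NULL) {
  stopifnot(inherits(exp, "tse"))
  emission <- match.arg(emission)
  conds <- sort(unique(exp$samples$condition))
  C <- length(conds)
  if (C < 2L) stop("HMM needs at least 2 biological conditions")
  times <- sort(unique(exp$samples$time))
  m <- length(times)
  G <- nrow(exp$counts)
  if (is.null(update_hyper)) update_hyper <- emission == "gp"
  x <- hmm_data(exp, emission)
  states <- enumerate_partitions(C)
  S <- length(states)
  pooled <- if (emission == "gp") as.numeric(x)
            else unlist(x, use.names = FALSE)
  hyper0 <- moments_gamma_hyper(pooled)
  k <- if (emission == "nbd") moments_nb_k(exp) else NULL

  emis_array <- function(alpha, beta) {
    # genes x times x states log emissions
    arr <- array(0, dim = c(G, m, S))
    if (emission == "gp") {
      lfact <- rowSums(array(lfactorial(x), dim = dim(x)), dims = 2L)
      for (s in seq_len(S)) {
        ls <- matrix(-lgamma(alpha) * 0, G, m)
        for (blk in states[[s]]$blocks) {
          Sb <- rowSums(array(x[, , blk, drop = FALSE],
                              dim = c(G, m, length(blk))), dims = 2L)
          n <- length(blk)
          ls <- ls + alpha * log(beta) - lgamma(alpha) +
            lgamma(alpha + Sb) - (alpha + Sb) * log(beta + n)
        }
        arr[, , s] <- ls - lfact
      }
    } else {
      for (g in seq_len(G)) for (ti in seq_len(m)) for (s in seq_len(S))
        arr[g, ti, s] <- nb_marginal_density(x[[g]][[ti]], states[[s]],
                                             alpha, beta, k)
    }
    arr
  }

  run_em <- function(A, pi0, alpha, beta) {
    logB <- emis_array(alpha, beta)
    trace <- numeric(0)
    post <- array(0, dim = c(G, m, S))
    for (it in seq_len(max_iter)) {
      xi_tot <- matrix(0, S, S); g1 <- numeric(S); ll <- 0
      for (g in seq_len(G)) {
        fb <- fb_core(matrix(logB[g, , ], m, S), A, pi0)
        post[g, , ] <- fb$gamma
        xi_tot <- xi_tot + fb$xi
        g1 <- g1 + fb$gamma[1L, ]
        ll <- ll + fb$loglik
      }
      if (length(trace) && ll < trace[length(trace)] -
            1e-6 * (abs(ll) + 1))
        stop("EM log-likelihood decreased: ", trace[length(trace)],
             " -> ", ll)
      converged <- length(trace) &&
        abs(ll - trace[length(trace)]) <=
          tol * (abs(trace[length(trace)]) + 1)
      trace <- c(trace, ll)
      if (converged) break
      # M-step
      pi0 <- g1 / sum(g1)
      pi0 <- pmax(pi0, 1e-12); pi0 <- pi0 / sum(pi0)
      rs <- rowSums(xi_tot)
      A_new <- xi_tot / ifelse(rs > 0, rs, 1)
      A_new[rs == 0, ] <- 1 / S
      A <- pmax(A_new, 1e-12); A <- A / rowSums(A)
      if (update_hyper) {
        qfun <- function(par) {
          al <- exp(par[1]); be <- exp(par[2])
          lb <- emis_array(al, be)
          -sum(post * lb)
        }
        op <- optim(log(c(alpha, beta)), qfun, method = "Nelder-Mead",
                    control = list(maxit = 60))
        alpha <- exp(op$par[1]); beta <- exp(op$par[2])
        logB <- emis_array(alpha, beta)
      }
    }
    list(A = A, pi0 = pi0, alpha = alpha, beta = beta, post = post,
         trace = trace, loglik = trace[length(trace)], logB = logB)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    if (r == 1L) {
      A <- matrix((1 - 0.8) / max(S - 1, 1), S, S); diag(A) <- 0.8
      if (S == 1L) A <- matrix(1, 1, 1)
      pi0 <- rep(1 / S, S)
      alpha <- hyper0["alpha"]; beta <- hyper0["beta"]
    } else {
      A <- matrix(runif(S * S, 0.1, 1), S, S); A <- A / rowSums(A)
      pi0 <- runif(S, 0.1, 1); pi0 <- pi0 / sum(pi0)
      alpha <- hyper0["alpha"] * exp(runif(1, -0.5, 0.5))
      beta <- hyper0["beta"] * exp(runif(1, -0.5, 0.5))
    }
    fit <- run_em(A, pi0, unname(alpha), unname(beta))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  model <- hmm_model(C, best$A, best$pi0, best$alpha, best$beta,
                     emission = emission, k = k)
  vit <- t(vapply(seq_len(G), function(g)
    unname(viterbi(NULL, model,
                   log_emissions = matrix(best$logB[g, , ], m, S))),
    integer(m)))
  occupancy <- apply(best$post, c(2, 3), mean)
  structure(list(model = model, posterior = best$post, viterbi = vit,
                 loglik_trace = best$trace, occupancy = occupancy,
                 gene_ids = gene_ids(exp), times = times,
                 conditions = conds),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Partition-state HMM fit: %d genes, %d times, %d states (%s emissions)\n",
              length(x$gene_ids), length(x$times),
              length(x$model$states), x$model$emission))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations\n",
              x$loglik_trace[length(x$loglik_trace)],
              length(x$loglik_trace)))
  cat(sprintf("  DE-anywhere (Viterbi): %d genes\n",
              sum(apply(x$viterbi != 1L, 1L, any))))
  invisible(x)
}

#' Per-gene temporal pattern calls from a fitted HMM
#'
#' At each time point a gene is EE when the decoded state is the
#' all-equal partition and DE otherwise. The pattern string joins the
#' per-time calls ("EE-DE-EE"); \code{state_path} keeps the full
#' partition codes. Under the posterior rule a time point is DE when
#' the posterior mass on non-equal states reaches \code{tau}.
#'
#' @param fit an \code{"hmm_fit"} from \code{\link{tde_hmm}}.
#' @param rule \code{"viterbi"} or \code{"posterior"}.
#' @param tau posterior threshold (default 0.5).
#' @return data.frame with gene_id, pattern, state_path, de_anywhere.
#' @export
call_patterns <- function(fit, rule = c("viterbi", "posterior"),
                          tau = 0.5) {
  rule <- match.arg(rule)
  codes <- vapply(fit$model$states, `[[`, "", "code")
  m <- length(fit$times)
  if (rule == "viterbi") {
    de <- fit$viterbi != 1L
    path <- matrix(codes[fit$viterbi], nrow = nrow(fit$viterbi))
  } else {
    pde <- 1 - fit$posterior[, , 1L, drop = FALSE]
    de <- matrix(pde >= tau, nrow = dim(fit$posterior)[1])
    amax <- apply(fit$posterior, c(1, 2), which.max)
    path <- matrix(codes[amax], nrow = nrow(amax))
  }
  pattern <- apply(de, 1L, function(z)
    paste(ifelse(z, "DE", "EE"), collapse = "-"))
  state_path <- apply(path, 1L, paste, collapse = "-")
  data.frame(gene_id = fit$gene_ids, pattern = pattern,
             state_path = state_path,
             de_anywhere = apply(de, 1L, any),
             stringsAsFactors = FALSE)
}
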