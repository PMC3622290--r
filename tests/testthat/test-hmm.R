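bell_recursion <- function(n) {
  # B(n+1) = sum_k C(n,k) B(k)
  B <- numeric(n + 1); B[1] <- 1
  for (i in seq_len(n))
    B[i + 1] <- sum(choose(i - 1, 0:(i - 1)) * B[1:i])
  B[n + 1]
}

test_that("partition states enumerate Bell numbers in canonical order", {
  ps4 <- enumerate_partitions(4)
  expect_length(ps4, 15L)
  codes <- vapply(ps4, `[[`, "", "code")
  expect_equal(codes[1], "1111")
  expect_equal(codes[15], "1234")
  # the named states printed for four tissues all appear
  expect_true(all(c("1221", "1222", "1121", "1212", "1233") %in% codes))
  expect_false(anyDuplicated(codes) > 0)

  expect_length(enumerate_partitions(1), 1L)
  ps2 <- enumerate_partitions(2)
  expect_equal(vapply(ps2, `[[`, "", "code"), c("11", "12"))
  expect_length(enumerate_partitions(5), 52L)
  for (C in 1:8)
    expect_length(enumerate_partitions(C), bell_recursion(C))
  expect_error(enumerate_partitions(9), "state space")
})

test_that("gamma-Poisson marginal equals the analytic and quadrature forms", {
  st1 <- enumerate_partitions(1)[[1]]
  for (y in c(0L, 3L, 17L)) for (al in c(0.5, 2)) for (be in c(0.5, 3)) {
    got <- gp_marginal_density(y, st1, al, be)
    analytic <- lgamma(y + al) - lgamma(al) - lfactorial(y) +
      al * log(be / (be + 1)) - y * log(be + 1)
    expect_equal(got, analytic, tolerance = 1e-12)
    quad <- integrate(function(l) dpois(y, l) *
                        dgamma(l, al, rate = be), 0, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(got, log(quad), tolerance = 1e-8)
  }
  expect_error(gp_marginal_density(1L, st1, -1, 1), "positive")
})

test_that("equal counts favour the shared-mean state", {
  st <- enumerate_partitions(2)
  for (y in 0:20) for (al in c(1, 4)) for (be in c(0.5, 2)) {
    ee <- gp_marginal_density(c(y, y), st[[1]], al, be)
    de <- gp_marginal_density(c(y, y), st[[2]], al, be)
    expect_gte(ee, de)
  }
})

test_that("the joint predictive normalizes over a truncated grid", {
  st <- enumerate_partitions(2)
  total <- 0
  for (y1 in 0:60) for (y2 in 0:60)
    total <- total + exp(gp_marginal_density(c(y1, y2), st[[1]], 2, 1.5))
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("NB marginal handles replicates and recovers the Poisson limit", {
  st <- enumerate_partitions(2)
  reps_eq <- list(c(5L, 6L), c(5L, 6L))
  ee <- nb_marginal_density(reps_eq, st[[1]], 2, 0.4, k = 10)
  de <- nb_marginal_density(reps_eq, st[[2]], 2, 0.4, k = 10)
  expect_gte(ee, de)

  for (y in list(c(0L, 4L), c(12L, 7L))) {
    lim <- nb_marginal_density(list(y[1], y[2]), st[[2]], 1.5, 0.8,
                               k = 1e8)
    gp <- gp_marginal_density(y, st[[2]], 1.5, 0.8)
    expect_equal(lim, gp, tolerance = 1e-4)
  }
  expect_error(nb_marginal_density(list(1L, 2L), st[[1]], 0, 1, 5),
               "positive")
  # all-zero block is a proper limit, not an error
  expect_true(is.finite(nb_marginal_density(list(0L, 0L), st[[1]],
                                            1, 1, 5)))
})

test_that("forward-backward matches exhaustive path enumeration", {
  A <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  pi0 <- c(0.6, 0.4)
  model <- hmm_model(2, A, pi0, alpha = 1, beta = 1)
  set.seed(12)
  for (rep in 1:5) {
    logB <- matrix(log(runif(6, 0.05, 1)), 3, 2)
    fb <- forward_backward(NULL, model, log_emissions = logB)
    oracle <- hmm_enum_oracle(logB, A, pi0)
    expect_equal(fb$posterior, oracle$posterior, tolerance = 1e-12)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-12)
    expect_equal(rowSums(fb$posterior), rep(1, 3), tolerance = 1e-12)
    vit <- viterbi(NULL, model, log_emissions = logB)
    expect_equal(unname(vit), unname(oracle$viterbi))
  }
})

test_that("degenerate chains behave as closed forms dictate", {
  m1 <- hmm_model(1, matrix(1, 1, 1), 1, alpha = 1, beta = 1)
  fb <- forward_backward(matrix(c(3L, 1L, 4L), 3, 1), m1)
  expect_equal(as.numeric(fb$posterior), rep(1, 3))
  expect_equal(unname(viterbi(matrix(c(3L, 1L, 4L), 3, 1), m1)),
               rep(1L, 3))

  # uniform emissions: posteriors are the pure-chain marginals
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  pi0 <- c(0.3, 0.7)
  model <- hmm_model(2, A, pi0, alpha = 1, beta = 1)
  logB <- matrix(0, 4, 2)
  fb <- forward_backward(NULL, model, log_emissions = logB)
  marg <- pi0
  for (t in 1:4) {
    expect_equal(fb$posterior[t, ], marg, tolerance = 1e-12)
    marg <- as.numeric(marg %*% A)
  }
})

sim_hmm_counts <- function(G, m, A, pi0, seed, sep = 6) {
  # 2 conditions; EE state shares one rate, DE state uses two rates
  set.seed(seed)
  counts <- matrix(0L, G, 2 * m)
  states <- matrix(0L, G, m)
  for (g in seq_len(G)) {
    s <- numeric(m)
    s[1] <- sample(1:2, 1, prob = pi0)
    for (t in seq_len(m - 1)) s[t + 1] <- sample(1:2, 1, prob = A[s[t], ])
    states[g, ] <- s
    for (t in seq_len(m)) {
      if (s[t] == 1) {
        lam <- rgamma(1, 30, 1); l1 <- l2 <- lam
      } else {
        l1 <- rgamma(1, 30, 1); l2 <- l1 * sep
      }
      counts[g, t] <- rpois(1, l1)
      counts[g, m + t] <- rpois(1, l2)
    }
  }
  rownames(counts) <- sprintf("g%04d", seq_len(G))
  exp <- tse(counts, time = rep(1:m, 2),
             condition = rep(c("A", "B"), each = m),
             replicate = rep(1L, 2 * m))
  list(exp = exp, states = states)
}

test_that("EM recovers the transition matrix and keeps likelihood monotone", {
  A_true <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  sim <- sim_hmm_counts(400, 5, A_true, c(0.5, 0.5), seed = 8, sep = 8)
  fit <- tde_hmm(sim$exp, "gp", max_iter = 80, restarts = 2, seed = 1)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-6 * (abs(fit$loglik_trace[-1]) + 1)))
  expect_lt(max(abs(fit$model$A - A_true)), 0.1)
  expect_true(all(abs(rowSums(fit$model$A) - 1) < 1e-10))

  # decoded states track the truth on well-separated emissions
  acc <- mean(fit$viterbi == sim$states)
  expect_gt(acc, 0.9)
})

test_that("EE-only data concentrates occupancy on the all-equal state", {
  A_true <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)  # absorbing EE
  sim <- sim_hmm_counts(120, 4, A_true, c(1, 0), seed = 3)
  fit <- tde_hmm(sim$exp, "gp", max_iter = 60, restarts = 1, seed = 2)
  expect_true(all(fit$occupancy[, 1] > 0.8))
})

test_that("pattern calls map decoded states to EE/DE strings", {
  model <- hmm_model(4, diag(0.9, 15) + matrix(0.1 / 14, 15, 15) -
                       diag(0.1 / 14, 15),
                     rep(1 / 15, 15), alpha = 1, beta = 1)
  codes <- vapply(model$states, `[[`, "", "code")
  i1212 <- which(codes == "1212")
  post <- array(0, dim = c(1, 3, 15))
  post[1, 1, 1] <- 1; post[1, 2, i1212] <- 1; post[1, 3, 1] <- 1
  fit <- structure(list(model = model, posterior = post,
                        viterbi = matrix(c(1L, i1212, 1L), 1),
                        loglik_trace = 0, occupancy = NULL,
                        gene_ids = "g1", times = 1:3,
                        conditions = LETTERS[1:4]),
                   class = "hmm_fit")
  pat <- call_patterns(fit, "viterbi")
  expect_equal(pat$pattern, "EE-DE-EE")
  expect_equal(pat$state_path, "1111-1212-1111")
  expect_true(pat$de_anywhere)

  fit$viterbi <- matrix(c(1L, 1L, 1L), 1)
  fit$posterior[1, 2, ] <- c(1, rep(0, 14))
  expect_false(call_patterns(fit, "viterbi")$de_anywhere)
})

test_that("raising the posterior threshold never adds DE calls", {
  A_true <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE)
  sim <- sim_hmm_counts(80, 4, A_true, c(0.5, 0.5), seed = 5, sep = 2)
  fit <- tde_hmm(sim$exp, "gp", max_iter = 50, restarts = 1, seed = 4)
  de_50 <- call_patterns(fit, "posterior", tau = 0.5)$de_anywhere
  de_99 <- call_patterns(fit, "posterior", tau = 0.99)$de_anywhere
  expect_true(all(!de_99 | de_50))

  # tau = 0.5 posterior rule agrees with Viterbi on separated data
  sim2 <- sim_hmm_counts(80, 4, A_true, c(0.5, 0.5), seed = 6, sep = 8)
  fit2 <- tde_hmm(sim2$exp, "gp", max_iter = 50, restarts = 1, seed = 4)
  agree <- mean(call_patterns(fit2, "posterior", 0.5)$de_anywhere ==
                  call_patterns(fit2, "viterbi")$de_anywhere)
  expect_gte(agree, 0.95)
})

test_that("the nbd emission route fits replicated factorial designs", {
  set.seed(9)
  G <- 40; m <- 4; nR <- 2
  counts <- matrix(0L, G, 2 * m * nR)
  de_gene <- rep(c(FALSE, TRUE), each = G / 2)
  for (g in seq_len(G)) {
    for (t in seq_len(m)) {
      lam <- rgamma(1, 20, 1)
      l2 <- if (de_gene[g]) lam * 6 else lam
      for (r in seq_len(nR)) {
        counts[g, (t - 1) * nR + r] <- rnbinom(1, mu = lam, size = 8)
        counts[g, m * nR + (t - 1) * nR + r] <-
          rnbinom(1, mu = l2, size = 8)
      }
    }
  }
  rownames(counts) <- sprintf("g%03d", seq_len(G))
  exp <- tse(counts,
             time = rep(rep(1:m, each = nR), 2),
             condition = rep(c("A", "B"), each = m * nR),
             replicate = rep(rep(1:nR, m), 2))
  fit <- tde_hmm(exp, "nbd", max_iter = 15, restarts = 1, seed = 7)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-6 * (abs(fit$loglik_trace[-1]) + 1)))
  calls <- call_patterns(fit)$de_anywhere
  expect_gt(mean(calls[de_gene]), mean(calls[!de_gene]))
})
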