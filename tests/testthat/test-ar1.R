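test_that("Poisson AR(1) recovers a strong autocorrelation", {
  s <- simulate_gene(0.9, 3, 0.5, nT = 60, seed = 2)
  fit <- fit_poisson_ar1(as.numeric(rowSums(s$counts)),
                         ar1_spec("poisson", n_iter = 4000,
                                  n_burnin = 1000, offset = "none",
                                  seed = 5))
  expect_s3_class(fit, "ar1_fit")
  expect_lt(abs(mean(fit$draws$phi) - 0.9), 0.15)
  expect_gt(fit$ci95[1], 0)
  expect_equal(fit$call, "TDE")
  expect_true(all(abs(fit$ci95) < 1))
  expect_gte(fit$tail_prob, 0.5)
})

test_that("credible-interval classification matches the interval sign rule", {
  for (seed in 1:4) {
    s <- simulate_gene(ifelse(seed %% 2, 0, 0.8), 3, 0.5, nT = 12,
                       seed = seed)
    fit <- fit_poisson_ar1(as.numeric(rowSums(s$counts)),
                           ar1_spec("poisson", n_iter = 1500,
                                    n_burnin = 400, offset = "none",
                                    seed = seed))
    expected <- if (fit$ci95[1] > 0 || fit$ci95[2] < 0) "TDE" else "EE"
    expect_identical(fit$call, expected)
    # tail probability consistent with the posterior draws
    expect_equal(fit$tail_prob,
                 max(mean(fit$draws$phi > 0), mean(fit$draws$phi < 0)))
  }
})

test_that("degenerate and invalid series are handled", {
  expect_error(fit_poisson_ar1(c(1.5, 2, 3, 4), normalized = TRUE),
               "raw")
  z <- fit_poisson_ar1(rep(0, 8), ar1_spec("poisson"))
  expect_true(z$degenerate)
  expect_equal(z$call, "EE")
  expect_error(fit_poisson_ar1(c(1, 2, 3)), "4 time points")
})

test_that("MCMC draws are bit-reproducible under a fixed seed", {
  s <- simulate_gene(0.5, 2, 0.5, nT = 15, seed = 3)
  spec <- ar1_spec("poisson", n_iter = 800, n_burnin = 200,
                   offset = "none", seed = 77)
  f1 <- fit_poisson_ar1(as.numeric(rowSums(s$counts)), spec)
  f2 <- fit_poisson_ar1(as.numeric(rowSums(s$counts)), spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("acceptance rates stay in a workable Metropolis range", {
  s <- simulate_gene(0.75, 3, 0.5, nT = 30, seed = 6)
  fit <- fit_poisson_ar1(as.numeric(rowSums(s$counts)),
                         ar1_spec("poisson", n_iter = 2000,
                                  n_burnin = 600, offset = "none",
                                  seed = 2))
  acc <- fit$accept[c("w", "beta", "phi")]
  expect_true(all(acc > 0.1 & acc < 0.7))
})

test_that("negative-binomial AR(1) needs replicates and recovers k", {
  sim <- simulate_dataset(sim_spec(n_genes = 1, phi_values = 0.75,
                                   prop_tde = 1, nT = 10, nR = 3,
                                   beta_range = c(3, 3), sigma = 0.5,
                                   likelihood = "negbin", nb_k = 5,
                                   seed = 4))
  s <- gene_series(sim$experiment, 1, use_raw = TRUE)
  fit <- fit_negbin_ar1(s, ar1_spec("negbin", n_iter = 3000,
                                    n_burnin = 800, offset = "none",
                                    seed = 9))
  expect_true(!is.null(fit$draws$k))
  expect_gte(median(fit$draws$k), 1)
  expect_lte(median(fit$draws$k), 30)

  nore <- gene_series(
    simulate_dataset(sim_spec(n_genes = 1, nT = 8, nR = 1,
                              seed = 2))$experiment, 1, use_raw = TRUE)
  expect_error(fit_negbin_ar1(nore), "Poisson")
})

test_that("NB model approaches the Poisson model when dispersion vanishes", {
  # same latent path, nearly Poisson NB counts
  agree <- 0L
  n <- 20L
  for (g in seq_len(n)) {
    s <- simulate_gene(0.6, 3, 0.5, nT = 10, nR = 2,
                       likelihood = "negbin", nb_k = 1e6,
                       seed = 100 + g)
    exp1 <- tse(matrix(as.integer(t(s$counts)), 1, 20,
                       dimnames = list("g", NULL)),
                time = rep(1:10, each = 2),
                condition = rep("A", 20), replicate = rep(1:2, 10))
    series <- gene_series(exp1, 1, use_raw = TRUE)
    fn <- fit_negbin_ar1(series, ar1_spec("negbin", n_iter = 1200,
                                          n_burnin = 400,
                                          offset = "none",
                                          seed = 11 + g))
    fp <- fit_poisson_ar1(series, ar1_spec("poisson", n_iter = 1200,
                                           n_burnin = 400,
                                           offset = "none",
                                           seed = 11 + g))
    if (fn$call == fp$call) agree <- agree + 1L
  }
  expect_gte(agree / n, 0.9)
})

test_that("the gene-by-gene screen is reproducible and robust", {
  sim <- simulate_dataset(sim_spec(n_genes = 12, nT = 10, nR = 1,
                                   phi_values = 0.9, prop_tde = 0.5,
                                   seed = 15))
  spec <- ar1_spec("poisson", n_iter = 600, n_burnin = 200, seed = 3)
  t1 <- run_ar1(sim$experiment, spec = spec)
  t2 <- run_ar1(sim$experiment, spec = spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$call %in% c("TDE", "EE")))
  expect_error(run_ar1(sim$experiment, condition = "nope", spec = spec),
               "condition")
})

test_that("the sampler preserves the joint prior-data distribution", {
  # successive-conditional simulation: alternate data regeneration and
  # one sampler sweep; the stationary law of (phi, sigma2) must be the
  # prior. Tight test priors so the moments exist.
  for (cfg in list(list(m = 6, bsd = 1), list(m = 10, bsd = 0.5))) {
    m <- cfg$m
    spec <- ar1_spec("poisson", n_iter = 2, n_burnin = 1,
                     beta_sd = cfg$bsd, sigma_shape = 3, sigma_rate = 3,
                     offset = "none")
    set.seed(99 + m)
    st <- {
      phi <- runif(1, -1, 1)
      sig2 <- 1 / rgamma(1, 3, rate = 3)
      w <- numeric(m)
      w[1] <- rnorm(1, 0, sqrt(sig2 / (1 - phi^2)))
      for (j in 2:m) w[j] <- phi * w[j - 1] + rnorm(1, 0, sqrt(sig2))
      list(w = w, beta = rnorm(1, 0, cfg$bsd), sigma2 = sig2,
           phi = phi, k = 5)
    }
    N <- 2500
    phis <- sig2s <- numeric(N)
    for (i in seq_len(N)) {
      y <- rpois(m, exp(pmin(st$w + st$beta, 20)))
      sp <- spec; sp$seed <- 1000 + i
      out <- tsdyn:::ar1_mcmc(y, seq_len(m), rep(0, m), m, sp,
                              init = st, return_state = TRUE)
      st <- out$state
      phis[i] <- st$phi; sig2s[i] <- st$sigma2
    }
    # prior: phi ~ U(-1,1) (mean 0, var 1/3); sigma2 ~ IG(3,3) (mean 1.5)
    expect_lt(abs(mean(phis)), 0.1)
    expect_gt(var(phis), 0.25); expect_lt(var(phis), 0.42)
    expect_gt(mean(sig2s), 1.2); expect_lt(mean(sig2s), 1.8)
  }
})
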