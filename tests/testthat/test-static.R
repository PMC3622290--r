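test_that("Fisher's exact test reproduces hand-enumerated values", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")

  tab <- contingency_2x2(4, 9, 100, 120)
  expect_equal(sum(tab), 220)
  expect_error(contingency_2x2(4, 9, 3, 120), "non-negative")

  # swap the two groups: identical two-sided p
  set.seed(16)
  for (i in 1:50) {
    t1 <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact(t1), fisher_exact(t1[, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with full-support enumeration", {
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), fisher_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("Audic-Claverie closed form and tails behave", {
  expect_equal(audic_claverie(0, 0)$predictive_prob, 0.5)
  expect_equal(audic_claverie(1, 1)$predictive_prob, 0.25)
  # predictive probability is symmetric in the two counts
  for (x in c(0, 2, 9)) for (y in c(1, 5))
    expect_equal(audic_claverie(x, y)$predictive_prob,
                 audic_claverie(y, x)$predictive_prob,
                 tolerance = 1e-12)
  # normalization and flat-prior predictive mean x + 1
  for (x in c(0L, 7L, 50L)) {
    yy <- 0:(20 * (x + 2))
    pr <- vapply(yy, function(y)
      audic_claverie(x, y)$predictive_prob, numeric(1))
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_equal(sum(yy * pr), x + 1, tolerance = 1e-8)
  }
  p <- audic_claverie(2, 40)$p_value
  expect_gt(p, 0); expect_lt(p, 1e-6)
  expect_equal(audic_claverie(5, 5)$p_value, 1)
  expect_error(audic_claverie(3, 3, lib1 = 100, lib2 = 200), "unequal")
  gen <- audic_claverie(3, 6, lib1 = 100, lib2 = 200, unequal = TRUE)
  expect_gt(gen$p_value, 0.5)  # 3 vs 6 matches the 1:2 depth ratio
  expect_error(audic_claverie(-1, 2), "non-negative")
})

test_that("log-linear LRT flags strong time effects and not flat genes", {
  set.seed(10)
  tt <- rep(1:5, each = 2)
  hits <- 0L
  for (i in 1:40) {
    y <- rpois(10, 20 * 2^(tt - 1))  # doubling mean per time step
    r <- poisson_loglinear_lrt(y, tt, likelihood = "poisson")
    expect_gte(r$statistic, 0)
    if (r$p_value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)

  flat <- poisson_loglinear_lrt(rpois(10, 20), tt,
                                likelihood = "poisson")
  expect_gt(flat$p_value, 0.001)
  expect_error(poisson_loglinear_lrt(rpois(4, 5), rep(1, 4)),
               "2 time levels")
})

test_that("the NB variant engages under replicated overdispersion", {
  set.seed(13)
  tt <- rep(1:4, each = 3)
  y <- rnbinom(12, mu = 50, size = 2)
  r <- poisson_loglinear_lrt(y, tt, likelihood = "auto")
  expect_equal(r$likelihood, "negbin")
  # factorial design: interaction terms included
  y2 <- rpois(16, 30)
  r2 <- poisson_loglinear_lrt(y2, rep(1:4, 4),
                              condition = rep(c("A", "B"), each = 8),
                              likelihood = "poisson")
  expect_equal(r2$df, 6L)  # 3 time + 3 interaction dof
})

test_that("union-of-pairwise calling has union semantics and full detail", {
  set.seed(18)
  G <- 30; m <- 4
  counts <- matrix(rpois(G * m, 50), G, m)
  counts[1, 3] <- 600L  # one gene DE in comparisons involving t3
  rownames(counts) <- paste0("g", seq_len(G))
  exp <- make_exp(counts + 0L, time = 1:m)
  res <- union_pairwise_tde(exp, "fisher")
  expect_equal(res$call[res$gene_id == "g1"], "TDE")
  detail <- attr(res, "detail")
  expect_equal(nrow(detail), G * choose(m, 2))
  expect_equal(unique(res$n_comparisons), choose(m, 2))

  res_ac <- union_pairwise_tde(exp, "ac")
  expect_equal(res_ac$call[res_ac$gene_id == "g1"], "TDE")

  expect_error(make_exp(matrix(rpois(4, 10), 4, 1,
                               dimnames = list(paste0("g", 1:4), "s1")),
                        time = 1),
               "2 distinct time")
})

test_that("union calling across more comparisons inflates false positives", {
  # flat experiment: more admissible pairs -> more union FDR calls
  set.seed(33)
  G <- 120
  mk <- function(m) {
    counts <- matrix(rpois(G * m, exp(rnorm(G, 5, 1))), G, m)
    rownames(counts) <- paste0("g", seq_len(G))
    make_exp(counts + 0L, time = seq_len(m))
  }
  few <- union_pairwise_tde(mk(2), "fisher")
  many <- union_pairwise_tde(mk(8), "fisher")
  expect_gte(sum(many$call == "TDE"), sum(few$call == "TDE"))
})

test_that("the gene-wise LRT screen assembles a calibrated table", {
  sim <- simulate_dataset(sim_spec(n_genes = 25, nT = 6, nR = 2,
                                   prop_tde = 0, constant_ee = TRUE,
                                   seed = 21))
  tab <- run_loglinear(sim$experiment)
  expect_named(tab, c("gene_id", "statistic", "df", "p_value", "fdr",
                      "call"))
  ok <- !is.na(tab$p_value)
  expect_true(all(tab$p_value[ok] >= 0 & tab$p_value[ok] <= 1))
  expect_lte(sum(tab$call[ok] == "TDE"), 3)
})
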