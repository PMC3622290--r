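# tsdyn — dynamic statistics for RNA-seq time series

RNA-seq time courses measure read counts for thousands of genes at a
handful of time points, often with few or no replicates. The common
workaround — running a static two-sample test for every pair of time
points and unioning the calls, or fitting a pooled factor model —
ignores that expression at one time point is correlated with the
previous one, inflating false discoveries and missing genuinely
temporal genes. `tsdyn` is for analysts of developmental, disease-course
or treatment time series who want calls of *temporally differential
expression* (TDE) that model the serial dependence directly.

The package implements:

* **SETI** — the statistical evolutionary trajectory index: a cubic
  smoothing spline per gene, the residual autocorrelation
  `ACR(k) = Σ_j r_j r_{j+k} / ((m−k) σ²)` aggregated over all lags,
  with permutation significance (N = 10,000), a residual-bootstrap
  trimmed mean and 95% CI (B = 100), and BH FDR across genes.
* **Bayesian AR(1) count models** — Poisson or negative-binomial
  observations around a latent stationary Gaussian AR(1) path
  (`log μ_j = w_j + β`, `w_j = φ w_{j−1} + u_j`), fit by
  Metropolis-within-Gibbs MCMC (C++ core; 6,000 iterations, 1,000
  burn-in). A gene is TDE when the 95% credible interval of φ excludes
  0; the tail probability of φ ranks genes.
* **A partition-state HMM** for factorial designs: at each time point
  the hidden state is a set partition of the condition labels
  (Bell(C) states; 15 for four conditions), with gamma-Poisson or
  negative-binomial empirical-Bayes emissions, one homogeneous chain
  shared by all genes, EM fitting, forward-backward and Viterbi
  decoding, and per-time EE/DE pattern calls ("EE-DE-EE").
* **Coupled-trajectory metrics** — Granger causality on spline
  residuals, the Glass d-score `d = (r_ij − r̄_i)/s_{r_i}` with a
  permutation null, and lagged correlation — screened over all pairs
  of TDE genes.
* **Static baselines** — Fisher's exact test, the Audic-Claverie
  statistic `p(y|x) = 2^{−(x+y+1)} C(x+y, x)`, a Poisson/NB log-linear
  LRT, and union-of-pairwise calling — for head-to-head comparison.
* **A gold-standard simulator** (latent AR(1) → Poisson/NB counts with
  known EE/TDE labels) and recall/precision evaluation.

See `vignettes/tsdyn-methods.Rmd` for the models, priors, numerical
choices and their rationale.

## Worked example

Simulate a 60-gene benchmark (half EE, half TDE across the φ grid) and
screen it with the Poisson AR(1) model:

```r
library(tsdyn)
sim <- simulate_dataset(sim_spec(n_genes = 60, nT = 10, nR = 1, seed = 42))
fit <- run_ar1(sim$experiment,
               spec = ar1_spec("poisson", n_iter = 4000, n_burnin = 1000,
                               seed = 1))
fit
#> AR(1) poisson screen: 60 genes, condition pooled, 4000 iterations
#>   TDE: 7, EE: 53, failed/flagged: 0
#>     gene_id phi_mean ci95_low ci95_high tail_prob call note
#> 1  gene0001  0.35034   -0.559     0.922     0.844   EE
#> 2  gene0002 -0.13756   -0.769     0.592     0.671   EE
#> ...

ev <- evaluate_calls(fit, sim)
round(unlist(ev[c("recall", "precision")]), 3)
#>    recall precision
#>     0.233     1.000
round(ev$recall_by_phi, 2)
#>  0.1 0.25  0.5 0.75  0.9
#> 0.00 0.17 0.17 0.17 0.67
```

Each row is one gene: the posterior mean and 95% credible interval of
its autocorrelation φ, the tail probability max{P(φ>0|y), P(φ<0|y)},
and the TDE/EE call. With only ten time points the credible-interval
rule is conservative — recall rises steeply with φ (67% at φ = 0.9
here) while precision stays at 1: every gene it calls is genuinely
temporal. `run_seti()` gives the permutation/bootstrap analogue,
`tde_hmm()` + `call_patterns()` the factorial pattern classification,
and `union_pairwise_tde()` the static union baseline for comparison.

A thin command-line front end with `seti`, `ar1`, `hmm`, `couple`,
`static`, `simulate` and `evaluate` subcommands is in
`inst/scripts/tsdyn.R`.

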