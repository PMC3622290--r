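#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Bayesian AR(1) count model:
//   y_obs ~ Poisson(mu) or NB(k, mu),  log mu = w_{t(obs)} + beta + offset
//   w_1 ~ N(0, s2/(1-phi^2))  (stationary; literal s2*(1-phi^2) optional)
//   w_j | w_{j-1} ~ N(phi * w_{j-1}, s2)
//   beta ~ N(0, beta_sd^2), s2 ~ InvGamma(sig_a, sig_b), phi ~ U(-1, 1),
//   log k ~ N(logk_mu, logk_sd^2) for the NB likelihood.
// Single-site random-walk updates for w and beta, Fisher-z random walk
// for phi, conjugate inverse-gamma draw for s2, random walk on log k.
// Step sizes adapt toward 0.44 acceptance during burn-in only.

static inline double obs_loglik(double y, double logmu, int likelihood,
                                double k) {
  if (likelihood == 0) {  // Poisson
    return y * logmu - std::exp(logmu) - std::lgamma(y + 1.0);
  }
  double mu = std::exp(logmu);
  return std::lgamma(y + k) - std::lgamma(k) - std::lgamma(y + 1.0) +
         k * (std::log(k) - std::log(mu + k)) +
         y * (logmu - std::log(mu + k));
}

// log prior of the latent path given (phi, s2); c1 multiplies w_1^2
static inline double w1_prec_factor(double phi, bool stationary) {
  return stationary ? (1.0 - phi * phi) : 1.0 / (1.0 - phi * phi);
}

static inline double path_logdens(const std::vector<double>& w, double phi,
                                  double s2, bool stationary) {
  int m = w.size();
  double c1 = w1_prec_factor(phi, stationary);
  // N(0, s2/c1) for w_1 plus the AR transitions; constants in s2 kept
  // because the phi update changes the w_1 variance
  double ld = 0.5 * std::log(c1) - c1 * w[0] * w[0] / (2.0 * s2);
  for (int j = 1; j < m; ++j) {
    double e = w[j] - phi * w[j - 1];
    ld -= e * e / (2.0 * s2);
  }
  return ld;
}

// [[Rcpp::export]]
List ar1_mcmc_cpp(NumericVector y, IntegerVector tidx, NumericVector offset,
                  int m, int likelihood, int n_iter, int n_burnin,
                  bool stationary, double beta_sd, double sig_a,
                  double sig_b, double logk_mu, double logk_sd,
                  Nullable<List> init = R_NilValue,
                  bool return_state = false) {
  int n_obs = y.size();
  if (tidx.size() != n_obs || offset.size() != n_obs)
    stop("y, tidx and offset must have equal length");
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter");

  // observation indices per time point
  std::vector< std::vector<int> > at_time(m);
  for (int i = 0; i < n_obs; ++i) {
    if (tidx[i] < 1 || tidx[i] > m) stop("tidx out of range");
    at_time[tidx[i] - 1].push_back(i);
  }

  double ybar = 0.0, obar = 0.0;
  for (int i = 0; i < n_obs; ++i) { ybar += y[i]; obar += offset[i]; }
  ybar /= n_obs; obar /= n_obs;

  std::vector<double> w(m, 0.0);
  double beta = std::log(ybar + 0.5) - obar;
  double s2 = 0.25, phi = 0.0, logk = std::log(5.0);

  if (init.isNotNull()) {
    List st(init);
    NumericVector wi = st["w"];
    if ((int)wi.size() != m) stop("init$w has wrong length");
    for (int j = 0; j < m; ++j) w[j] = wi[j];
    beta = as<double>(st["beta"]);
    s2 = as<double>(st["sigma2"]);
    phi = as<double>(st["phi"]);
    if (st.containsElementNamed("k"))
      logk = std::log(as<double>(st["k"]));
  }

  double step_w = 0.5, step_beta = 0.2, step_phi = 0.5, step_k = 0.4;
  int acc_w = 0, try_w = 0, acc_beta = 0, try_beta = 0;
  int acc_phi = 0, try_phi = 0, acc_k = 0, try_k = 0;
  int keep = n_iter - n_burnin;
  NumericVector phi_draws(keep), beta_draws(keep), s2_draws(keep),
      k_draws(likelihood == 1 ? keep : 0);
  std::vector<double> w_sum(m, 0.0);

  RNGScope scope;
  int batch_acc_w = 0, batch_try_w = 0, batch_acc_b = 0, batch_try_b = 0;
  int batch_acc_p = 0, batch_try_p = 0, batch_acc_k = 0, batch_try_k = 0;

  for (int it = 0; it < n_iter; ++it) {
    double k = std::exp(logk);

    // --- latent path, one site at a time ---
    for (int j = 0; j < m; ++j) {
      double wprop = w[j] + step_w * R::norm_rand();
      double dlog = 0.0;
      for (size_t u = 0; u < at_time[j].size(); ++u) {
        int i = at_time[j][u];
        dlog += obs_loglik(y[i], wprop + beta + offset[i], likelihood, k) -
                obs_loglik(y[i], w[j] + beta + offset[i], likelihood, k);
      }
      if (j == 0) {
        double c1 = w1_prec_factor(phi, stationary);
        dlog -= c1 * (wprop * wprop - w[0] * w[0]) / (2.0 * s2);
        if (m > 1) {
          double en = w[1] - phi * wprop, eo = w[1] - phi * w[0];
          dlog -= (en * en - eo * eo) / (2.0 * s2);
        }
      } else {
        double en = wprop - phi * w[j - 1], eo = w[j] - phi * w[j - 1];
        dlog -= (en * en - eo * eo) / (2.0 * s2);
        if (j < m - 1) {
          double fn = w[j + 1] - phi * wprop, fo = w[j + 1] - phi * w[j];
          dlog -= (fn * fn - fo * fo) / (2.0 * s2);
        }
      }
      ++try_w; ++batch_try_w;
      if (std::log(R::unif_rand()) < dlog) {
        w[j] = wprop; ++acc_w; ++batch_acc_w;
      }
    }

    // --- intercept ---
    {
      double bprop = beta + step_beta * R::norm_rand();
      double dlog = -(bprop * bprop - beta * beta) /
                    (2.0 * beta_sd * beta_sd);
      for (int i = 0; i < n_obs; ++i)
        dlog += obs_loglik(y[i], w[tidx[i] - 1] + bprop + offset[i],
                           likelihood, k) -
                obs_loglik(y[i], w[tidx[i] - 1] + beta + offset[i],
                           likelihood, k);
      ++try_beta; ++batch_try_b;
      if (std::log(R::unif_rand()) < dlog) {
        beta = bprop; ++acc_beta; ++batch_acc_b;
      }
    }

    // --- innovation variance: conjugate inverse-gamma ---
    {
      double c1 = w1_prec_factor(phi, stationary);
      double rate = sig_b + 0.5 * c1 * w[0] * w[0];
      for (int j = 1; j < m; ++j) {
        double e = w[j] - phi * w[j - 1];
        rate += 0.5 * e * e;
      }
      double shape = sig_a + 0.5 * m;
      double prec = R::rgamma(shape, 1.0 / rate);
      s2 = 1.0 / prec;
    }

    // --- autocorrelation, Fisher-z random walk; U(-1,1) prior ---
    {
      double z = std::atanh(phi);
      double zprop = z + step_phi * R::norm_rand();
      double pprop = std::tanh(zprop);
      // Jacobian of phi = tanh(z): dphi/dz = 1 - phi^2
      double dlog = path_logdens(w, pprop, s2, stationary) -
                    path_logdens(w, phi, s2, stationary) +
                    std::log1p(-pprop * pprop) - std::log1p(-phi * phi);
      ++try_phi; ++batch_try_p;
      if (std::log(R::unif_rand()) < dlog) {
        phi = pprop; ++acc_phi; ++batch_acc_p;
      }
    }

    // --- NB size parameter ---
    if (likelihood == 1) {
      double lkprop = logk + step_k * R::norm_rand();
      double kprop = std::exp(lkprop);
      double dlog = -((lkprop - logk_mu) * (lkprop - logk_mu) -
                      (logk - logk_mu) * (logk - logk_mu)) /
                    (2.0 * logk_sd * logk_sd);
      for (int i = 0; i < n_obs; ++i)
        dlog += obs_loglik(y[i], w[tidx[i] - 1] + beta + offset[i], 1,
                           kprop) -
                obs_loglik(y[i], w[tidx[i] - 1] + beta + offset[i], 1,
                           std::exp(logk));
      ++try_k; ++batch_try_k;
      if (std::log(R::unif_rand()) < dlog) {
        logk = lkprop; ++acc_k; ++batch_acc_k;
      }
    }

    // --- adapt step sizes during burn-in ---
    if (it < n_burnin && (it + 1) % 50 == 0) {
      double d = 0.1;
      if (batch_try_w > 0)
        step_w *= std::exp(((double)batch_acc_w / batch_try_w - 0.44) * d * 5);
      if (batch_try_b > 0)
        step_beta *= std::exp(((double)batch_acc_b / batch_try_b - 0.44) * d * 5);
      if (batch_try_p > 0)
        step_phi *= std::exp(((double)batch_acc_p / batch_try_p - 0.44) * d * 5);
      if (batch_try_k > 0)
        step_k *= std::exp(((double)batch_acc_k / batch_try_k - 0.44) * d * 5);
      batch_acc_w = batch_try_w = batch_acc_b = batch_try_b = 0;
      batch_acc_p = batch_try_p = batch_acc_k = batch_try_k = 0;
    }

    if (it >= n_burnin) {
      int r = it - n_burnin;
      phi_draws[r] = phi;
      beta_draws[r] = beta;
      s2_draws[r] = s2;
      if (likelihood == 1) k_draws[r] = std::exp(logk);
      for (int j = 0; j < m; ++j) w_sum[j] += w[j];
    }
  }

  NumericVector w_mean(m);
  for (int j = 0; j < m; ++j) w_mean[j] = w_sum[j] / keep;

  List out = List::create(
      _["phi"] = phi_draws, _["beta"] = beta_draws,
      _["sigma2"] = s2_draws, _["k"] = k_draws, _["w_mean"] = w_mean,
      _["accept"] = NumericVector::create(
          _["w"] = (double)acc_w / try_w,
          _["beta"] = (double)acc_beta / try_beta,
          _["phi"] = (double)acc_phi / try_phi,
          _["k"] = try_k > 0 ? (double)acc_k / try_k : NA_REAL));
  if (return_state) {
    out["state"] = List::create(
        _["w"] = NumericVector(w.begin(), w.end()), _["beta"] = beta,
        _["sigma2"] = s2, _["phi"] = phi, _["k"] = std::exp(logk));
  }
  return out;
}
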