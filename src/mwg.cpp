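#include <Rcpp.h>
using namespace Rcpp;

// Log posterior of one (stratum, month) cell on the sampling scale
// theta_d = log(sigma^2_d).  Records are collapsed to indicator patterns:
// X is P x D (0/1), n_p / S_p / SS_p are per-pattern count, sum(y), sum(y^2).
// A record with pattern p has marginal law Normal(sum_d mu_d, sum_d sigma2_d)
// because the latent components are independent Normals summed analytically.
// Priors: mu_d ~ Normal(0, mu_sd^2); theta_d ~ Normal(0, theta_sd^2)
// (equivalently sigma^2 ~ LogNormal(0, theta_sd^2); the Jacobian of
// theta = log sigma^2 is absorbed into the Normal density on theta).
static double cell_lp(const IntegerMatrix &X,
                      const NumericVector &n_p,
                      const NumericVector &S_p,
                      const NumericVector &SS_p,
                      const std::vector<double> &mu,
                      const std::vector<double> &sig2,
                      const std::vector<double> &theta,
                      double mu_sd, double theta_sd) {
  const int P = X.nrow(), D = X.ncol();
  double lp = 0.0;
  for (int p = 0; p < P; ++p) {
    double m = 0.0, v = 0.0;
    for (int d = 0; d < D; ++d) {
      if (X(p, d)) { m += mu[d]; v += sig2[d]; }
    }
    lp += -0.5 * n_p[p] * std::log(2.0 * M_PI * v)
          - (SS_p[p] - 2.0 * m * S_p[p] + n_p[p] * m * m) / (2.0 * v);
  }
  for (int d = 0; d < D; ++d) {
    lp += R::dnorm(mu[d], 0.0, mu_sd, 1);
    lp += R::dnorm(theta[d], 0.0, theta_sd, 1);
  }
  return lp;
}

// [[Rcpp::export(name = ".cpp_cell_lp")]]
double cpp_cell_lp(IntegerMatrix X, NumericVector n_p, NumericVector S_p,
                   NumericVector SS_p, NumericVector mu, NumericVector theta,
                   double mu_sd, double theta_sd) {
  const int D = X.ncol();
  std::vector<double> muv(D), s2(D), th(D);
  for (int d = 0; d < D; ++d) {
    muv[d] = mu[d];
    th[d] = theta[d];
    s2[d] = std::exp(theta[d]);
  }
  return cell_lp(X, n_p, S_p, SS_p, muv, s2, th, mu_sd, theta_sd);
}

// Adaptive (during warm-up only) random-walk Metropolis-within-Gibbs over
// (mu_1..mu_D, theta_1..theta_D).  Proposal scales follow a Robbins-Monro
// recursion toward 44% acceptance and are frozen at the end of warm-up so
// retained draws come from a time-homogeneous Markov chain.
// Returns an array [kept x (2D + 1) x chains]; the last slice is the
// log-posterior trace.
// [[Rcpp::export(name = ".cpp_mwg_sample")]]
NumericVector cpp_mwg_sample(IntegerMatrix X, NumericVector n_p,
                             NumericVector S_p, NumericVector SS_p,
                             double mu_sd, double theta_sd,
                             NumericMatrix mu_init, NumericMatrix theta_init,
                             NumericVector scale_init,
                             int n_iter, int n_warmup) {
  const int D = X.ncol();
  const int n_par = 2 * D;
  const int n_chains = mu_init.ncol();
  const int kept = n_iter - n_warmup;

  NumericVector out(static_cast<R_xlen_t>(kept) * (n_par + 1) * n_chains);
  out.attr("dim") = IntegerVector::create(kept, n_par + 1, n_chains);

  RNGScope scope;

  for (int c = 0; c < n_chains; ++c) {
    std::vector<double> mu(D), theta(D), sig2(D), ls(n_par);
    for (int d = 0; d < D; ++d) {
      mu[d] = mu_init(d, c);
      theta[d] = theta_init(d, c);
      sig2[d] = std::exp(theta[d]);
    }
    for (int j = 0; j < n_par; ++j) ls[j] = std::log(scale_init[j]);

    double lp = cell_lp(X, n_p, S_p, SS_p, mu, sig2, theta, mu_sd, theta_sd);

    for (int it = 0; it < n_iter; ++it) {
      for (int j = 0; j < n_par; ++j) {
        const int d = j % D;
        const bool is_mu = j < D;
        const double step = std::exp(ls[j]) * R::norm_rand();
        double saved_mu = mu[d], saved_th = theta[d], saved_s2 = sig2[d];
        if (is_mu) {
          mu[d] += step;
        } else {
          theta[d] += step;
          sig2[d] = std::exp(theta[d]);
        }
        const double lp_new =
            cell_lp(X, n_p, S_p, SS_p, mu, sig2, theta, mu_sd, theta_sd);
        const double acc_lp = lp_new - lp;
        bool accept = acc_lp >= 0.0 || R::unif_rand() < std::exp(acc_lp);
        if (accept) {
          lp = lp_new;
        } else {
          mu[d] = saved_mu;
          theta[d] = saved_th;
          sig2[d] = saved_s2;
        }
        if (it < n_warmup) {
          const double acc_prob =
              acc_lp >= 0.0 ? 1.0 : std::exp(acc_lp);
          const double gamma = std::min(0.25, 2.0 / std::sqrt(it + 1.0));
          ls[j] += gamma * (acc_prob - 0.44);
          if (ls[j] < -12.0) ls[j] = -12.0;
          if (ls[j] > 6.0) ls[j] = 6.0;
        }
      }
      if (it >= n_warmup) {
        const int row = it - n_warmup;
        for (int d = 0; d < D; ++d) {
          out[row + kept * d + static_cast<R_xlen_t>(kept) * (n_par + 1) * c] =
              mu[d];
          out[row + kept * (D + d) +
              static_cast<R_xlen_t>(kept) * (n_par + 1) * c] = theta[d];
        }
        out[row + kept * n_par +
            static_cast<R_xlen_t>(kept) * (n_par + 1) * c] = lp;
      }
      if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
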