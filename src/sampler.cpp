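#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Boyd-Richerson conformist-transmission term, centred at zero:
// f(x) = x - 1/2 + c * x (1 - x) (2x - 1).
static inline double ctrans(double x, double c) {
  return x - 0.5 + c * x * (1.0 - x) * (2.0 * x - 1.0);
}

// log(1 + exp(eta)) without overflow for |eta| up to ~700.
static inline double softplus(double eta) {
  if (eta > 0.0) return eta + std::log1p(std::exp(-eta));
  return std::log1p(std::exp(eta));
}

// One Metropolis-within-Gibbs chain for the conformist choice model.
//
// Two model shapes share this kernel:
//  * indicator model: theta = (beta1, beta2, beta3, c); the social predictor
//    column of X is selected by the categorical indicator m (1-based), which
//    is either fixed or updated from its closed-form full conditional
//    P(m = k) propto prior_k * L(data | theta, X_k);
//  * pair model: theta = (beta1, beta2, coef_1, shape_1, coef_2, shape_2)
//    with the two social terms bound to fixed columns in term_cols (0-based).
//
// Continuous parameters get random-walk normal proposals, accepted with
// probability min(1, posterior ratio); priors are iid Normal(prior_mean,
// precision prior_prec). update[j] == false pins theta[j] at init[j].
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List run_chain_cpp(NumericVector y, NumericVector side, NumericMatrix X,
                   IntegerVector term_cols, bool indicator, int fixed_m,
                   NumericVector ind_logprobs, double prior_mean,
                   double prior_prec, int n_iter, int n_burn, int thin,
                   NumericVector init, NumericVector scales,
                   LogicalVector update, bool adapt) {
  const int n = y.size();
  const int P = init.size();
  const int T = indicator ? 1 : term_cols.size();

  std::vector<double> th(init.begin(), init.end());
  std::vector<double> sc(scales.begin(), scales.end());

  auto loglik = [&](const std::vector<double>& theta, int m) -> double {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = theta[0] + theta[1] * side[i];
      if (indicator) {
        eta += theta[2] * ctrans(X(i, m - 1), theta[3]);
      } else {
        for (int t = 0; t < T; ++t)
          eta += theta[2 + 2 * t] * ctrans(X(i, term_cols[t]), theta[3 + 2 * t]);
      }
      ll += y[i] * eta - softplus(eta);
    }
    return ll;
  };

  int m = indicator ? (fixed_m > 0 ? fixed_m : 1) : 0;
  double cur_ll = loglik(th, m);

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, P + 1);
  std::vector<long> acc(P, 0);           // post-burn-in acceptances
  std::vector<int> win_acc(P, 0), win_n(P, 0);  // adaptation windows
  const int win_len = 50;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < P; ++j) {
      if (!update[j]) continue;
      std::vector<double> prop(th);
      prop[j] = th[j] + sc[j] * norm_rand();
      double prop_ll = loglik(prop, m);
      double dprior = -0.5 * prior_prec *
        ((prop[j] - prior_mean) * (prop[j] - prior_mean) -
         (th[j] - prior_mean) * (th[j] - prior_mean));
      double logr = prop_ll - cur_ll + dprior;
      bool accept = logr >= 0.0 || std::log(unif_rand()) < logr;
      if (accept) {
        th = prop;
        cur_ll = prop_ll;
      }
      if (it <= n_burn) {
        win_n[j]++;
        if (accept) win_acc[j]++;
        if (adapt && win_n[j] == win_len) {
          double rate = (double)win_acc[j] / win_len;
          if (rate < 0.2) sc[j] *= 0.8;
          else if (rate > 0.5) sc[j] *= 1.25;
          win_acc[j] = 0;
          win_n[j] = 0;
        }
      } else if (accept) {
        acc[j]++;
      }
    }

    if (indicator && fixed_m == 0) {
      double llk[3], lp[3];
      double mx = -INFINITY;
      for (int k = 0; k < 3; ++k) {
        llk[k] = (k + 1 == m) ? cur_ll : loglik(th, k + 1);
        lp[k] = ind_logprobs[k] + llk[k];
        if (lp[k] > mx) mx = lp[k];
      }
      double tot = 0.0, pk[3];
      for (int k = 0; k < 3; ++k) {
        pk[k] = std::exp(lp[k] - mx);
        tot += pk[k];
      }
      double u = unif_rand() * tot, cum = 0.0;
      int pick = 2;
      for (int k = 0; k < 3; ++k) {
        cum += pk[k];
        if (u <= cum) { pick = k; break; }
      }
      m = pick + 1;
      cur_ll = llk[pick];
    }

    if (it > n_burn && (it - n_burn) % thin == 0) {
      for (int j = 0; j < P; ++j) draws(kept, j) = th[j];
      draws(kept, P) = indicator ? (double)m : NA_REAL;
      kept++;
    }
  }

  NumericVector acc_rate(P);
  const double denom = n_iter - n_burn;
  for (int j = 0; j < P; ++j)
    acc_rate[j] = update[j] ? acc[j] / denom : NA_REAL;

  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["scales"] = NumericVector(sc.begin(), sc.end()));
}
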