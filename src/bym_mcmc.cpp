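// MCMC sampler for the Besag-York-Mollie model:
//   Y_i ~ Poisson(E_i * theta_i),  log theta_i = alpha + u_i + v_i
//   v_i ~ N(0, 1/tau_v) iid
//   u | tau_u ~ intrinsic CAR: density prop. to
//       exp(-(tau_u/2) * sum_{i~j} (u_i - u_j)^2)   (unique pairs)
//   alpha flat; tau_u, tau_v ~ Gamma(shape, rate) hyperpriors.
//
// Updates: single-site random-walk Metropolis for u_i and v_i,
// random-walk Metropolis for alpha, conjugate Gamma draws for both
// precisions, and a re-centring of u each sweep (the mean of u over
// non-island areas moves into alpha; islands keep u_i = 0 and their v
// absorbs the compensating shift so their likelihood is untouched).
// Proposal scales adapt toward 0.44 acceptance during burn-in only.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bym_mcmc_chain(IntegerVector Y, NumericVector E,
                    IntegerVector nb_index, IntegerVector nb_start,
                    LogicalVector island, int icar_rank,
                    int burn_in, int n_iter, int thin,
                    double a_u, double b_u, double a_v, double b_v,
                    double alpha0, NumericVector u0, NumericVector v0,
                    double tau_u0, double tau_v0) {
  const int n = Y.size();
  const int n_save = n_iter / thin;
  double alpha = alpha0, tau_u = tau_u0, tau_v = tau_v0;
  NumericVector u = clone(u0), v = clone(v0);
  int n_free = 0;                      // non-island areas
  for (int i = 0; i < n; ++i) if (!island[i]) ++n_free;
  for (int i = 0; i < n; ++i) if (island[i]) u[i] = 0.0;

  // adaptive random-walk scales (log scale), per site
  NumericVector ls_u(n, std::log(0.3)), ls_v(n, std::log(0.3));
  double ls_a = std::log(0.1);
  IntegerVector acc_u(n), acc_v(n);
  int acc_a = 0, batch = 0, batch_no = 0;
  IntegerVector tot_acc_u(n), tot_acc_v(n);
  int tot_acc_a = 0;

  NumericVector alpha_s(n_save), su_s(n_save), sv_s(n_save);
  NumericMatrix U_s(n_save, n), V_s(n_save, n);

  RNGScope scope;
  const int total = burn_in + n_iter;
  int saved = 0;

  for (int it = 0; it < total; ++it) {
    const bool adapting = it < burn_in;

    // --- u_i updates (non-islands) ---
    for (int i = 0; i < n; ++i) {
      if (island[i]) continue;
      const double cur = u[i];
      const double prop = cur + std::exp(ls_u[i]) * R::norm_rand();
      double dprior = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
        const double uj = u[nb_index[k]];
        dprior += (prop - uj) * (prop - uj) - (cur - uj) * (cur - uj);
      }
      const double base = E[i] * std::exp(alpha + v[i]);
      const double dlog = Y[i] * (prop - cur)
        - base * (std::exp(prop) - std::exp(cur))
        - 0.5 * tau_u * dprior;
      if (dlog >= 0.0 || R::unif_rand() < std::exp(dlog)) {
        u[i] = prop;
        ++acc_u[i]; ++tot_acc_u[i];
      }
    }

    // --- v_i updates ---
    for (int i = 0; i < n; ++i) {
      const double cur = v[i];
      const double prop = cur + std::exp(ls_v[i]) * R::norm_rand();
      const double base = E[i] * std::exp(alpha + u[i]);
      const double dlog = Y[i] * (prop - cur)
        - base * (std::exp(prop) - std::exp(cur))
        - 0.5 * tau_v * (prop * prop - cur * cur);
      if (dlog >= 0.0 || R::unif_rand() < std::exp(dlog)) {
        v[i] = prop;
        ++acc_v[i]; ++tot_acc_v[i];
      }
    }

    // --- alpha update ---
    {
      const double prop = alpha + std::exp(ls_a) * R::norm_rand();
      double sumy = 0.0, summu = 0.0;
      for (int i = 0; i < n; ++i) {
        sumy += Y[i];
        summu += E[i] * std::exp(u[i] + v[i]);
      }
      const double dlog = sumy * (prop - alpha)
        - summu * (std::exp(prop) - std::exp(alpha));
      if (dlog >= 0.0 || R::unif_rand() < std::exp(dlog)) {
        alpha = prop;
        ++acc_a; ++tot_acc_a;
      }
    }

    // --- re-centre u; deficit into alpha, islands' v compensates ---
    if (n_free > 0) {
      double delta = 0.0;
      for (int i = 0; i < n; ++i) if (!island[i]) delta += u[i];
      delta /= n_free;
      for (int i = 0; i < n; ++i) {
        if (!island[i]) u[i] -= delta;
        else v[i] -= delta;
      }
      alpha += delta;
    }

    // --- precision updates (conjugate) ---
    if (icar_rank > 0) {
      double ss = 0.0;   // directed sum, each unique pair counted twice
      for (int i = 0; i < n; ++i) {
        if (island[i]) continue;
        for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
          const double d = u[i] - u[nb_index[k]];
          ss += d * d;
        }
      }
      tau_u = R::rgamma(a_u + 0.5 * icar_rank, 1.0 / (b_u + 0.25 * ss));
    } else {
      tau_u = R::rgamma(a_u, 1.0 / b_u);
    }
    {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * ss));
    }

    // --- adaptation (burn-in only), batches of 100 sweeps ---
    ++batch;
    if (adapting && batch == 100) {
      ++batch_no;
      const double step = std::min(0.1, 1.0 / std::sqrt((double) batch_no));
      for (int i = 0; i < n; ++i) {
        ls_u[i] += (acc_u[i] > 44) ? step : -step;
        ls_v[i] += (acc_v[i] > 44) ? step : -step;
        acc_u[i] = 0; acc_v[i] = 0;
      }
      ls_a += (acc_a > 44) ? step : -step;
      acc_a = 0;
      batch = 0;
    } else if (batch == 100) {
      batch = 0;
    }

    // --- save ---
    if (it >= burn_in && ((it - burn_in + 1) % thin == 0)) {
      alpha_s[saved] = alpha;
      su_s[saved] = 1.0 / std::sqrt(tau_u);
      sv_s[saved] = 1.0 / std::sqrt(tau_v);
      for (int i = 0; i < n; ++i) {
        U_s(saved, i) = u[i];
        V_s(saved, i) = v[i];
      }
      ++saved;
    }
  }

  const double denom = (double) total;
  return List::create(
    _["alpha"] = alpha_s, _["sigma_u"] = su_s, _["sigma_v"] = sv_s,
    _["u"] = U_s, _["v"] = V_s,
    _["accept"] = List::create(
      _["u"] = NumericVector(tot_acc_u) / denom,
      _["v"] = NumericVector(tot_acc_v) / denom,
      _["alpha"] = tot_acc_a / denom));
}
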