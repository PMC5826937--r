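#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Elastic-net-penalised Poisson regression along a lambda path.
//
// Minimises  -(1/N) sum_i [ y_i eta_i - exp(eta_i) ]
//            + lambda ( (1-alpha) ||beta||_2^2 / 2 + alpha ||beta||_1 )
// with eta_i = beta0 + x_i' beta, by outer IRLS (weights w = mu, working
// response z = eta + (y - mu)/mu) and inner cyclic coordinate descent
// with soft-thresholding. The intercept is unpenalised. X must arrive
// column-centred (no internal standardisation). The linear predictor is
// capped at +/- eta_cap before exponentiation.
//
// Warm starts: each lambda starts from the previous solution; the first
// lambda starts from (beta0_init, beta_init).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_poisson_path")]]
List cd_poisson_path(NumericMatrix X, NumericVector y, double alpha,
                     NumericVector lambda_seq, double tol, int max_sweeps,
                     double beta0_init, NumericVector beta_init,
                     double eta_cap) {
  const int N = X.nrow(), p = X.ncol(), L = lambda_seq.size();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  double beta0 = beta0_init;

  NumericMatrix beta_out(p, L);
  NumericVector beta0_out(L), maxdelta_out(L);
  IntegerVector sweeps_out(L), irls_out(L), full_sweeps_out(L);
  LogicalVector converged_out(L);

  std::vector<double> eta(N), w(N), r(N), v(p);
  std::vector<bool> active(p, false);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda_seq[l];
    const double l1 = lam * alpha, l2 = lam * (1.0 - alpha);
    int sweeps = 0, irls_iters = 0, full_sweeps = 0;
    bool outer_converged = false;
    double last_outer_change = R_PosInf;
    for (int j = 0; j < p; ++j) active[j] = beta[j] != 0.0;

    for (int irls = 0; irls < 200 && !outer_converged; ++irls) {
      ++irls_iters;
      // linear predictor from scratch (nonzero coefficients only)
      for (int i = 0; i < N; ++i) eta[i] = beta0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double bj = beta[j];
          for (int i = 0; i < N; ++i) eta[i] += bj * X(i, j);
        }
      }
      double sum_w = 0.0;
      for (int i = 0; i < N; ++i) {
        double e = eta[i];
        if (e > eta_cap) e = eta_cap;
        if (e < -eta_cap) e = -eta_cap;
        const double mu = std::exp(e);
        w[i] = mu;
        r[i] = (y[i] - mu) / mu;   // z - eta with z = eta + (y-mu)/mu
        sum_w += mu;
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += w[i] * X(i, j) * X(i, j);
        v[j] = s / N;
      }

      // inner coordinate descent on the weighted quadratic approximation
      double irls_change = 0.0;   // largest coefficient move this IRLS step
      bool full_sweep = true;     // alternate full / active-set sweeps
      while (true) {
        if (sweeps >= max_sweeps) break;
        ++sweeps;
        if (full_sweep) ++full_sweeps;
        double max_delta = 0.0;
        bool grew = false;

        // intercept as an unpenalised coordinate
        double d0 = 0.0;
        for (int i = 0; i < N; ++i) d0 += w[i] * r[i];
        d0 /= sum_w;
        if (d0 != 0.0) {
          beta0 += d0;
          for (int i = 0; i < N; ++i) r[i] -= d0;
          if (std::fabs(d0) > max_delta) max_delta = std::fabs(d0);
        }

        for (int j = 0; j < p; ++j) {
          if (!full_sweep && !active[j]) continue;
          double g = 0.0;
          for (int i = 0; i < N; ++i) g += w[i] * X(i, j) * r[i];
          g = g / N + v[j] * beta[j];
          const double bnew = soft(g, l1) / (v[j] + l2);
          const double delta = bnew - beta[j];
          if (delta != 0.0) {
            beta[j] = bnew;
            for (int i = 0; i < N; ++i) r[i] -= delta * X(i, j);
            if (std::fabs(delta) > max_delta) max_delta = std::fabs(delta);
          }
          if (bnew != 0.0 && !active[j]) { active[j] = true; grew = true; }
        }

        if (max_delta > irls_change) irls_change = max_delta;
        if (max_delta < tol) {
          if (full_sweep && !grew) break;   // full sweep stable: done
          full_sweep = true;                // confirm with a full sweep
        } else {
          full_sweep = false;               // iterate on the active set
        }
      }

      last_outer_change = irls_change;
      if (irls_change < tol) outer_converged = true;
      if (sweeps >= max_sweeps) break;
    }

    beta0_out[l] = beta0;
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    sweeps_out[l] = sweeps;
    irls_out[l] = irls_iters;
    full_sweeps_out[l] = full_sweeps;
    maxdelta_out[l] = last_outer_change;
    converged_out[l] = outer_converged;
  }

  return List::create(_["beta0"] = beta0_out, _["beta"] = beta_out,
                      _["sweeps"] = sweeps_out,
                      _["irls"] = irls_out,
                      _["full_sweeps"] = full_sweeps_out,
                      _["max_delta"] = maxdelta_out,
                      _["converged"] = converged_out);
}
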