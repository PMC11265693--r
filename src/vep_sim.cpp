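#include <Rcpp.h>
using namespace Rcpp;

// Forward Euler / Euler-Maruyama integration of the 2D Epileptor network:
//   dx_i = 1 - x_i^3 - 2 x_i^2 - z_i + I
//   dz_i = (1/tau) * (4 (x_i - eta_i) - z_i - K * sum_j C_ij (x_j - x_i))
// Process noise (sd sigma) enters both equations as sigma * sqrt(dt) * N(0,1).
// When sigma == 0 no random numbers are drawn, so the noise-free SDE path is
// bitwise identical to the ODE path.
//
// State magnitudes beyond `blowup` abort the integration (diverged_step >= 0).

static const double BLOWUP = 1e6;

// [[Rcpp::export]]
List sim_vep_cpp(NumericMatrix C, NumericVector eta, double K, double tau,
                 double I, double dt, int n_steps, NumericVector x0,
                 NumericVector z0, double sigma, int store_every) {
  const int n = eta.size();
  const int n_stored = n_steps / store_every + 1;
  NumericMatrix xs(n_stored, n), zs(n_stored, n);
  std::vector<double> x(n), z(n), rowsum(n, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = x0[i];
    z[i] = z0[i];
    for (int j = 0; j < n; ++j) rowsum[i] += C(i, j);
  }
  const double inv_tau = 1.0 / tau;
  const double sq_dt = std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  int diverged = -1;

  for (int i = 0; i < n; ++i) { xs(0, i) = x[i]; zs(0, i) = z[i]; }
  int row = 1;
  std::vector<double> xn(n), zn(n);
  for (int step = 1; step <= n_steps; ++step) {
    // coupling term: sum_j C_ij x_j - x_i * rowsum_i
    for (int i = 0; i < n; ++i) {
      double cx = 0.0;
      if (K != 0.0) {
        for (int j = 0; j < n; ++j) cx += C(i, j) * x[j];
        cx -= rowsum[i] * x[i];
      }
      double dx = 1.0 - x[i] * x[i] * x[i] - 2.0 * x[i] * x[i] - z[i] + I;
      double dz = inv_tau * (4.0 * (x[i] - eta[i]) - z[i] - K * cx);
      double nx = x[i] + dt * dx;
      double nz = z[i] + dt * dz;
      if (noisy) {
        nx += sigma * sq_dt * R::norm_rand();
        nz += sigma * sq_dt * R::norm_rand();
      }
      xn[i] = nx;
      zn[i] = nz;
    }
    x.swap(xn);
    z.swap(zn);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(z[i]) ||
          std::fabs(x[i]) > BLOWUP || std::fabs(z[i]) > BLOWUP) {
        diverged = step;
      }
    }
    if (diverged >= 0) break;
    if (step % store_every == 0) {
      for (int i = 0; i < n; ++i) { xs(row, i) = x[i]; zs(row, i) = z[i]; }
      ++row;
    }
  }
  return List::create(_["x"] = xs, _["z"] = zs, _["diverged_step"] = diverged);
}

// RMSE between the observation matrix and the sensor projection
// S_i(t) = sum_j G_ij exp(x_j(t)) of a fresh simulation under (eta, K).
// `obs` has one row per stored step (step 0 included) and one column per
// channel; `gain` is N_s x N_n (pass the identity for source-level problems).
// Divergence yields +Inf so the optimizer can discard the candidate.

// [[Rcpp::export]]
double cost_rmse_cpp(NumericMatrix C, NumericVector eta, double K, double tau,
                     double I, double dt, int n_steps, NumericVector x0,
                     NumericVector z0, double sigma, int store_every,
                     NumericMatrix gain, NumericMatrix obs) {
  const int n = eta.size();
  const int ns = gain.nrow();
  std::vector<double> x(n), z(n), rowsum(n, 0.0), ex(n), xn(n), zn(n);
  std::vector<double> Crm((size_t)n * n), Grm((size_t)ns * n);
  for (int i = 0; i < n; ++i) {
    x[i] = x0[i];
    z[i] = z0[i];
    for (int j = 0; j < n; ++j) {
      rowsum[i] += C(i, j);
      Crm[(size_t)i * n + j] = C(i, j);
    }
  }
  for (int s = 0; s < ns; ++s)
    for (int j = 0; j < n; ++j) Grm[(size_t)s * n + j] = gain(s, j);
  const double inv_tau = 1.0 / tau;
  const double sq_dt = std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  double sse = 0.0;
  long n_terms = 0;
  int row = 0;

  // accumulate row 0 (initial state) then each stored step
  for (int step = 0; step <= n_steps; ++step) {
    if (step > 0) {
      for (int i = 0; i < n; ++i) {
        double cx = 0.0;
        if (K != 0.0) {
          const double *ci = &Crm[(size_t)i * n];
          for (int j = 0; j < n; ++j) cx += ci[j] * x[j];
          cx -= rowsum[i] * x[i];
        }
        double dx = 1.0 - x[i] * x[i] * x[i] - 2.0 * x[i] * x[i] - z[i] + I;
        double dz = inv_tau * (4.0 * (x[i] - eta[i]) - z[i] - K * cx);
        double nx = x[i] + dt * dx;
        double nz = z[i] + dt * dz;
        if (noisy) {
          nx += sigma * sq_dt * R::norm_rand();
          nz += sigma * sq_dt * R::norm_rand();
        }
        xn[i] = nx;
        zn[i] = nz;
      }
      x.swap(xn);
      z.swap(zn);
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(z[i]) ||
            std::fabs(x[i]) > BLOWUP || std::fabs(z[i]) > BLOWUP)
          return R_PosInf;
      }
    }
    if (step % store_every == 0) {
      if (row >= obs.nrow()) break;
      for (int i = 0; i < n; ++i) ex[i] = std::exp(x[i]);
      for (int s = 0; s < ns; ++s) {
        double proj = 0.0;
        const double *gs = &Grm[(size_t)s * n];
        for (int j = 0; j < n; ++j) proj += gs[j] * ex[j];
        double d = proj - obs(row, s);
        sse += d * d;
        ++n_terms;
      }
      ++row;
    }
  }
  return std::sqrt(sse / (double)n_terms);
}
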