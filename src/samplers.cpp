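#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic surface families, mirrored from R/surfaces.R. Codes:
//   1 harmonic        par = (dim, center[dim], k[dim])
//   2 double_well 1D  par = (h, a)
//   3 gaussian_basin  par = (dim, nb, centers[nb*dim row-major], depths[nb],
//                            widths[nb], confine_k, confine_center[dim])
static inline void grad_surface(int code, const std::vector<double>& par,
                                const double* x, int dim, double* g) {
  if (code == 1) {
    const double* c = &par[1];
    const double* k = &par[1 + dim];
    for (int d = 0; d < dim; ++d) g[d] = k[d] * (x[d] - c[d]);
  } else if (code == 2) {
    double h = par[0], a = par[1];
    g[0] = 4.0 * h * x[0] * (x[0] * x[0] - a * a) / (a * a * a * a);
  } else if (code == 3) {
    int nb = (int)par[1];
    const double* centers = &par[2];
    const double* depths = &par[2 + nb * dim];
    const double* widths = &par[2 + nb * dim + nb];
    double ck = par[2 + nb * dim + 2 * nb];
    const double* cc = &par[2 + nb * dim + 2 * nb + 1];
    for (int d = 0; d < dim; ++d) g[d] = ck * (x[d] - cc[d]);
    for (int b = 0; b < nb; ++b) {
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dx = x[d] - centers[b * dim + d];
        r2 += dx * dx;
      }
      double w2 = widths[b] * widths[b];
      double e = depths[b] * std::exp(-r2 / (2.0 * w2)) / w2;
      for (int d = 0; d < dim; ++d) g[d] += (x[d] - centers[b * dim + d]) * e;
    }
  } else {
    stop("unknown surface code");
  }
}

// Overdamped Langevin (Brownian dynamics) with optional harmonic bias.
// x <- x - D*beta*grad(U + bias)*dt + sqrt(2*D*dt)*xi.
// Uses R's RNG, so runs are reproducible through set.seed() on the R side.
// [[Rcpp::export(name = ".langevin_run_cpp")]]
NumericMatrix langevin_run_cpp(int code, NumericVector surf_par, int dim,
                               NumericVector start, NumericVector bias_center,
                               NumericVector bias_k, double dt, double diffusion,
                               double beta, int n_steps, int stride,
                               double max_step) {
  std::vector<double> par(surf_par.begin(), surf_par.end());
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> g(dim);
  bool biased = bias_k.size() > 0;
  double drift = diffusion * beta * dt;
  double noise = std::sqrt(2.0 * diffusion * dt);
  int n_out = n_steps / stride;
  NumericMatrix out(n_out, dim);
  int row = 0;
  for (int s = 1; s <= n_steps; ++s) {
    grad_surface(code, par, x.data(), dim, g.data());
    if (biased)
      for (int d = 0; d < dim; ++d) g[d] += bias_k[d] * (x[d] - bias_center[d]);
    for (int d = 0; d < dim; ++d) {
      double step = -drift * g[d] + noise * R::norm_rand();
      if (std::fabs(step) > max_step)
        stop("langevin_sample: divergent step (|dx| = %f > %f); "
             "use a smaller timestep", std::fabs(step), max_step);
      x[d] += step;
    }
    if (s % stride == 0 && row < n_out) {
      for (int d = 0; d < dim; ++d) out(row, d) = x[d];
      ++row;
    }
  }
  return out;
}

// Two-state Markov chain with stationary P(state = 1) = p1 and per-step
// autocorrelation lambda (second eigenvalue of the transition matrix).
// Returns 0/1 states; initial state drawn from the stationary distribution.
// [[Rcpp::export(name = ".two_state_chain_cpp")]]
IntegerVector two_state_chain_cpp(int n, double p1, double lambda) {
  if (n <= 0) stop("two_state_chain: n must be positive");
  if (p1 < 0.0 || p1 > 1.0) stop("two_state_chain: invalid stationary probability");
  IntegerVector out(n);
  double p01 = p1 * (1.0 - lambda);        // 0 -> 1
  double p10 = (1.0 - p1) * (1.0 - lambda); // 1 -> 0
  int s = (unif_rand() < p1) ? 1 : 0;
  out[0] = s;
  for (int i = 1; i < n; ++i) {
    double u = unif_rand();
    if (s == 1) { if (u < p10) s = 0; }
    else { if (u < p01) s = 1; }
    out[i] = s;
  }
  return out;
}
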