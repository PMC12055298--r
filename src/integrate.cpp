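#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the four network dynamics models.
//
// model: 0 = double_well, 1 = mutualistic, 2 = sis, 3 = gene.
// Edges are 0-based endpoint vectors of the undirected edge list; the
// coupling sums are accumulated over both orientations of each edge.
// Noise draws come from R's RNG (one standard normal per node per step, in
// node order), so results are reproducible under set.seed().
// For the clamped models any component pushed below zero is set to zero
// immediately after each step.

// [[Rcpp::export(name = ".em_integrate_cpp")]]
NumericVector em_integrate_cpp(int model, NumericVector params,
                               IntegerVector efrom, IntegerVector eto,
                               NumericVector x0, double D, double u,
                               double dt, int nsteps, double sigma,
                               bool clamp) {
  const int n = x0.size();
  const int m = efrom.size();
  const double sqdt = std::sqrt(dt);
  NumericVector x = clone(x0);
  NumericVector f(n);

  for (int step = 0; step < nsteps; ++step) {
    // drift
    if (model == 0) {            // double well
      const double r1 = params[0], r2 = params[1], r3 = params[2];
      for (int i = 0; i < n; ++i)
        f[i] = -(x[i] - r1) * (x[i] - r2) * (x[i] - r3) + u;
      for (int e = 0; e < m; ++e) {
        const int a = efrom[e], b = eto[e];
        f[a] += D * x[b];
        f[b] += D * x[a];
      }
    } else if (model == 1) {     // mutualistic species
      const double B = params[0], K = params[1], C = params[2];
      const double Dt = params[3], E = params[4], H = params[5];
      for (int i = 0; i < n; ++i)
        f[i] = B + x[i] * (1.0 - x[i] / K) * (x[i] / C - 1.0) + u;
      for (int e = 0; e < m; ++e) {
        const int a = efrom[e], b = eto[e];
        const double xa = x[a], xb = x[b];
        f[a] += D * xa * xb / (Dt + E * xa + H * xb);
        f[b] += D * xb * xa / (Dt + E * xb + H * xa);
      }
    } else if (model == 2) {     // SIS
      const double mu = params[0];
      for (int i = 0; i < n; ++i) f[i] = 0.0;
      for (int e = 0; e < m; ++e) {
        const int a = efrom[e], b = eto[e];
        f[a] += x[b];
        f[b] += x[a];
      }
      for (int i = 0; i < n; ++i)
        f[i] = -mu * x[i] + D * (1.0 - x[i]) * f[i];
    } else {                     // gene regulatory
      const double B = params[0], fexp = params[1], h = params[2];
      for (int i = 0; i < n; ++i) f[i] = 0.0;
      for (int e = 0; e < m; ++e) {
        const int a = efrom[e], b = eto[e];
        const double ga = std::pow(x[a], h), gb = std::pow(x[b], h);
        f[a] += gb / (1.0 + gb);
        f[b] += ga / (1.0 + ga);
      }
      for (int i = 0; i < n; ++i)
        f[i] = -B * std::pow(x[i], fexp) + D * f[i] + u;
    }

    // Euler-Maruyama update
    if (sigma > 0.0) {
      for (int i = 0; i < n; ++i)
        x[i] += f[i] * dt + sigma * sqdt * norm_rand();
    } else {
      for (int i = 0; i < n; ++i)
        x[i] += f[i] * dt;
    }
    if (clamp)
      for (int i = 0; i < n; ++i)
        if (x[i] < 0.0) x[i] = 0.0;
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(x[i]))
        stop("state diverged (non-finite x) at step %d of %d (D = %g, u = %g)",
             step + 1, nsteps, D, u);
  }
  return x;
}
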