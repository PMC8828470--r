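#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler diffusion of a normalized expression vector on a regular
// lattice until the entropy change per step falls below eps.
//
// nbr: n x m matrix of 0-based neighbour indices, -1 where a neighbour is
// missing (zero-flux boundary: missing neighbours contribute the centre
// value). scale: stencil scaling (2/3 for the 6-neighbour hex stencil,
// 1 for the 4-neighbour square stencil).
// [[Rcpp::export(name = ".sepal_diffuse")]]
List sepal_diffuse(NumericVector u0, IntegerMatrix nbr, double D, double dt,
                   double eps, int max_iters, double scale) {
  const int n = u0.size();
  const int m = nbr.ncol();
  std::vector<double> u(u0.begin(), u0.end()), unew(n);

  auto entropy = [&](const std::vector<double>& v) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (s <= 0.0) return 0.0;
    double h = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = v[i] / s;
      if (p > 0.0) h -= p * std::log(p);
    }
    return h;
  };

  double h_prev = entropy(u);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iters; ++iter) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        int j = nbr(i, k);
        s += (j >= 0) ? u[j] : u[i];
      }
      unew[i] = u[i] + D * dt * scale * (s / m - u[i]);
    }
    u.swap(unew);
    double h = entropy(u);
    if (std::abs(h - h_prev) < eps) {
      converged = true;
      break;
    }
    h_prev = h;
  }
  if (!converged) iter = max_iters;
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += u[i];
  return List::create(_["score"] = iter * dt, _["converged"] = converged,
                      _["n_iters"] = iter, _["mass"] = total);
}
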