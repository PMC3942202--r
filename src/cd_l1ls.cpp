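#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for min ||Wx - y||^2 + lambda ||x||_1,
// parameterized by G = W'W and b = W'y. Maintains Gx incrementally and
// stops when the subgradient (KKT) gap falls below tol. Coordinates with
// a (numerically) zero diagonal keep a zero coefficient.
// [[Rcpp::export(name = ".cd_l1ls")]]
List cd_l1ls(const NumericMatrix& G, const NumericVector& b,
             double lambda, double tol, int max_iter) {
  const int n = G.ncol();
  const double half = lambda / 2.0;
  const double eps = std::numeric_limits<double>::epsilon();
  std::vector<double> x(n, 0.0), Gx(n, 0.0);
  double kkt = R_PosInf;
  int it = 0;

  while (it < max_iter) {
    ++it;
    for (int j = 0; j < n; ++j) {
      const double gjj = G(j, j);
      if (gjj <= eps) continue;
      const double rho = b[j] - Gx[j] + gjj * x[j];
      double xj = std::abs(rho) - half;
      xj = (xj > 0.0) ? ((rho > 0.0 ? xj : -xj) / gjj) : 0.0;
      const double d = xj - x[j];
      if (d != 0.0) {
        const double* gcol = &G(0, j);
        for (int i = 0; i < n; ++i) Gx[i] += gcol[i] * d;
        x[j] = xj;
      }
    }
    // KKT gap: g = 2(b - Gx); off support |g| <= lambda, on support
    // g = lambda * sign(x)
    kkt = 0.0;
    for (int j = 0; j < n; ++j) {
      const double g = 2.0 * (b[j] - Gx[j]);
      double v;
      if (x[j] == 0.0) {
        v = std::abs(g) - lambda;
        if (v < 0.0) v = 0.0;
      } else {
        v = std::abs(g - (x[j] > 0.0 ? lambda : -lambda));
      }
      if (v > kkt) kkt = v;
    }
    if (kkt <= tol) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["kkt_gap"] = kkt, _["n_iter"] = it);
}
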