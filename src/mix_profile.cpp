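// Profile maximization of the Model A mixture weights. Parameters are
// (a, b) = logit(q), logit(r) with p = (qr, q(1-r), (1-q)r, (1-q)(1-r));
// damped Newton with analytic gradient and finite-difference Hessian from
// several fixed starts (the surface has a ridge at q -> 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void props(double q, double r, double* p) {
  p[0] = q * r; p[1] = q * (1 - r); p[2] = (1 - q) * r;
  p[3] = (1 - q) * (1 - r);
}

// negative profile log-likelihood (without the column-max base) + gradient
static double nll_grad(const arma::mat& lik, const arma::vec& w,
                       double a, double b, arma::vec* grad) {
  double q = plogis_(a), r = plogis_(b), p[4];
  props(q, r, p);
  arma::rowvec den = p[0] * lik.row(0) + p[1] * lik.row(1) +
    p[2] * lik.row(2) + p[3] * lik.row(3);
  double f = -arma::dot(arma::log(den), w.t());
  if (grad) {
    arma::vec wd = w / den.t();
    double g[4];
    for (int c = 0; c < 4; ++c) g[c] = arma::dot(lik.row(c).t(), wd);
    double dpdq[4] = {r, 1 - r, -r, -(1 - r)};
    double dpdr[4] = {q, -q, 1 - q, -(1 - q)};
    double ga = 0, gb = 0;
    for (int c = 0; c < 4; ++c) { ga += g[c] * dpdq[c]; gb += g[c] * dpdr[c]; }
    (*grad)(0) = -ga * q * (1 - q);
    (*grad)(1) = -gb * r * (1 - r);
  }
  return f;
}

// [[Rcpp::export(name = ".rfMixProfile")]]
List rf_mix_profile(const arma::mat& cs, const arma::vec& w,
                    const arma::mat& starts) {
  const int S = cs.n_cols;
  arma::rowvec mx = arma::max(cs, 0);
  arma::mat lik = cs;
  lik.each_row() -= mx;
  lik = arma::exp(lik);
  double base = arma::dot(mx, w.t());
  const double LB = std::log(1e-4 / (1 - 1e-4)), UB = -LB;

  double bestF = 1e300, bestA = 0, bestB = 0;
  for (arma::uword s0 = 0; s0 < starts.n_rows; ++s0) {
    double a = std::log(starts(s0, 0) / (1 - starts(s0, 0)));
    double b = std::log(starts(s0, 1) / (1 - starts(s0, 1)));
    arma::vec g(2), g1(2), g2(2);
    double f = nll_grad(lik, w, a, b, &g);
    for (int it = 0; it < 100; ++it) {
      const double h = 1e-5;
      nll_grad(lik, w, a + h, b, &g1);
      nll_grad(lik, w, a, b + h, &g2);
      arma::mat H(2, 2);
      H(0, 0) = (g1(0) - g(0)) / h; H(0, 1) = (g2(0) - g(0)) / h;
      H(1, 0) = (g1(1) - g(1)) / h; H(1, 1) = (g2(1) - g(1)) / h;
      H = 0.5 * (H + H.t());
      // damp to positive definite
      double lam = 1e-8;
      arma::vec step;
      for (int k = 0; k < 8; ++k) {
        arma::mat Hd = H + lam * arma::eye(2, 2);
        bool ok = arma::solve(step, Hd, -g, arma::solve_opts::no_approx);
        if (ok && arma::dot(step, -g) < 0) { lam *= 10; continue; }
        if (ok) break;
        lam *= 10;
      }
      if (!step.is_finite()) step = -g;
      double t = 1.0, fNew = 0;
      double aN = a, bN = b;
      for (int ls = 0; ls < 30; ++ls) {
        aN = std::min(std::max(a + t * step(0), LB), UB);
        bN = std::min(std::max(b + t * step(1), LB), UB);
        fNew = nll_grad(lik, w, aN, bN, nullptr);
        if (fNew <= f + 1e-12) break;
        t *= 0.5;
      }
      double df = f - fNew;
      a = aN; b = bN;
      f = nll_grad(lik, w, a, b, &g);
      if (df < 1e-12 && arma::norm(g, "inf") < 1e-9) break;
      if (df < 1e-13) break;
    }
    if (f < bestF) { bestF = f; bestA = a; bestB = b; }
  }
  return List::create(_["q"] = plogis_(bestA), _["r"] = plogis_(bestB),
                      _["logL"] = base - bestF);
}
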