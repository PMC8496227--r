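// GY94 codon-model kernels: rate-matrix eigendecomposition, transition
// probabilities, and Felsenstein pruning over the 61 sense codons.
//
// The substitution classification between codon pairs (single-nt neighbour,
// transition vs transversion, synonymous vs nonsynonymous) is passed in as an
// integer matrix built once on the R side from the standard genetic code:
//   0 = not reachable by a single nucleotide change
//   1 = synonymous transversion, 2 = synonymous transition
//   3 = nonsynonymous transversion, 4 = nonsynonymous transition

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct CodonEigen {
  arma::vec lambda;   // eigenvalues of the reversible generator
  arma::mat A;        // D^{-1/2} U
  arma::mat B;        // U' D^{1/2}
  double mu;          // mean rate -sum_i pi_i Q_ii of the unscaled generator
};

static arma::mat build_q(const arma::imat& type, const arma::vec& pi,
                         double kappa, double omega) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int t = type(i, j);
      if (t == 0) continue;
      double r = pi(j);
      if (t == 2 || t == 4) r *= kappa;   // transition
      if (t == 3 || t == 4) r *= omega;   // nonsynonymous
      Q(i, j) = r;
      rowsum += r;
    }
    Q(i, i) = -rowsum;
  }
  return Q;
}

static CodonEigen codon_eigen(const arma::imat& type, const arma::vec& pi,
                              double kappa, double omega) {
  const int n = pi.n_elem;
  arma::mat Q = build_q(type, pi, kappa, omega);
  CodonEigen ce;
  ce.mu = 0.0;
  for (int i = 0; i < n; ++i) ce.mu -= pi(i) * Q(i, i);
  arma::vec sq = arma::sqrt(pi);
  // Symmetrize: S = D^{1/2} Q D^{-1/2} is symmetric for a reversible Q.
  arma::mat S(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      S(i, j) = sq(i) * Q(i, j) / sq(j);
  S = 0.5 * (S + S.t());
  arma::vec lam;
  arma::mat U;
  arma::eig_sym(lam, U, S);
  ce.lambda = lam;
  ce.A = U;
  ce.A.each_col() /= sq;          // D^{-1/2} U
  ce.B = U.t();
  ce.B.each_row() %= sq.t();      // U' D^{1/2}
  return ce;
}

static arma::mat pmat_from_eigen(const CodonEigen& ce, double t) {
  arma::vec e = arma::exp(ce.lambda * t);
  arma::mat P = ce.A * arma::diagmat(e) * ce.B;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// Eigendecomposition of one GY94 generator, returned to R so the caller
// can cache it across likelihood evaluations (kappa/omega pairs recur
// heavily inside quasi-Newton fits).
// [[Rcpp::export(name = ".rfCodonEigen")]]
List rf_codon_eigen_export(const arma::imat& type, const arma::vec& pi,
                           double kappa, double omega) {
  CodonEigen ce = codon_eigen(type, pi, kappa, omega);
  return List::create(_["lambda"] = ce.lambda, _["A"] = ce.A,
                      _["B"] = ce.B, _["mu"] = ce.mu);
}

// Pruning over precomputed eigendecompositions. eigenIdx is C x E, 1-based
// into the eigens list; teff already includes rate scaling.
// [[Rcpp::export(name = ".rfClassSiteLoglikPre")]]
arma::mat rf_class_site_loglik_pre(const arma::imat& edge, int nTip,
                                   const arma::imat& tipStates,
                                   const arma::mat& teff,
                                   const arma::imat& eigenIdx,
                                   const List& eigens, const arma::vec& pi) {
  const int E = edge.n_rows;
  const int C = teff.n_rows;
  const int S = tipStates.n_cols;
  const int n = pi.n_elem;
  int nNode = edge.max();
  const int root = edge(E - 1, 0);

  std::vector<CodonEigen> ces(eigens.size());
  for (int k = 0; k < eigens.size(); ++k) {
    List e = eigens[k];
    ces[k].lambda = as<arma::vec>(e["lambda"]);
    ces[k].A = as<arma::mat>(e["A"]);
    ces[k].B = as<arma::mat>(e["B"]);
    ces[k].mu = as<double>(e["mu"]);
  }
  // transition matrices dedupe: classes often share (generator, time) pairs
  std::map<std::pair<int, double>, arma::mat> pcache;
  arma::mat out(C, S);
  for (int c = 0; c < C; ++c) {
    std::vector<arma::mat> partial(nNode + 1);
    std::vector<arma::rowvec> lsc(nNode + 1);
    for (int v = 1; v <= nNode; ++v) lsc[v] = arma::rowvec(S, arma::fill::zeros);
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      std::pair<int, double> key(eigenIdx(c, e), teff(c, e));
      auto pit = pcache.find(key);
      if (pit == pcache.end())
        pit = pcache.emplace(
            key, pmat_from_eigen(ces[eigenIdx(c, e) - 1], teff(c, e))).first;
      const arma::mat& P = pit->second;
      arma::mat contrib(n, S);
      if (ch <= nTip) {
        for (int s = 0; s < S; ++s) {
          int st = tipStates(ch - 1, s);
          if (st < 0)
            contrib.col(s) = arma::sum(P, 1);
          else
            contrib.col(s) = P.col(st);
        }
      } else {
        contrib = P * partial[ch];
      }
      if (partial[par].n_elem == 0) {
        partial[par] = contrib;
        lsc[par] = (ch <= nTip) ? arma::rowvec(S, arma::fill::zeros) : lsc[ch];
      } else {
        partial[par] %= contrib;
        if (ch > nTip) lsc[par] += lsc[ch];
      }
      arma::rowvec m = arma::max(partial[par], 0);
      m.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
      partial[par].each_row() /= m;
      lsc[par] += arma::log(m);
    }
    arma::rowvec rootlik = pi.t() * partial[root];
    out.row(c) = arma::log(rootlik) + lsc[root];
  }
  return out;
}

// [[Rcpp::export(name = ".rfMeanRate")]]
double rf_mean_rate(const arma::imat& type, const arma::vec& pi,
                    double kappa, double omega) {
  arma::mat Q = build_q(type, pi, kappa, omega);
  double mu = 0.0;
  for (arma::uword i = 0; i < pi.n_elem; ++i) mu -= pi(i) * Q(i, i);
  return mu;
}

// Transition probability matrix P(t) for an unscaled GY94 generator.
// [[Rcpp::export(name = ".rfPmat")]]
arma::mat rf_pmat(const arma::imat& type, const arma::vec& pi,
                  double kappa, double omega, double t) {
  CodonEigen ce = codon_eigen(type, pi, kappa, omega);
  return pmat_from_eigen(ce, t);
}

// Per-site log-likelihoods for C site classes by pruning.
//
// edge:      E x 2 matrix of 1-based node ids in postorder (parent, child)
// tipStates: nTip x S integer matrix, 0-based codon indices, -1 = missing
// teff:      C x E matrix of effective times (branch length already divided
//            by the rate-scaling constant)
// omegaMat:  C x E matrix of omega on each edge for each class
// Returns a C x S matrix of site log-likelihoods (root weighted by pi).
// [[Rcpp::export(name = ".rfClassSiteLoglik")]]
arma::mat rf_class_site_loglik(const arma::imat& edge, int nTip,
                               const arma::imat& tipStates,
                               const arma::mat& teff, const arma::mat& omegaMat,
                               double kappa, const arma::vec& pi,
                               const arma::imat& type) {
  const int E = edge.n_rows;
  const int C = teff.n_rows;
  const int S = tipStates.n_cols;
  const int n = pi.n_elem;
  int nNode = edge.max();
  const int root = edge(E - 1, 0);

  std::map<double, CodonEigen> cache;
  arma::mat out(C, S);

  for (int c = 0; c < C; ++c) {
    std::vector<arma::mat> partial(nNode + 1);
    std::vector<arma::rowvec> lsc(nNode + 1);
    for (int v = 1; v <= nNode; ++v) lsc[v] = arma::rowvec(S, arma::fill::zeros);

    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      double om = omegaMat(c, e);
      auto it = cache.find(om);
      if (it == cache.end())
        it = cache.emplace(om, codon_eigen(type, pi, kappa, om)).first;
      arma::mat P = pmat_from_eigen(it->second, teff(c, e));

      arma::mat contrib(n, S);
      if (ch <= nTip) {
        // tip: indicator partial; contribution column = P(:, state)
        for (int s = 0; s < S; ++s) {
          int st = tipStates(ch - 1, s);
          if (st < 0)
            contrib.col(s) = arma::sum(P, 1);  // missing: sum over states
          else
            contrib.col(s) = P.col(st);
        }
      } else {
        contrib = P * partial[ch];
      }
      if (partial[par].n_elem == 0) {
        partial[par] = contrib;
        lsc[par] = (ch <= nTip) ? arma::rowvec(S, arma::fill::zeros) : lsc[ch];
      } else {
        partial[par] %= contrib;
        if (ch > nTip) lsc[par] += lsc[ch];
      }
      // column rescale to avoid underflow
      arma::rowvec m = arma::max(partial[par], 0);
      m.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
      partial[par].each_row() /= m;
      lsc[par] += arma::log(m);
    }

    arma::rowvec rootlik = pi.t() * partial[root];
    out.row(c) = arma::log(rootlik) + lsc[root];
  }
  return out;
}
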